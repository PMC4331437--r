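## Bundled fixture: the printed per-library counts of the original five-tissue
## L1Hs/AluYa5 junction-library survey (one donor: cerebellum, frontal cortex,
## SVZ, dentate gyrus, myocardium). Raw discovery from tissue DNA is not
## reproducible without the deposited reads; every *derivable* number (rates,
## fractions, sums, means and the whole test battery) is recomputed from these
## counts by auditCountTable().

.FIXTURE_MD5 <- c(
  library_counts.tsv = "5350546e1979ac1f85bc80996660f6a2",
  orientation_counts.tsv = "b5f54780b92989f6b391c2c538fef47d",
  detection_counts.tsv = "09620ae52769d329309da69ef4d779a7",
  combined_fractions.tsv = "27a634bf371cce61e94ec8054a3821b4"
)

.fixturePath <- function(file) {
  p <- system.file("extdata", file, package = "retroMosaic")
  if (p == "") stop("fixture '", file, "' not found")
  md5 <- unname(tools::md5sum(p))
  if (!identical(md5, unname(.FIXTURE_MD5[[file]])))
    stop("fixture '", file, "' fails its checksum; refusing to use a ",
         "tampered count table")
  p
}

#' Bundled published count tables
#'
#' Load the packaged per-library count tables of the five-tissue survey:
#' \code{countsFixture()} the read/insertion/compartment counts per family and
#' tissue; \code{orientationFixture()} co-/counter-orientation counts per
#' compartment; \code{detectionFixture()} reference-RE detection and
#' all-tissue germline counts; \code{combinedFixture()} the printed combined
#' L1+Alu compartment percentages. Each file is checksum-verified on load.
#'
#' @return a data.frame
#' @examples
#' head(countsFixture())
#' @export
countsFixture <- function() {
  utils::read.table(.fixturePath("library_counts.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname countsFixture
#' @export
orientationFixture <- function() {
  utils::read.table(.fixturePath("orientation_counts.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname countsFixture
#' @export
detectionFixture <- function() {
  utils::read.table(.fixturePath("detection_counts.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname countsFixture
#' @export
combinedFixture <- function() {
  utils::read.table(.fixturePath("combined_fractions.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Recompute every derivable published number from the bundled counts
#'
#' Recomputes, from the raw packaged counts alone: normalized somatic read
#' rates, genic/promoter percentages (per family and combined), grand totals,
#' reference-RE detection percentages, the mean and SD of co-oriented genic L1
#' percentages, and the full test battery (focal-tissue-vs-pooled and pairwise
#' exact Poisson rate tests, exact binomial orientation tests, overdispersion
#' tests), and compares each with the printed value at printed precision
#' (half-up rounding).
#'
#' Rows are classed \code{arithmetic} (pure recomputation of a printed number;
#' all are expected to pass) or \code{claim} (a printed statistical statement;
#' a claim that the declared test construction does not reproduce is reported
#' as a failure rather than adjusted away).
#'
#' @return data.frame with columns \code{target}, \code{class},
#'   \code{computed}, \code{expected}, \code{pass}
#' @examples
#' audit <- auditCountTable()
#' subset(audit, !pass)
#' @export
auditCountTable <- function() {
  lc <- countsFixture()
  oc <- orientationFixture()
  dc <- detectionFixture()
  cf <- combinedFixture()
  rows <- list()
  add <- function(target, class, computed, expected, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, class = class, computed = computed,
      expected = expected, pass = pass)
  }
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)

  for (i in seq_len(nrow(lc))) {
    lab <- paste(lc$family[i], lc$tissue[i], sep = "/")
    r <- roundHalfUp(100 * lc$somatic_reads[i] / lc$total_reads[i], 4)
    add(paste0("rate_pct ", lab), "arithmetic", fmt(r), fmt(lc$rate_pct[i]),
        r == lc$rate_pct[i])
    g <- roundHalfUp(100 * lc$genic_n[i] / lc$somatic_insertions[i], 2)
    add(paste0("genic_pct ", lab), "arithmetic", fmt(g), fmt(lc$genic_pct[i]),
        g == lc$genic_pct[i])
    p <- roundHalfUp(100 * lc$promoter_n[i] / lc$somatic_insertions[i], 2)
    add(paste0("promoter_pct ", lab), "arithmetic", fmt(p),
        fmt(lc$promoter_pct[i]), p == lc$promoter_pct[i])
  }
  ## combined L1+Alu compartment fractions per tissue
  for (t in cf$tissue) {
    sel <- lc$tissue == t
    gi <- roundHalfUp(100 * sum(lc$genic_n[sel]) / sum(lc$somatic_insertions[sel]), 2)
    pi <- roundHalfUp(100 * sum(lc$promoter_n[sel]) / sum(lc$somatic_insertions[sel]), 2)
    eg <- cf$genic_pct[cf$tissue == t]
    ep <- cf$promoter_pct[cf$tissue == t]
    add(paste0("combined_genic_pct ", t), "arithmetic", fmt(gi), fmt(eg), gi == eg)
    add(paste0("combined_promoter_pct ", t), "arithmetic", fmt(pi), fmt(ep), pi == ep)
  }
  ## grand totals
  tot <- function(fam, col) sum(lc[[col]][lc$family == fam])
  totals <- list(
    c("somatic_L1_total", "somatic_insertions", "L1Hs", 7497),
    c("somatic_Alu_total", "somatic_insertions", "AluYa5", 8990),
    c("genic_L1_total", "genic_n", "L1Hs", 3798),
    c("genic_Alu_total", "genic_n", "AluYa5", 4314),
    c("promoter_L1_total", "promoter_n", "L1Hs", 436),
    c("promoter_Alu_total", "promoter_n", "AluYa5", 393))
  for (tt in totals) {
    v <- tot(tt[3], tt[2])
    add(tt[1], "arithmetic", fmt(v), tt[4], v == as.numeric(tt[4]))
  }
  ## reference detection
  for (i in seq_len(nrow(dc))) {
    v <- roundHalfUp(100 * dc$ref_detected[i] / dc$ref_total[i], 1)
    add(paste0("ref_detection_pct ", dc$family[i]), "arithmetic",
        fmt(v), fmt(dc$ref_pct[i]), v == dc$ref_pct[i])
  }
  ## orientation percentages
  for (i in seq_len(nrow(oc))) {
    lab <- paste(oc$family[i], oc$tissue[i], oc$compartment[i], sep = "/")
    co <- roundHalfUp(100 * oc$co[i] / oc$n[i], 2)
    add(paste0("co_pct ", lab), "arithmetic", fmt(co), fmt(oc$co_pct[i]),
        co == oc$co_pct[i])
  }
  ## internal consistency of the printed orientation rows (co + counter = n);
  ## the cerebellum genic Alu row is inconsistent as printed (323 + 301 = 624)
  bad <- which(oc$co + oc$counter != oc$n)
  add("orientation_rows_internally_consistent", "claim",
      if (length(bad)) paste(oc$family[bad], oc$tissue[bad], oc$compartment[bad],
                             sprintf("%d+%d!=%d", oc$co[bad], oc$counter[bad],
                                     oc$n[bad]), collapse = "; ")
      else "all rows", "co + counter = n", length(bad) == 0L)

  ## mean +/- SD of co-oriented genic L1 percentages across tissues
  gl1 <- oc[oc$family == "L1Hs" & oc$compartment == "genic", ]
  cop <- 100 * gl1$co / gl1$n
  m <- roundHalfUp(mean(cop), 2)
  s <- roundHalfUp(stats::sd(cop), 2)
  add("co_genic_L1_mean", "arithmetic", fmt(m), "40.96", m == 40.96)
  add("co_genic_L1_sd", "arithmetic", fmt(s), "0.31", s == 0.31)

  ## --- test battery ---------------------------------------------------------
  x <- function(fam) stats::setNames(lc$somatic_reads[lc$family == fam],
                                     lc$tissue[lc$family == fam])
  n <- function(fam) stats::setNames(lc$total_reads[lc$family == fam],
                                     lc$tissue[lc$family == fam])
  ## cerebellum vs SVZ Alu rate: printed 0.0506
  pA <- poissonRateTest(x("AluYa5")[["cerebellum"]], n("AluYa5")[["cerebellum"]],
                        x("AluYa5")[["SVZ"]], n("AluYa5")[["SVZ"]])$p.value
  add("poisson_cerebellum_vs_SVZ_Alu_p", "claim", fmt(roundHalfUp(pA, 4)),
      "0.0506", roundHalfUp(pA, 4) == 0.0506)
  ## dentate-gyrus L1 vs pooled rest: printed < 0.0001
  pD <- rateVsPooledTest(x("L1Hs"), n("L1Hs"), "dentate_gyrus")$p.value
  add("poisson_DG_vs_pooled_L1_p", "claim", fmt(signif(pD, 3)), "< 0.0001",
      pD < 1e-4)
  ## pairwise L1 pattern: DG significant vs every tissue, the rest not
  pw <- pairwiseRateTests(x("L1Hs"), n("L1Hs"))
  dg <- pw$lib1 == "dentate_gyrus" | pw$lib2 == "dentate_gyrus"
  add("pairwise_L1_DG_all_lt_0.0001", "claim",
      fmt(signif(max(pw$p.value[dg]), 3)), "< 0.0001",
      all(pw$p.value[dg] < 1e-4))
  add("pairwise_L1_nonDG_all_gt_0.05", "claim",
      fmt(signif(min(pw$p.value[!dg]), 3)), "> 0.05",
      all(pw$p.value[!dg] > 0.05))
  ## pairwise Alu: everything significant except cerebellum vs SVZ
  pwA <- pairwiseRateTests(x("AluYa5"), n("AluYa5"))
  cs <- (pwA$lib1 == "cerebellum" & pwA$lib2 == "SVZ") |
    (pwA$lib1 == "SVZ" & pwA$lib2 == "cerebellum")
  add("pairwise_Alu_except_cer_SVZ", "claim",
      fmt(roundHalfUp(pwA$p.value[cs], 4)), "0.0506",
      roundHalfUp(pwA$p.value[cs], 4) == 0.0506 &&
        all(pwA$p.value[!cs] < 0.05))
  ## orientation tests
  pDGAlu <- orientationTest(oc$co[oc$family == "AluYa5" & oc$tissue == "dentate_gyrus" &
                                    oc$compartment == "genic"],
                            oc$n[oc$family == "AluYa5" & oc$tissue == "dentate_gyrus" &
                                   oc$compartment == "genic"])$p.value
  add("binomial_DG_genic_Alu_p", "claim", fmt(roundHalfUp(pDGAlu, 3)), "0.032",
      roundHalfUp(pDGAlu, 3) == 0.032)
  pOri <- vapply(seq_len(nrow(gl1)),
                 function(i) orientationTest(gl1$co[i], gl1$n[i])$p.value,
                 numeric(1))
  add("binomial_genic_L1_all_lt_0.0001", "claim", fmt(signif(max(pOri), 3)),
      "< 0.0001", all(pOri < 1e-4))
  promL1 <- oc[oc$family == "L1Hs" & oc$compartment == "promoter", ]
  pProm <- vapply(seq_len(nrow(promL1)),
                  function(i) orientationTest(promL1$co[i], promL1$n[i])$p.value,
                  numeric(1))
  add("binomial_promoter_L1_all_gt_0.05", "claim", fmt(signif(min(pProm), 3)),
      "> 0.05", all(pProm > 0.05))
  ## overdispersion on compartment fractions ("p > 0.98" printed)
  for (fam in c("L1Hs", "AluYa5")) {
    sel <- lc$family == fam
    for (col in c("genic_n", "promoter_n")) {
      pv <- overdispersionTest(lc[[col]][sel], lc$somatic_insertions[sel])$p.value
      add(sprintf("overdispersion_%s_%s_p", fam, sub("_n", "", col)), "claim",
          fmt(roundHalfUp(pv, 4)), "> 0.98", pv > 0.98)
    }
  }
  ## overdispersion on genic L1 orientation across tissues (printed 0.9999)
  pOd <- overdispersionTest(gl1$co, gl1$n)$p.value
  add("overdispersion_genic_L1_orientation_p", "claim",
      fmt(roundHalfUp(pOd, 4)), "0.9999", roundHalfUp(pOd, 4) == 0.9999)

  do.call(rbind, rows)
}
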