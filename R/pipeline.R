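#' Run the full somatic-insertion pipeline on a simulated experiment
#'
#' Executes simulate \eqn{\rightarrow} screen \eqn{\rightarrow} map
#' \eqn{\rightarrow} collapse \eqn{\rightarrow} classify \eqn{\rightarrow}
#' annotate \eqn{\rightarrow} statistics for every configured family, and
#' optionally writes the per-library summary TSV, orientation TSV, structured
#' statistics records (JSON) and a reconciliation log. Re-running with the
#' same configuration and seed reproduces byte-identical outputs.
#'
#' @param config a \code{\link{SimulationConfig}}
#' @param seed integer seed for simulation (calling is deterministic)
#' @param outDir optional output directory
#' @param minTerminus,minFlank screen thresholds (bp)
#' @param seedLength,maxMismatch mapper parameters
#' @param window collapse window (bp)
#' @param refTolerance reference-match tolerance (bp)
#' @param classifyTolerance cross-library merge tolerance (bp)
#' @param mcReplicates Monte-Carlo replicates for the distribution tests
#'   (0 skips them)
#' @param sim optionally, a pre-computed result of
#'   \code{\link{simulateLibraries}} to reuse
#' @return a list with \code{sim}, per-family \code{callsets},
#'   \code{classified}, \code{located}, \code{summary} (data.frame over all
#'   libraries), \code{orientation} (data.frame), \code{stats} (see
#'   \code{\link{pipelineStats}}), \code{log}
#' @export
runPipeline <- function(config, seed, outDir = NULL,
                        minTerminus = 20L, minFlank = 25L,
                        seedLength = 20L, maxMismatch = 2L, window = 3L,
                        refTolerance = 100L, classifyTolerance = 3L,
                        mcReplicates = 1000L, sim = NULL) {
  if (is.null(sim)) sim <- simulateLibraries(config, seed)
  genome <- sim$genome
  index <- buildAnnotationIndex(genome)
  callsets <- list()
  classified <- list()
  located <- list()
  summaries <- list()
  logLines <- c(sprintf("retroMosaic %s", as.character(utils::packageVersion("retroMosaic"))),
                sprintf("seed: %d", as.integer(seed)))
  for (fam in config@families) {
    rd <- sim$reads[[fam]]
    famSets <- list()
    totals <- stats::setNames(numeric(length(config@tissues)), config@tissues)
    for (tis in config@tissues) {
      sel <- rd$tissue == tis
      sc <- screenReads(rd$read1[sel], fam, minTerminus = minTerminus,
                        minFlank = minFlank, adapter = config@adapter,
                        ids = rd$read_id[sel])
      if (sc$tallies[["total"]] == 0L)
        logLines <- c(logLines, sprintf("%s/%s: no reads", tis, fam))
      mp <- mapFlanks(sc, genome, fam, seedLength = seedLength,
                      maxMismatch = maxMismatch)
      cs <- collapseCalls(mp$mapped, tissue = tis, family = fam,
                          window = window,
                          tallies = c(sc$tallies, mp$tallies))
      famSets[[tis]] <- cs
      totals[tis] <- sc$tallies[["accepted"]]
      logLines <- c(logLines, sprintf(
        "%s/%s: reads=%d accepted=%d rejected_terminus=%d short_flank=%d unique=%d ambiguous=%d unmapped=%d calls=%d",
        tis, fam, sc$tallies[["total"]], sc$tallies[["accepted"]],
        sc$tallies[["rejected_terminus"]], sc$tallies[["short_flank"]],
        mp$tallies[["unique"]], mp$tallies[["ambiguous"]],
        mp$tallies[["unmapped"]], length(cs)))
    }
    callsets[[fam]] <- famSets
    cls <- classifyInsertions(famSets, refREAnnotation(genome),
                              tolerance = classifyTolerance,
                              refTolerance = refTolerance)
    classified[[fam]] <- cls
    located[[fam]] <- locateInsertions(cls, index)
    summaries[[fam]] <- summarizeLibraries(cls, totals, index, family = fam)
  }
  summary <- do.call(rbind, unname(summaries))
  res <- list(sim = sim, index = index, callsets = callsets,
              classified = classified, located = located, summary = summary)
  res$orientation <- orientationSummary(classified, located, config@tissues)
  res$stats <- pipelineStats(res, config, mcReplicates = mcReplicates,
                             seed = seed)
  res$log <- logLines
  if (!is.null(outDir)) .writePipelineReport(res, outDir)
  res
}

#' Orientation summary table
#'
#' One row per (family, tissue, compartment in \{genic, promoter\}): somatic
#' insertion count, co- and counter-oriented counts and percentages.
#'
#' @param classified named (by family) list of classified
#'   \code{\link{InsertionSet}}s
#' @param located matching list of \code{\link{locateInsertions}} results
#' @param tissues tissue names
#' @return data.frame
#' @export
orientationSummary <- function(classified, located, tissues) {
  rows <- list()
  for (fam in names(classified)) {
    ev <- insertionEvents(classified[[fam]])
    som <- which(ev$class == "somatic")
    loc <- located[[fam]]
    tis <- as.character(unlist(ev$tissues[som]))
    for (t in tissues) {
      for (comp in c("genic", "promoter")) {
        i <- som[tis == t & loc$compartment[som] == comp]
        co <- sum(loc$orientation[i] == "co")
        ct <- sum(loc$orientation[i] == "counter")
        n <- co + ct
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, tissue = t, compartment = comp,
          n = n, co = co, counter = ct,
          co_pct = if (n > 0) 100 * co / n else NA_real_,
          counter_pct = if (n > 0) 100 * ct / n else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Statistical battery over a pipeline result
#'
#' Runs, per family: the focal-tissue-vs-pooled exact Poisson rate test and
#' all pairwise rate tests on somatic read rates; the overdispersion test on
#' genic fractions; exact binomial orientation tests per tissue and
#' compartment; and (when \code{mcReplicates > 0}) Monte-Carlo
#' genomic-distribution tests per library. Running it again on a saved
#' classification reproduces identical results.
#'
#' @param res a \code{\link{runPipeline}} result (or a list with
#'   \code{summary}, \code{orientation}, \code{index}, \code{sim})
#' @param config the \code{\link{SimulationConfig}} used
#' @param mcReplicates Monte-Carlo replicates (0 to skip)
#' @param seed seed for the Monte-Carlo draws
#' @return a list of per-family lists: \code{focalVsPooled},
#'   \code{pairwise}, \code{overdispersionGenic}, \code{orientation},
#'   \code{monteCarlo}
#' @export
pipelineStats <- function(res, config, mcReplicates = 1000L, seed = 1L) {
  out <- list()
  gl <- Biostrings::width(genomeSequences(res$sim$genome))
  names(gl) <- names(genomeSequences(res$sim$genome))
  seeds <- subSeeds(seed + 7L, length(config@families) * length(config@tissues))
  si <- 0L
  for (fam in unique(res$summary$family)) {
    if (is.na(fam)) next
    sm <- res$summary[res$summary$family == fam, ]
    x <- stats::setNames(sm$somatic_reads, sm$tissue)
    n <- stats::setNames(sm$total_reads, sm$tissue)
    famStats <- list()
    if (all(n > 0)) {
      famStats$focalVsPooled <- rateVsPooledTest(x, n, config@focalTissue)
      famStats$pairwise <- pairwiseRateTests(x, n)
    }
    if (!is.null(sm$genic_n) && sum(sm$somatic_insertions) > 0 &&
        all(sm$somatic_insertions > 0))
      famStats$overdispersionGenic <-
        overdispersionTest(sm$genic_n, sm$somatic_insertions)
    ori <- res$orientation[res$orientation$family == fam, ]
    famStats$orientation <- lapply(seq_len(nrow(ori)), function(i) {
      if (ori$n[i] < 1) return(NULL)
      ht <- orientationTest(ori$co[i], ori$n[i])
      ht$tissue <- ori$tissue[i]
      ht$compartment <- ori$compartment[i]
      ht
    })
    if (mcReplicates > 0) {
      famStats$monteCarlo <- list()
      ev <- insertionEvents(res$classified[[fam]])
      som <- which(ev$class == "somatic")
      loc <- res$located[[fam]]
      tis <- as.character(unlist(ev$tissues[som]))
      for (t in config@tissues) {
        si <- si + 1L
        i <- som[tis == t]
        if (length(i) == 0L) next
        famStats$monteCarlo[[t]] <- monteCarloDistributionTest(
          N = length(i), index = res$index, genomeLengths = gl,
          observedGenic = sum(loc$compartment[i] == "genic"),
          observedPromoter = sum(loc$compartment[i] == "promoter"),
          R = mcReplicates, seed = seeds[si])
      }
    }
    out[[fam]] <- famStats
  }
  out
}

.writePipelineReport <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(.roundCols(res$summary, c(rate_pct = 4, genic_pct = 2,
                                     promoter_pct = 2)),
           file.path(outDir, "library_summary.tsv"))
  writeTsv(.roundCols(res$orientation, c(co_pct = 2, counter_pct = 2)),
           file.path(outDir, "orientation_summary.tsv"))
  jsonlite::write_json(.statsRecords(res$stats),
                       file.path(outDir, "stats_records.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(outDir, "run_log.txt"))
  for (fam in names(res$callsets))
    for (tis in names(res$callsets[[fam]]))
      writeCallSet(res$callsets[[fam]][[tis]],
                   file.path(outDir, sprintf("calls_%s_%s.bed", tis, fam)))
  invisible(outDir)
}

.roundCols <- function(df, digits) {
  for (nm in names(digits))
    if (nm %in% colnames(df)) df[[nm]] <- roundHalfUp(df[[nm]], digits[[nm]])
  df
}

.statsRecords <- function(stats) {
  strip <- function(x) {
    if (inherits(x, "htest")) {
      y <- unclass(x)
      y$statistic <- as.list(y$statistic)
      y$parameter <- as.list(y$parameter)
      return(y)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(stats)
}

#' Somatic precision and recall against the simulated truth
#'
#' Compares classified somatic insertions with the planted somatic truth
#' events. A called somatic insertion is a true positive when a somatic truth
#' event of the same family and tissue lies within \code{tolerance} bp on the
#' same strand. Recall is measured against the amplifiable somatic truth
#' events (those whose junction fragment survived digestion): events that
#' produce no library molecule are invisible to any caller.
#'
#' @param res a \code{\link{runPipeline}} result
#' @param tolerance matching tolerance in bp
#' @return data.frame with one row per family: true positives, called,
#'   amplifiable truth, precision, recall
#' @export
somaticAccuracy <- function(res, tolerance = 3L) {
  rows <- list()
  for (fam in names(res$classified)) {
    ev <- insertionEvents(res$classified[[fam]])
    som <- ev[ev$class == "somatic"]
    frag <- res$sim$fragments[[fam]]
    truth <- frag[frag$class == "somatic", , drop = FALSE]
    keyT <- paste(truth$chrom, truth$strand,
                  vapply(truth$tissues, `[[`, character(1), 1))
    keyC <- paste(as.character(GenomicRanges::seqnames(som)),
                  as.character(GenomicRanges::strand(som)),
                  vapply(som$tissues, `[[`, character(1), 1))
    tp <- 0L
    usedT <- logical(nrow(truth))
    for (i in seq_along(som)) {
      cand <- which(keyT == keyC[i] & !usedT &
                      abs(truth$pos0 - (GenomicRanges::start(som)[i] - 1L)) <=
                      tolerance)
      if (length(cand)) {
        tp <- tp + 1L
        usedT[cand[1]] <- TRUE
      }
    }
    rows[[fam]] <- data.frame(
      family = fam, tp = tp, called = length(som), truth = nrow(truth),
      precision = if (length(som)) tp / length(som) else NA_real_,
      recall = if (nrow(truth)) tp / nrow(truth) else NA_real_)
  }
  do.call(rbind, rows)
}
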