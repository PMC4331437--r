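test_that("tissue assignment follows the class contract", {
  cfg <- tinyConfig()
  g <- tinyGenome()
  ev <- insertionEvents(plantInsertions(g, cfg, seed = 21))
  k <- length(cfg@tissues)
  expect_true(all(lengths(ev$tissues[ev$class == "germline"]) == k))
  expect_true(all(lengths(ev$tissues[ev$class == "reference"]) == k))
  expect_true(all(lengths(ev$tissues[ev$class == "somatic"]) == 1L))
})

test_that("somatic rate zero leaves only germline and reference events", {
  cfg <- tinyConfig()
  cfg@somaticRate[] <- 0
  ev <- insertionEvents(plantInsertions(tinyGenome(), cfg, seed = 22))
  expect_false(any(ev$class == "somatic"))
  expect_true(all(lengths(ev$tissues) == length(cfg@tissues)))
})

test_that("genic co-orientation frequency matches the configured probability", {
  # many genic events on a high-coverage genome; binomial 3 SE band
  cfg <- tinyConfig(geneFraction = 0.9, refCount = c(L1Hs = 0L, AluYa5 = 0L),
                    germlineCount = c(L1Hs = 0L, AluYa5 = 0L))
  cfg@somaticRate[] <- 0
  cfg@somaticRate[, "L1Hs"] <- 8000  # ~10k events over 5 tissues at 0.24 Mb
  g <- buildGenome(cfg, seed = 23)
  ev <- suppressWarnings(insertionEvents(plantInsertions(g, cfg, seed = 24)))
  genes <- geneAnnotation(g)
  hit <- GenomicRanges::findOverlaps(GenomicRanges::granges(ev), genes,
                                     ignore.strand = TRUE, select = "first")
  genic <- !is.na(hit)
  co <- as.character(GenomicRanges::strand(ev))[genic] ==
    as.character(GenomicRanges::strand(genes))[hit[genic]]
  n <- sum(genic)
  p <- cfg@coOrientProb[["L1Hs"]]
  expect_lt(abs(mean(co) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a unit genic multiplier gives a uniform genomic distribution", {
  cfg <- tinyConfig(refCount = c(L1Hs = 0L, AluYa5 = 0L),
                    germlineCount = c(L1Hs = 0L, AluYa5 = 0L))
  cfg@genicMultiplier[] <- 1
  cfg@somaticRate[] <- 0
  cfg@somaticRate[, "L1Hs"] <- 4000
  g <- tinyGenome()
  ev <- suppressWarnings(insertionEvents(plantInsertions(g, cfg, seed = 25)))
  genes <- geneAnnotation(g)
  f <- sum(GenomicRanges::width(genes)) /
    sum(Biostrings::width(genomeSequences(g)))
  genic <- GenomicRanges::countOverlaps(GenomicRanges::granges(ev), genes,
                                        ignore.strand = TRUE) > 0
  n <- length(ev)
  expect_lt(abs(mean(genic) - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("colliding insertion points are resampled with a warning", {
  cfg <- tinyConfig(chromLengths = c(chrA = 50000L),
                    refCount = c(L1Hs = 0L, AluYa5 = 0L))
  cfg@somaticRate[, "L1Hs"] <- 600   # ~150 events on 50 kb: collisions expected
  g <- buildGenome(cfg, seed = 26)
  expect_warning(is <- plantInsertions(g, cfg, seed = 27), "resampled")
  ev <- insertionEvents(is)
  for (chr in unique(as.character(GenomicRanges::seqnames(ev)))) {
    p <- sort(GenomicRanges::start(ev)[
      as.character(GenomicRanges::seqnames(ev)) == chr])
    expect_true(all(diff(p) >= 20L))
  }
})
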