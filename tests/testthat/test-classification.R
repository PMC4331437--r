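mkCallSet <- function(tissue, pos, strand = "+", chrom = "chr1", count = 1L,
                      family = "L1Hs") {
  n <- length(pos)
  calls <- GenomicRanges::GRanges(
    rep(chrom, n), IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L),
    strand = rep(strand, length.out = n),
    count = rep(as.integer(count), length.out = n),
    flank = rep("ACGT", n))
  methods::new("CallSet", tissue = tissue, family = family, calls = calls,
               tallies = c(accepted = n))
}

emptyRef <- GenomicRanges::GRanges(family = character())

test_that("single-tissue calls are somatic, all-tissue calls germline", {
  tis <- c("cerebellum", "frontal_cortex", "SVZ", "dentate_gyrus", "myocardium")
  sets <- lapply(tis, function(t) {
    pos <- c(10000L, if (t == "dentate_gyrus") 25000L)
    mkCallSet(t, pos)
  })
  cls <- classifyInsertions(sets, emptyRef)
  ev <- insertionEvents(cls)
  expect_identical(ev$class[GenomicRanges::start(ev) == 10001L], "germline")
  expect_identical(ev$class[GenomicRanges::start(ev) == 25001L], "somatic")
  expect_identical(as.character(unlist(
    ev$tissues[GenomicRanges::start(ev) == 25001L])), "dentate_gyrus")
})

test_that("calls in 2..k-1 tissues fall into the explicit ambiguous class", {
  sets <- list(mkCallSet("a", c(100L, 900L)), mkCallSet("b", 100L),
               mkCallSet("c", 5000L))
  ev <- insertionEvents(classifyInsertions(sets, emptyRef))
  cls <- ev$class[GenomicRanges::start(ev) == 101L]
  expect_identical(cls, "ambiguous_multi_tissue")
  # partition: each merged insertion gets exactly one class and counts add up
  expect_identical(length(ev), 3L)
  expect_setequal(ev$class, c("ambiguous_multi_tissue", "somatic", "somatic"))
})

test_that("classification is invariant to library input order", {
  sets <- list(mkCallSet("a", c(100L, 900L)), mkCallSet("b", c(102L, 4000L)),
               mkCallSet("c", 5000L))
  f <- function(s) {
    ev <- insertionEvents(classifyInsertions(s, emptyRef))
    df <- data.frame(pos = GenomicRanges::start(ev), class = ev$class)
    df[order(df$pos), ]
  }
  expect_identical(f(sets), f(rev(sets)))
})

test_that("duplicate library ids are a hard error", {
  expect_error(classifyInsertions(list(mkCallSet("a", 1L), mkCallSet("a", 2L)),
                                  emptyRef), "duplicate")
})

test_that("calls near an annotated same-family RE junction are reference", {
  # '+' L1: junction at the element's right (3') end
  re <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5086),
                               strand = "+", family = "L1Hs")
  cs <- mkCallSet("a", c(5086L, 5150L, 12000L))
  flags <- matchReference(cs, re, tolerance = 100L)
  expect_identical(flags, c(TRUE, TRUE, FALSE))
  # opposite strand does not match
  csm <- mkCallSet("a", 5086L, strand = "-")
  expect_false(matchReference(csm, re, tolerance = 100L))
  # Alu junction is at the 5' end
  reA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5073),
                                strand = "+", family = "AluYa5")
  csA <- mkCallSet("a", c(5000L, 5073L), strand = "-", family = "AluYa5")
  csA@calls <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5001L, 5074L), width = 1L), strand = "+",
    count = 1L, flank = "ACGT")
  expect_identical(matchReference(csA, reA, tolerance = 10L), c(TRUE, FALSE))
})

test_that("classified somatic insertions recover the planted truth", {
  res <- tinyPipeline()
  acc <- somaticAccuracy(res)
  expect_gte(acc$precision, 0.95)
  expect_gte(acc$recall, 0.95)
  # class partition on the merged set
  ev <- insertionEvents(res$classified$L1Hs)
  expect_identical(length(ev), sum(table(ev$class)))
})

test_that("summary reproduces printed-style rates at printed precision", {
  tis <- c("a", "b")
  sets <- list(mkCallSet("a", c(100L, 900L), count = c(2L, 1L)),
               mkCallSet("b", 5000L))
  cls <- classifyInsertions(sets, emptyRef)
  sm <- summarizeLibraries(cls, c(a = 3435529, b = 1000))
  expect_identical(sm$somatic_reads[sm$tissue == "a"], 3L)
  # the published dentate-gyrus L1 normalization: 3211 of 3435529 -> 0.0935%
  expect_identical(roundHalfUp(100 * 3211 / 3435529, 4), 0.0935)
  # and the genic fraction convention: 1558 of 3100 -> 50.26%
  expect_identical(roundHalfUp(100 * 1558 / 3100, 2), 50.26)
  # zero total reads: rate is missing, not zero
  sm0 <- summarizeLibraries(cls, c(a = 3435529, b = 0))
  expect_true(is.na(sm0$rate_pct[sm0$tissue == "b"]))
  # zero somatic reads with nonzero total: rate 0
  sets2 <- list(mkCallSet("a", 100L), mkCallSet("b", 100L))
  sm2 <- summarizeLibraries(classifyInsertions(sets2, emptyRef),
                            c(a = 1000, b = 1000))
  expect_identical(sm2$rate_pct, c(0, 0))
})

test_that("the somatic read-count ceiling reassigns high-support calls", {
  sets <- list(mkCallSet("a", c(100L, 900L), count = c(50L, 1L)),
               mkCallSet("b", 5000L))
  ev <- insertionEvents(classifyInsertions(sets, emptyRef,
                                           maxSomaticReads = 5L))
  expect_identical(ev$class[GenomicRanges::start(ev) == 101L], "germline")
  expect_identical(ev$class[GenomicRanges::start(ev) == 901L], "somatic")
})
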