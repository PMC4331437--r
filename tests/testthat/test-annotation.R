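test_that("promoter windows are 5 kb upstream on the gene's strand", {
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 40001, 2001), c(20000, 50000, 6000)),
    strand = c("+", "-", "+"), gene_id = c("g1", "g2", "g3"))
  idx <- buildAnnotationIndex(g)
  p <- promoterRanges(idx)
  # '+' gene [10001,20000]: promoter [5001,10000]
  expect_identical(GenomicRanges::start(p)[1], 5001L)
  expect_identical(GenomicRanges::end(p)[1], 10000L)
  # '-' gene [40001,50000]: promoter [50001,55000]
  expect_identical(GenomicRanges::start(p)[2], 50001L)
  expect_identical(GenomicRanges::end(p)[2], 55000L)
  # '+' gene starting at 2001: promoter clipped to [1,2000]
  expect_identical(GenomicRanges::start(p)[3], 1L)
  expect_identical(GenomicRanges::end(p)[3], 2000L)
  expect_error(buildAnnotationIndex(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), strand = "*")),
    "strand")
})

test_that("orientation is defined by element versus gene strand", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
                              strand = "+", gene_id = "g1")
  idx <- buildAnnotationIndex(g)
  ins <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(15000, 15000, 8000, 30000), width = 1),
    strand = c("-", "+", "-", "+"))
  loc <- locateInsertions(ins, idx)
  expect_identical(loc$compartment, c("genic", "genic", "promoter", "intergenic"))
  expect_identical(loc$orientation, c("counter", "co", "counter", NA))
  # boundary convention: half-open on the 0-based scale means base 10001 is
  # the first genic base and base 10000 the last promoter base
  b <- locateInsertions(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10000, 10001, 20000, 20001), width = 1),
    strand = "+"), idx)
  expect_identical(b$compartment, c("promoter", "genic", "genic", "intergenic"))
})

test_that("genic precedence makes compartments a partition", {
  # overlapping gene and promoter of another gene
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 22000), c(20000, 30000)),
    strand = c("+", "+"), gene_id = c("g1", "g2"))
  idx <- buildAnnotationIndex(g)   # g2 promoter [17000,21999] overlaps g1
  loc <- locateInsertions(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(18000, width = 1), strand = "+"), idx)
  expect_identical(loc$compartment, "genic")
  t <- attr(loc, "tallies")
  expect_identical(unname(t[["genic"]] + t[["promoter"]] + t[["intergenic"]]), 1L)
})

test_that("unknown chromosomes are counted intergenic with a warning", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
                              strand = "+", gene_id = "g1")
  idx <- buildAnnotationIndex(g)
  expect_warning(
    loc <- locateInsertions(GenomicRanges::GRanges(
      "chrUn", IRanges::IRanges(15000, width = 1), strand = "+"), idx),
    "unknown")
  expect_identical(loc$compartment, "intergenic")
})

test_that("point location agrees with a naive all-pairs overlap oracle", {
  g <- tinyGenome()
  idx <- buildAnnotationIndex(g)
  genes <- geneAnnotation(idx)
  prom <- promoterRanges(idx)
  set.seed(71)
  n <- 1000L
  chrom <- sample(names(genomeSequences(g)), n, replace = TRUE)
  pos <- vapply(chrom, function(ch)
    sample(Biostrings::width(genomeSequences(g))[[match(ch, names(genomeSequences(g)))]], 1L),
    numeric(1))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                              strand = sample(c("+", "-"), n, TRUE))
  loc <- locateInsertions(q, idx)
  naive <- function(ch, p) {
    gHit <- which(as.character(GenomicRanges::seqnames(genes)) == ch &
                    GenomicRanges::start(genes) <= p &
                    GenomicRanges::end(genes) >= p)
    if (length(gHit)) return("genic")
    pHit <- which(as.character(GenomicRanges::seqnames(prom)) == ch &
                    GenomicRanges::start(prom) <= p &
                    GenomicRanges::end(prom) >= p)
    if (length(pHit)) return("promoter")
    "intergenic"
  }
  want <- mapply(naive, chrom, pos)
  expect_identical(loc$compartment, unname(want))
})

test_that("uniform insertions hit genes at the genic genome fraction", {
  g <- tinyGenome()
  idx <- buildAnnotationIndex(g)
  f <- compartmentFractions(idx)[["genic"]]
  set.seed(72)
  n <- 5000L
  lens <- Biostrings::width(genomeSequences(g))
  chrom <- sample(names(genomeSequences(g)), n, replace = TRUE,
                  prob = lens / sum(lens))
  lp <- lens[match(chrom, names(genomeSequences(g)))]
  pos <- pmin(floor(runif(n) * lp), lp - 1) + 1
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  loc <- locateInsertions(q, idx)
  expect_lt(abs(mean(loc$compartment == "genic") - f),
            3 * sqrt(f * (1 - f) / n))
})
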