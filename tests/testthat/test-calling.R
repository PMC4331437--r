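test_that("terminus screening accepts clean reads and rejects 2-mismatch reads", {
  m <- l1hsFamilyModel()
  sT <- retroMosaic:::terminusFromPrimer(m)
  flank <- randomSeq(101 - nchar(sT))
  clean <- paste0(sT, flank)
  one <- clean
  substr(one, 3, 3) <- if (substr(one, 3, 3) == "A") "C" else "A"
  two <- one
  substr(two, 7, 7) <- if (substr(two, 7, 7) == "A") "C" else "A"
  sc <- screenReads(c(clean, one, two), m)
  expect_identical(unname(sc$tallies[["accepted"]]), 2L)
  expect_identical(unname(sc$tallies[["rejected_terminus"]]), 1L)
  expect_identical(nchar(sc$junctions$flank[1]), 101L - nchar(sT))
  # short flank is tallied separately
  shorty <- paste0(sT, randomSeq(10))
  sc2 <- screenReads(shorty, m)
  expect_identical(unname(sc2$tallies[["short_flank"]]), 1L)
  expect_identical(unname(sc2$tallies[["accepted"]]), 0L)
})

test_that("screen tallies reconcile with emitted junction pairs", {
  cfg <- tinyConfig(errorRate = 0)
  sim <- suppressWarnings(simulateLibraries(cfg, seed = 51))
  rd <- sim$reads$L1Hs
  sc <- screenReads(rd$read1, "L1Hs")
  # error-free reads all carry a perfect terminus and a >= minFlank flank
  expect_identical(unname(sc$tallies[["accepted"]]), nrow(rd))
  expect_identical(unname(sc$tallies[["total"]]),
                   unname(sc$tallies[["accepted"]] +
                            sc$tallies[["rejected_terminus"]] +
                            sc$tallies[["short_flank"]]))
})

test_that("malformed FASTQ raises an error naming the file", {
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II", "@r2", "ACGT"), bad)
  expect_error(readFastqSequences(bad), "malformed FASTQ")
})

test_that("verbatim flanks map back to their exact locus", {
  g <- tinyGenome()
  seqs <- genomeSequences(g)
  set.seed(61)
  fl <- as.character(Biostrings::subseq(seqs[["chrA"]], 5001, 5060))
  jn <- S4Vectors::DataFrame(read_id = "r1", terminus_match = 30L, flank = fl)
  mp <- mapFlanks(jn, g, "L1Hs")$mapped
  expect_identical(mp$status, "unique")
  expect_identical(mp$chrom, "chrA")
  expect_identical(mp$pos0, 5000L)        # 0-based junction at flank start
  expect_identical(mp$map_strand, "+")
})

test_that("a repeated flank is ambiguous and a foreign flank unmapped", {
  g <- tinyGenome()
  dup <- as.character(Biostrings::subseq(genomeSequences(g)[["chrA"]],
                                         7001, 7040))
  # a genome with the same 40-mer at two loci
  s <- paste0(randomSeq(60000), dup, randomSeq(500), dup, randomSeq(3000))
  g2 <- methods::new("GenomeModel",
                     sequences = Biostrings::DNAStringSet(c(chrX = s)),
                     genes = GenomicRanges::GRanges(),
                     refRE = GenomicRanges::GRanges())
  jn <- S4Vectors::DataFrame(read_id = c("a", "b"), terminus_match = 30L,
                             flank = c(dup, randomSeq(40)))
  mp <- mapFlanks(jn, g2, "L1Hs")$mapped
  expect_identical(mp$status, c("ambiguous", "unmapped"))
})

test_that("mapping status agrees with a brute-force full scan", {
  g <- tinyGenome()
  seqs <- genomeSequences(g)
  set.seed(62)
  flanks <- character(50)
  for (i in 1:50) {
    chr <- sample(names(seqs), 1)
    w <- sample(25:70, 1)
    st <- sample(length(seqs[[chr]]) - w, 1)
    fl <- as.character(Biostrings::subseq(seqs[[chr]], st, st + w - 1L))
    if (i %% 3 == 0)  # mix in reverse-strand flanks
      fl <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fl)))
    flanks[i] <- fl
  }
  jn <- S4Vectors::DataFrame(read_id = as.character(1:50),
                             terminus_match = 30L, flank = flanks)
  mp <- mapFlanks(jn, g, "L1Hs")$mapped
  for (i in 1:50) {
    n <- bruteMapCount(flanks[i], g, mm = 2L)
    want <- if (n == 0L) "unmapped" else if (n == 1L) "unique" else "ambiguous"
    expect_identical(mp$status[i], want, info = paste("flank", i))
  }
})

test_that("simulated error-bearing flanks map to the truth locus", {
  cfg <- tinyConfig()   # error rate 0.1%
  sim <- tinySim()
  rd <- sim$reads$L1Hs
  n <- min(nrow(rd), 1000L)
  sc <- screenReads(rd$read1[seq_len(n)], "L1Hs", ids = rd$read_id[seq_len(n)])
  mp <- mapFlanks(sc, sim$genome, "L1Hs")$mapped
  frag <- sim$fragments$L1Hs
  evid <- sub("^[^:]+:[^:]+:(.+):r\\d+$", "\\1", mp$read_id)
  truthPos <- frag$pos0[match(evid, frag$event_id)]
  uni <- mp$status == "unique"
  expect_gte(mean(uni), 0.95)
  expect_true(all(mp$pos0[uni] == truthPos[uni]))   # 0 bp position error
  # partition invariant
  expect_identical(unname(table(mp$status)["unique"] +
                            sum(mp$status == "ambiguous") +
                            sum(mp$status == "unmapped")),
                   as.integer(nrow(mp)))
})

test_that("collapse merges within the window at the modal coordinate", {
  mk <- function(pos, strand = "+") S4Vectors::DataFrame(
    read_id = as.character(seq_along(pos)), status = "unique",
    chrom = "chr1", pos0 = as.integer(pos),
    map_strand = strand, element_strand = strand, flank = "ACGT")
  cs <- collapseCalls(mk(c(1000L, 1002L)), "t", "L1Hs", window = 3L)
  expect_identical(length(cs), 1L)
  expect_identical(GenomicRanges::start(callRanges(cs)) - 1L, 1000L) # tie -> smaller
  expect_identical(callRanges(cs)$count, 2L)
  cs2 <- collapseCalls(mk(c(1000L, 1010L)), "t", "L1Hs", window = 3L)
  expect_identical(length(cs2), 2L)
  # same position, opposite strands: not merged
  both <- rbind(mk(1000L, "+"), mk(1000L, "-"))
  expect_identical(length(collapseCalls(both, "t", "L1Hs")), 2L)
})

test_that("collapsing a collapsed call set changes nothing", {
  res <- tinyPipeline()
  cs <- res$callsets$L1Hs$dentate_gyrus
  g <- callRanges(cs)
  again <- collapseCalls(S4Vectors::DataFrame(
    read_id = as.character(seq_along(g)), status = "unique",
    chrom = as.character(GenomicRanges::seqnames(g)),
    pos0 = GenomicRanges::start(g) - 1L,
    map_strand = as.character(GenomicRanges::strand(g)),
    element_strand = as.character(GenomicRanges::strand(g)),
    flank = g$flank, count = g$count), "dentate_gyrus", "L1Hs")
  expect_identical(GenomicRanges::start(callRanges(again)),
                   GenomicRanges::start(g))
  expect_identical(callRanges(again)$count, g$count)
})

test_that("error-free simulation yields one call per amplifiable event", {
  cfg <- tinyConfig(errorRate = 0)
  sim <- suppressWarnings(simulateLibraries(cfg, seed = 52))
  rd <- sim$reads$L1Hs
  frag <- sim$fragments$L1Hs
  tis <- "dentate_gyrus"
  sel <- rd$tissue == tis
  sc <- screenReads(rd$read1[sel], "L1Hs", ids = rd$read_id[sel])
  mp <- mapFlanks(sc, sim$genome, "L1Hs")
  cs <- collapseCalls(mp$mapped, tis, "L1Hs")
  carrying <- vapply(frag$tissues, function(t) tis %in% t, logical(1))
  emitted <- unique(rd$event_id[sel])
  expect_identical(length(cs), length(intersect(frag$event_id[carrying], emitted)))
})

test_that("BED import reproduces an exported call set exactly", {
  res <- tinyPipeline()
  cs <- res$callsets$L1Hs$cerebellum
  path <- withr::local_tempfile(fileext = ".bed")
  writeCallSet(cs, path)
  back <- importAlignments(path, "cerebellum", "L1Hs")
  expect_identical(GenomicRanges::start(callRanges(back)),
                   GenomicRanges::start(callRanges(cs)))
  expect_identical(as.character(GenomicRanges::strand(callRanges(back))),
                   as.character(GenomicRanges::strand(callRanges(cs))))
  expect_identical(callRanges(back)$count, callRanges(cs)$count)
})

test_that("BED import counts duplicates and rejects strandless records", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\ta\t0\t+",
               "chr1\t100\t101\tb\t0\t+",
               "chr2\t500\t501\tc\t0\t-"), bed)
  cs <- importAlignments(bed, "t", "L1Hs")
  expect_identical(length(cs), 2L)
  expect_setequal(callRanges(cs)$count, c(2L, 1L))
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t101\ta\t0\t.", bad)
  expect_error(importAlignments(bad, "t", "L1Hs"), "strand")
})
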