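# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small two-chromosome configuration, L1 only unless overridden
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    chromLengths = c(chrA = 120000L, chrB = 120000L),
    geneLengthRange = c(2000L, 8000L),
    families = "L1Hs",
    refCount = c(L1Hs = 8L, AluYa5 = 8L),
    germlineCount = c(L1Hs = 5L, AluYa5 = 5L))
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

tinyGenome <- function() cached("tinyGenome", buildGenome(tinyConfig(), seed = 301))

tinySim <- function() cached("tinySim",
  suppressWarnings(simulateLibraries(tinyConfig(), seed = 302)))

tinyPipeline <- function() cached("tinyPipeline",
  suppressWarnings(runPipeline(tinyConfig(), seed = 302, sim = tinySim(),
                               mcReplicates = 0)))

# brute-force digestion oracle: pure positional scan over every offset
bruteFragment <- function(seq, junction, enzymes, maxFragment = 3000L) {
  cuts <- integer()
  for (e in enzymes) {
    w <- nchar(e)
    for (o in seq_len(nchar(seq) - w + 1L)) {
      if (substr(seq, o, o + w - 1L) == e)
        cuts <- c(cuts, (o - 1L) + w %/% 2L)
    }
  }
  cuts <- sort(unique(cuts))
  lc <- cuts[cuts <= junction & junction - cuts <= maxFragment]
  rc <- cuts[cuts > junction & cuts - junction <= maxFragment]
  if (!length(lc) || !length(rc)) return(list(found = FALSE))
  list(found = TRUE, start = max(lc), end = min(rc))
}

# brute-force mapping oracle: full-scan occurrence count at <= mm mismatches
bruteMapCount <- function(flank, genome, mm = 2L) {
  seqs <- genomeSequences(genome)
  n <- 0L
  for (i in seq_along(seqs)) {
    n <- n + Biostrings::countPattern(flank, seqs[[i]], max.mismatch = mm)
    n <- n + Biostrings::countPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank))),
      seqs[[i]], max.mismatch = mm)
  }
  n
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
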