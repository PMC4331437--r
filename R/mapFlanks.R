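#' Map genomic flanks with an exact seed and mismatch-tolerant extension
#'
#' A toy read mapper sufficient for synthetic genomes: the first
#' \code{seedLength} bases of each flank are matched exactly against both
#' strands of the genome (\code{Biostrings} PDict matching), and every seed
#' hit is extended over the full flank allowing up to \code{maxMismatch}
#' substitutions. A flank maps uniquely only if exactly one extension passes;
#' several passing extensions make it \code{ambiguous}, none \code{unmapped}.
#' Flanks shorter than the seed are unmapped by definition.
#'
#' The junction coordinate is the flank's junction-adjacent boundary, giving
#' single-base resolution: the 0-based start of the hit for a forward-strand
#' mapping, its 0-based exclusive end for a reverse-strand mapping. The
#' element strand is the mapping strand for families whose 3' end abuts the
#' recovered flank, and the opposite strand for 5'-flank libraries.
#'
#' @param junctions screen result (\code{\link{screenReads}} output or its
#'   \code{junctions} DataFrame)
#' @param genome a \code{\link{GenomeModel}}
#' @param family an \code{\link{REFamilyModel}} (or family name)
#' @param seedLength exact-match seed length (bp)
#' @param maxMismatch maximum substitutions allowed over the full flank
#' @return list with \code{mapped} (a \code{DataFrame}: \code{read_id},
#'   \code{status} in \{unique, ambiguous, unmapped\}, and for unique hits
#'   \code{chrom}, \code{pos0} (0-based junction), \code{map_strand},
#'   \code{element_strand}, \code{flank}) and \code{tallies}
#' @export
mapFlanks <- function(junctions, genome, family, seedLength = 20L,
                      maxMismatch = 2L) {
  if (is.list(junctions) && !is(junctions, "DataFrame"))
    junctions <- junctions$junctions
  if (is.character(family)) family <- familyModel(family)
  flanks <- junctions$flank
  n <- length(flanks)
  status <- rep("unmapped", n)
  chrom <- rep(NA_character_, n)
  pos0 <- rep(NA_integer_, n)
  mapStrand <- rep(NA_character_, n)

  eligible <- which(nchar(flanks) >= seedLength &
                      !grepl("[^ACGT]", flanks))
  if (length(eligible)) {
    seeds <- substr(flanks[eligible], 1L, seedLength)
    useeds <- unique(seeds)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))
    fwd <- as.character(genomeSequences(genome))
    rev <- vapply(fwd, revcompChar, character(1))
    names(rev) <- names(fwd)

    cand <- list()   # per candidate: seedIdx, chrom, strand, start1 (in its own strand's coords)
    for (chr in names(fwd)) {
      for (st in c("+", "-")) {
        subject <- Biostrings::DNAString(if (st == "+") fwd[[chr]] else rev[[chr]])
        m <- Biostrings::matchPDict(pd, subject)
        hits <- S4Vectors::elementNROWS(m)
        if (sum(hits) == 0L) next
        si <- rep.int(seq_along(useeds), hits)
        starts <- unlist(IRanges::start(m), use.names = FALSE)
        cand[[length(cand) + 1L]] <-
          data.frame(seedIdx = si, chrom = chr, strand = st, start1 = starts)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      seedOf <- match(seeds, useeds)
      # expand candidates to reads sharing the seed
      readsBySeed <- split(eligible, seedOf)
      expIdx <- rep.int(seq_len(nrow(cand)),
                        lengths(readsBySeed[as.character(cand$seedIdx)]))
      readIdx <- unlist(readsBySeed[as.character(cand$seedIdx)], use.names = FALSE)
      cc <- cand[expIdx, , drop = FALSE]
      cc$read <- readIdx
      k <- nchar(flanks[cc$read])
      txt <- character(nrow(cc))
      for (chr in names(fwd)) {
        for (st in c("+", "-")) {
          sel <- cc$chrom == chr & cc$strand == st
          if (!any(sel)) next
          src <- if (st == "+") fwd[[chr]] else rev[[chr]]
          txt[sel] <- substring(src, cc$start1[sel], cc$start1[sel] + k[sel] - 1L)
        }
      }
      full <- nchar(txt) == k   # extension ran off the chromosome end otherwise
      mmok <- full
      mmok[full] <- mismatchPairwise(flanks[cc$read[full]], txt[full]) <= maxMismatch
      ok <- cc[mmok, , drop = FALSE]
      if (nrow(ok)) {
        nhit <- table(ok$read)
        uni <- as.integer(names(nhit)[nhit == 1L])
        amb <- as.integer(names(nhit)[nhit > 1L])
        status[amb] <- "ambiguous"
        if (length(uni)) {
          one <- ok[match(uni, ok$read), , drop = FALSE]
          status[uni] <- "unique"
          chrom[uni] <- one$chrom
          L <- nchar(fwd)[match(one$chrom, names(fwd))]
          kk <- nchar(flanks[uni])
          pos0[uni] <- ifelse(one$strand == "+",
                              one$start1 - 1L,             # 0-based start
                              L - one$start1 + 1L)         # 0-based exclusive end
          mapStrand[uni] <- one$strand
        }
      }
    }
  }
  flip <- family@flankedEnd == "5p"
  elementStrand <- if (flip) chartr("+-", "-+", mapStrand) else mapStrand
  mapped <- S4Vectors::DataFrame(
    read_id = junctions$read_id,
    status = status,
    chrom = chrom,
    pos0 = pos0,
    map_strand = mapStrand,
    element_strand = elementStrand,
    flank = flanks)
  list(mapped = mapped,
       tallies = c(reads = n,
                   unique = sum(status == "unique"),
                   ambiguous = sum(status == "ambiguous"),
                   unmapped = sum(status == "unmapped")))
}
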