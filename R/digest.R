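#' Locate the junction-containing restriction fragment in a sequence
#'
#' Scans a sequence for every occurrence of the given (palindromic,
#' mid-cutting) recognition sites, derives the cut positions, and returns the
#' fragment that contains the junction: the nearest cut at or left of the
#' junction to the nearest cut strictly right of it. This is the digestion
#' primitive used by \code{\link{digestEvents}} and is exposed for direct use
#' on literal sequences.
#'
#' @param seq character, the (insertion-bearing) sequence
#' @param junction 0-based inter-base junction coordinate within \code{seq}
#' @param enzymes character vector of recognition sequences; each is cut in
#'   the middle (e.g. AGCT is cut between G and C)
#' @param maxFragment maximum junction-to-cut distance considered; a missing
#'   cut within this span on either side makes the fragment unrecoverable
#' @return list with \code{found} (logical), and when found \code{start},
#'   \code{end} (0-based half-open fragment bounds), \code{left},
#'   \code{right} (junction-to-cut distances)
#' @examples
#' s <- paste(rep("A", 200), collapse = "")
#' substr(s, 81, 84) <- "AGCT"   # site at 0-based offset 80
#' substr(s, 151, 154) <- "GTAC" # site at 0-based offset 150
#' junctionFragment(s, 100, c("AGCT", "GTAC"))  # fragment [82, 152)
#' @export
junctionFragment <- function(seq, junction, enzymes, maxFragment = 3000L) {
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    m <- gregexpr(e, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(integer())
    as.integer(m - 1L + nchar(e) %/% 2L)   # 0-based cut position
  }))))
  leftCuts <- cuts[cuts <= junction & junction - cuts <= maxFragment]
  rightCuts <- cuts[cuts > junction & cuts - junction <= maxFragment]
  if (length(leftCuts) == 0L || length(rightCuts) == 0L)
    return(list(found = FALSE))
  s <- max(leftCuts)
  e <- min(rightCuts)
  list(found = TRUE, start = s, end = e, left = junction - s, right = e - junction)
}

#' Compute junction fragments for planted insertion events
#'
#' For every event of one family, reconstructs the local insertion-bearing
#' sequence (the terminus is virtually inserted at the junction for germline
#' and somatic events; reference events are read straight off the genome,
#' where the terminus is already embedded), digests it with the family's
#' enzymes, and keeps the junction-containing fragment when it is amplifiable:
#' the nested primer site must lie inside the fragment and the genomic flank
#' between junction and cut site must be at least \code{minFlank} bp.
#' Fragments whose nearest cut site is beyond \code{maxFragment} on either
#' side are dropped and counted in the suppression-loss tally.
#'
#' @param genome a \code{\link{GenomeModel}}
#' @param events an \code{\link{InsertionSet}}
#' @param family an \code{\link{REFamilyModel}} (or family name)
#' @param config a \code{\link{SimulationConfig}}
#' @return list with \code{fragments}, a \code{DataFrame} of amplifiable
#'   fragments (one row per event: junction, strand, class, tissues, flank
#'   sequence in read orientation truncated to what a read can cover, full
#'   flank length, fragment boundaries as junction distances) and
#'   \code{tallies} (\code{planted}, \code{amplifiable},
#'   \code{suppression_loss}, \code{short_flank}, \code{primer_loss})
#' @export
digestEvents <- function(genome, events, family, config) {
  if (is.character(family)) family <- familyModel(family)
  ev <- insertionEvents(events)
  ev <- ev[ev$family == family@family]
  seqs <- as.character(genomeSequences(genome))
  term <- as.character(family@terminus)
  tl <- nchar(term)
  sT <- terminusFromPrimer(family)
  primerOff <- nestedPrimerOffset(family)
  enz <- config@enzymes[[family@family]]
  maxFrag <- config@maxFragment
  readFlankMax <- config@readLength    # longest flank a read could need

  n <- length(ev)
  keep <- logical(n)
  flankSeq <- character(n)
  flankLen <- integer(n)
  leftLen <- integer(n)
  rightLen <- integer(n)
  drop <- c(suppression_loss = 0L, short_flank = 0L, primer_loss = 0L)

  for (i in seq_len(n)) {
    chr <- as.character(GenomicRanges::seqnames(ev)[i])
    j <- GenomicRanges::start(ev)[i] - 1L          # 0-based junction
    s <- as.character(GenomicRanges::strand(ev)[i])
    right <- (family@flankedEnd == "3p") == (s == "+")
    L <- nchar(seqs[[chr]])
    a <- max(0L, j - maxFrag - 100L)
    b <- min(L, j + maxFrag + 100L)
    ctxL <- substr(seqs[[chr]], a + 1L, j)         # genome [a, j)
    ctxR <- substr(seqs[[chr]], j + 1L, b)         # genome [j, b)
    if (ev$class[i] == "reference") {
      # terminus already embedded, junction at j by construction
      local <- paste0(ctxL, ctxR)
      jl <- j - a
    } else if (right) {
      local <- paste0(ctxL, term, ctxR)
      jl <- (j - a) + tl
    } else {
      local <- paste0(ctxL, revcompChar(term), ctxR)
      jl <- j - a
    }
    fr <- junctionFragment(local, jl, enz, maxFrag)
    if (!fr$found) { drop["suppression_loss"] <- drop["suppression_loss"] + 1L; next }
    fl <- if (right) fr$right else fr$left
    if (fl < config@minFlank) { drop["short_flank"] <- drop["short_flank"] + 1L; next }
    # nested primer must survive digestion: for a right-side junction the
    # element occupies local [jl - tl, jl) (reference events included, by
    # embedding); require the fragment to reach past the primer start.
    if (right) {
      primerStart <- jl - tl + primerOff
      if (fr$start > primerStart) { drop["primer_loss"] <- drop["primer_loss"] + 1L; next }
      fs <- substr(local, jl + 1L, jl + min(fl, readFlankMax))
    } else {
      primerEnd <- jl + tl - primerOff   # exclusive, in local coords
      if (fr$end < primerEnd) { drop["primer_loss"] <- drop["primer_loss"] + 1L; next }
      fs <- revcompChar(substr(local, jl - min(fl, readFlankMax) + 1L, jl))
    }
    keep[i] <- TRUE
    flankSeq[i] <- fs
    flankLen[i] <- fl
    leftLen[i] <- fr$left
    rightLen[i] <- fr$right
  }

  frag <- S4Vectors::DataFrame(
    event_id = ev$event_id[keep],
    chrom = as.character(GenomicRanges::seqnames(ev))[keep],
    pos0 = GenomicRanges::start(ev)[keep] - 1L,
    strand = as.character(GenomicRanges::strand(ev))[keep],
    family = family@family,
    class = ev$class[keep],
    tissues = ev$tissues[keep],
    flank_seq = flankSeq[keep],
    flank_len = flankLen[keep],
    frag_left = leftLen[keep],
    frag_right = rightLen[keep])
  list(fragments = frag,
       tallies = c(planted = n, amplifiable = sum(keep), drop))
}
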