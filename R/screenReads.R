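#' Screen junction-library reads for an informative element terminus
#'
#' Read 1 of an informative pair must begin with the family terminus (from the
#' nested primer onward) with at most one mismatch over at least
#' \code{minTerminus} bases; the remainder of the read is the genomic flank.
#' A read-through suppression-adapter suffix (recognised by an exact match of
#' the adapter's first 10 bases) is trimmed from the flank. Pairs whose
#' trimmed flank is shorter than \code{minFlank} are discarded and tallied.
#'
#' The screen thresholds are declared, configurable stand-ins for the
#' filtering applied to real libraries, whose exact steps are protocol
#' specific.
#'
#' @param reads1 character vector of read-1 sequences, a \code{DNAStringSet},
#'   or the path to a FASTQ file
#' @param family an \code{\link{REFamilyModel}} (or family name)
#' @param minTerminus minimum terminus match length (bp)
#' @param minFlank minimum informative flank length (bp)
#' @param adapter adapter sequence used for read-through trimming
#' @param ids optional read identifiers
#' @return list with \code{junctions} (a \code{DataFrame}: \code{read_id},
#'   \code{terminus_match}, \code{flank}) and \code{tallies}
#'   (\code{total}, \code{accepted}, \code{rejected_terminus},
#'   \code{short_flank})
#' @export
screenReads <- function(reads1, family, minTerminus = 20L, minFlank = 25L,
                        adapter = .ADAPTER, ids = NULL) {
  if (is.character(family)) family <- familyModel(family)
  if (is.character(reads1) && length(reads1) == 1L && file.exists(reads1))
    reads1 <- readFastqSequences(reads1)
  if (is(reads1, "XStringSet")) {
    if (is.null(ids)) ids <- names(reads1)
    reads1 <- as.character(reads1)
  }
  if (is.null(ids)) ids <- as.character(seq_along(reads1))
  sT <- terminusFromPrimer(family)
  m <- nchar(sT)
  if (m < minTerminus)
    stop("family terminus segment is shorter than minTerminus")

  n <- length(reads1)
  if (n == 0L) {
    return(list(junctions = S4Vectors::DataFrame(read_id = character(),
                                                 terminus_match = integer(),
                                                 flank = character()),
                tallies = c(total = 0L, accepted = 0L,
                            rejected_terminus = 0L, short_flank = 0L)))
  }
  longEnough <- nchar(reads1) > m
  mm <- rep(Inf, n)
  mm[longEnough] <- mismatchToRef(substr(reads1[longEnough], 1L, m), sT)
  pass <- longEnough & mm <= 1
  flank <- substr(reads1, m + 1L, nchar(reads1))
  # adapter read-through trimming: internal occurrence of the adapter start,
  # then partial terminal overlap (>= 3 bp of the adapter prefix at the read
  # end), as any adapter trimmer does
  akey <- substr(adapter, 1L, 10L)
  apos <- regexpr(akey, flank, fixed = TRUE)
  trim <- pass & apos > 0L
  flank[trim] <- substr(flank[trim], 1L, apos[trim] - 1L)
  for (k in 9:3) {
    fl <- nchar(flank)
    suf <- pass & fl >= k &
      substr(flank, fl - k + 1L, fl) == substr(adapter, 1L, k)
    flank[suf] <- substr(flank[suf], 1L, fl[suf] - k)
  }
  short <- pass & nchar(flank) < minFlank
  keep <- pass & !short
  list(junctions = S4Vectors::DataFrame(read_id = ids[keep],
                                        terminus_match = rep(m, sum(keep)),
                                        flank = flank[keep]),
       tallies = c(total = n, accepted = sum(keep),
                   rejected_terminus = sum(!pass),
                   short_flank = sum(short)))
}

#' Read sequences from a FASTQ file
#'
#' Thin wrapper over \code{Biostrings} FASTQ input that raises a clear error
#' naming the offending file when a record is malformed.
#'
#' @param path FASTQ path
#' @return a \code{DNAStringSet}
#' @export
readFastqSequences <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ record at end of '", path, "': ",
         "record ", length(lines) %/% 4L + 1L, " is truncated", call. = FALSE)
  hdr <- seq(1L, length(lines), by = 4L)
  bad <- which(substr(lines[hdr], 1L, 1L) != "@" |
                 substr(lines[hdr + 2L], 1L, 1L) != "+")
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'", call. = FALSE)
  tryCatch(Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = FALSE),
           error = function(e)
             stop("malformed FASTQ record in '", path, "': ",
                  conditionMessage(e), call. = FALSE))
}
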