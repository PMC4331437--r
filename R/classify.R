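#' Flag calls that match annotated reference retroelements
#'
#' A call is a rediscovery of a reference-genome RE copy when it lies within
#' \code{tolerance} bp of the junction-proximal end of an annotated
#' same-family element on the same strand (the 3'-end for L1-style families,
#' the 5'-end for Alu-style families).
#'
#' @param callset a \code{\link{CallSet}}
#' @param refRE reference-RE annotation \code{GRanges} (with \code{family})
#' @param tolerance match tolerance in bp
#' @return logical vector, one per call
#' @export
matchReference <- function(callset, refRE, tolerance = 100L) {
  g <- callRanges(callset)
  if (length(g) == 0L) return(logical())
  fam <- libraryFamily(callset)
  re <- refRE[refRE$family == fam]
  if (length(re) == 0L) return(rep(FALSE, length(g)))
  model <- familyModel(fam)
  j <- refJunctionPos0(re, model@flankedEnd)
  ref <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(re)),
    IRanges::IRanges(start = pmax(1L, j + 1L - tolerance),
                     end = j + 1L + tolerance),
    strand = GenomicRanges::strand(re))
  GenomeInfoDb::seqlevels(ref) <- union(GenomeInfoDb::seqlevels(ref),
                                        GenomeInfoDb::seqlevels(g))
  GenomicRanges::countOverlaps(g, ref, ignore.strand = FALSE) > 0L
}

#' Classify insertion calls across the libraries of one family
#'
#' Pools the call sets of all \code{k} tissues of one family, merges calls
#' co-located within \code{tolerance} bp on the same chromosome and element
#' strand, and classifies each merged insertion: matches a reference RE copy
#' in any library \eqn{\rightarrow} \code{reference}; otherwise present in
#' exactly one library \eqn{\rightarrow} \code{somatic}; in all \code{k}
#' \eqn{\rightarrow} \code{germline}; in between \eqn{\rightarrow}
#' \code{ambiguous_multi_tissue} (counted in neither extreme class). The
#' output is invariant to library input order.
#'
#' @param callsets list of \code{\link{CallSet}}s, one per tissue, same family
#' @param refRE reference-RE annotation \code{GRanges}
#' @param tolerance cross-library merge tolerance in bp
#' @param refTolerance reference-match tolerance in bp
#' @param maxSomaticReads optional ceiling on the read count of a somatic
#'   insertion; single-tissue insertions above it are treated as presumed
#'   germline events with library dropout and labelled \code{germline}.
#'   The default \code{NULL} applies no ceiling: observed somatic insertions
#'   carry very few reads, but the low read count is an observation, not a
#'   filter
#' @return an \code{\link{InsertionSet}} whose events carry \code{family},
#'   \code{class}, \code{tissues}, \code{counts} (per-carrying-library read
#'   counts, an \code{IntegerList} parallel to \code{tissues}) and
#'   \code{total_reads}
#' @export
classifyInsertions <- function(callsets, refRE, tolerance = 3L,
                               refTolerance = 100L, maxSomaticReads = NULL) {
  stopifnot(length(callsets) >= 2L)
  tissues <- vapply(callsets, libraryTissue, character(1))
  if (anyDuplicated(tissues)) stop("duplicate library ids")
  fams <- unique(vapply(callsets, libraryFamily, character(1)))
  if (length(fams) != 1L) stop("all call sets must target the same family")
  o <- order(tissues)              # input-order invariance
  callsets <- callsets[o]
  tissues <- tissues[o]
  k <- length(callsets)

  rows <- lapply(seq_len(k), function(i) {
    g <- callRanges(callsets[[i]])
    data.frame(
      tissue = if (length(g)) tissues[i] else character(),
      chrom = as.character(GenomicRanges::seqnames(g)),
      pos0 = GenomicRanges::start(g) - 1L,
      strand = as.character(GenomicRanges::strand(g)),
      count = if (length(g)) g$count else integer(),
      isref = matchReference(callsets[[i]], refRE, refTolerance),
      row.names = NULL)
  })
  df <- do.call(rbind, rows)
  if (nrow(df) == 0L) {
    ev <- GenomicRanges::GRanges(family = character(), class = character(),
                                 tissues = IRanges::CharacterList(),
                                 counts = IRanges::IntegerList(),
                                 total_reads = integer())
    return(new("InsertionSet", events = ev))
  }
  key <- paste(df$chrom, df$strand)
  cl <- integer(nrow(df))
  off <- 0L
  for (kk in unique(key)) {
    i <- which(key == kk)
    cl[i] <- chainCluster(df$pos0[i], tolerance) + off
    off <- max(cl[i])
  }
  grp <- split(seq_len(nrow(df)), cl)
  recs <- lapply(grp, function(i) {
    tis <- sort(unique(df$tissue[i]))
    cnt <- vapply(tis, function(t) sum(df$count[i][df$tissue[i] == t]),
                  numeric(1))
    cls <- if (any(df$isref[i])) "reference"
    else if (length(tis) == 1L) "somatic"
    else if (length(tis) == k) "germline"
    else "ambiguous_multi_tissue"
    if (!is.null(maxSomaticReads) && cls == "somatic" &&
        sum(cnt) > maxSomaticReads) cls <- "germline"
    list(chrom = df$chrom[i][1],
         pos0 = modalValue(df$pos0[i], df$count[i]),
         strand = df$strand[i][1],
         class = cls, tissues = tis, counts = as.integer(cnt),
         total = sum(cnt))
  })
  ev <- GenomicRanges::GRanges(
    unname(vapply(recs, `[[`, character(1), "chrom")),
    IRanges::IRanges(start = unname(vapply(recs, `[[`, numeric(1), "pos0")) + 1L,
                     width = 1L),
    strand = unname(vapply(recs, `[[`, character(1), "strand")),
    family = fams,
    class = unname(vapply(recs, `[[`, character(1), "class")),
    tissues = IRanges::CharacterList(unname(lapply(recs, `[[`, "tissues"))),
    counts = IRanges::IntegerList(unname(lapply(recs, `[[`, "counts"))),
    total_reads = unname(vapply(recs, `[[`, numeric(1), "total")))
  ev <- sort(ev, ignore.strand = TRUE)
  out <- new("InsertionSet", events = ev)
  validObject(out)
  out
}

#' Per-library summary of somatic insertion discovery
#'
#' Builds the per-library summary table: total high-quality reads, reads
#' representing potentially somatic insertions, somatic insertion count, the
#' normalized rate (\code{100 * somatic reads / total reads}), and, when an
#' \code{\link{AnnotationIndex}} is supplied, the count and percentage of
#' somatic insertions in genes and in promoter windows. Rates are reported
#' unrounded; printed-precision rounding is applied only when formatting.
#' A zero read total yields a missing (NA) rate, not zero.
#'
#' @param classified an \code{\link{InsertionSet}} from
#'   \code{\link{classifyInsertions}}
#' @param totalReads named numeric: total high-quality reads per tissue
#' @param index optional \code{\link{AnnotationIndex}}
#' @param family family label used when the classified set is empty
#' @return a \code{data.frame} with one row per tissue
#' @export
summarizeLibraries <- function(classified, totalReads, index = NULL,
                               family = NULL) {
  ev <- insertionEvents(classified)
  som <- ev[ev$class == "somatic"]
  tiss <- names(totalReads)
  somTissue <- as.character(unlist(som$tissues))
  loc <- NULL
  if (!is.null(index) && length(som))
    loc <- locateInsertions(som, index)
  out <- lapply(tiss, function(t) {
    i <- which(somTissue == t)
    somReads <- sum(unlist(som$counts[i]))
    n <- length(i)
    rate <- if (totalReads[[t]] > 0) 100 * somReads / totalReads[[t]] else NA_real_
    fam <- if (!is.null(family)) family else
      if (length(ev)) ev$family[1] else NA_character_
    row <- data.frame(tissue = t,
                      family = fam,
                      total_reads = totalReads[[t]],
                      somatic_reads = somReads,
                      somatic_insertions = n,
                      rate_pct = rate)
    if (!is.null(loc)) {
      gi <- sum(loc$compartment[i] == "genic")
      pi <- sum(loc$compartment[i] == "promoter")
      row$genic_n <- gi
      row$genic_pct <- if (n > 0) 100 * gi / n else NA_real_
      row$promoter_n <- pi
      row$promoter_pct <- if (n > 0) 100 * pi / n else NA_real_
    }
    row
  })
  do.call(rbind, out)
}
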