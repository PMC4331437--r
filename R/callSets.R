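#' Collapse uniquely mapped junction reads into calls
#'
#' Reads whose junction coordinates lie within \code{window} bp of one another
#' on the same chromosome and element strand chain-merge into one call placed
#' at the modal coordinate (ties broken toward the smaller coordinate); the
#' call's read count is the merged read total. Collapsing is idempotent.
#'
#' @param mapped result of \code{\link{mapFlanks}} (or its \code{mapped}
#'   DataFrame); only \code{status == "unique"} rows are used
#' @param tissue library tissue label
#' @param family family label
#' @param window merge window in bp
#' @param tallies optional named numeric carried into the \code{CallSet}
#' @return a \code{\link{CallSet}}
#' @export
collapseCalls <- function(mapped, tissue, family, window = 3L,
                          tallies = numeric()) {
  if (is.list(mapped) && !is(mapped, "DataFrame")) {
    if (length(tallies) == 0L && !is.null(mapped$tallies))
      tallies <- mapped$tallies
    mapped <- mapped$mapped
  }
  u <- mapped[mapped$status == "unique", , drop = FALSE]
  if (nrow(u) == 0L) {
    calls <- GenomicRanges::GRanges(count = integer(), flank = character())
    return(new("CallSet", tissue = tissue, family = family,
               calls = calls, tallies = stats::setNames(as.numeric(tallies),
                                                        names(tallies))))
  }
  wt <- if ("count" %in% colnames(u)) u$count else rep(1L, nrow(u))
  key <- paste(u$chrom, u$element_strand)
  cl <- integer(nrow(u))
  off <- 0L
  for (kk in unique(key)) {
    i <- which(key == kk)
    cl[i] <- chainCluster(u$pos0[i], window) + off
    off <- max(cl[i])
  }
  pos <- vapply(split(seq_len(nrow(u)), cl), function(i)
    modalValue(u$pos0[i], wt[i]), numeric(1))
  grp <- split(seq_len(nrow(u)), cl)
  count <- vapply(grp, function(i) sum(wt[i]), numeric(1))
  first <- vapply(seq_along(grp), function(g) {
    i <- grp[[g]]
    i[u$pos0[i] == pos[g]][1]
  }, integer(1))
  calls <- GenomicRanges::GRanges(
    u$chrom[first],
    IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L),
    strand = u$element_strand[first],
    count = as.integer(count),
    flank = u$flank[first])
  o <- GenomicRanges::order(calls)
  cs <- new("CallSet", tissue = tissue, family = family, calls = calls[o],
            tallies = tallies)
  validObject(cs)
  cs
}

#' Export a call set as BED6+1
#'
#' Columns: chrom, 0-based half-open junction interval, name, score = read
#' count, element strand, family.
#'
#' @param callset a \code{\link{CallSet}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeCallSet <- function(callset, path) {
  g <- callRanges(callset)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::start(g),
    name = sprintf("%s_%s_call%05d", libraryTissue(callset),
                   libraryFamily(callset), seq_along(g)),
    score = g$count,
    strand = as.character(GenomicRanges::strand(g)),
    family = libraryFamily(callset))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import pre-mapped junction alignments as a call set
#'
#' Accepts a BED file of junction records (BED6, optionally with a 7th family
#' column as written by \code{\link{writeCallSet}}) or a SAM/BAM file of
#' flank alignments (requires \pkg{Rsamtools}; the junction is taken at the
#' alignment's strand-appropriate boundary). Records without strand are
#' rejected. Duplicate positions merge; a BED score column, when present and
#' positive, is taken as the read count of the record.
#'
#' @param path BED/SAM/BAM path
#' @param tissue library tissue label
#' @param family family label
#' @param window collapse window in bp, as in \code{\link{collapseCalls}}
#' @return a \code{\link{CallSet}}
#' @export
importAlignments <- function(path, tissue, family, window = 3L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    df <- .samJunctions(path)
  } else {
    df <- .bedJunctions(path)
  }
  if (any(is.na(df$strand) | df$strand == "*" | df$strand == "."))
    stop("alignment records without strand are rejected")
  mapped <- S4Vectors::DataFrame(
    read_id = as.character(seq_len(nrow(df))),
    status = "unique",
    chrom = df$chrom,
    pos0 = df$pos0,
    map_strand = df$strand,
    element_strand = df$strand,
    flank = if (is.null(df$flank)) "" else df$flank,
    count = df$count)
  collapseCalls(mapped, tissue = tissue, family = family, window = window,
                tallies = c(imported = nrow(df)))
}

.bedJunctions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("need BED6 with a strand column")
  count <- if (all(df[[5]] > 0)) as.integer(df[[5]]) else rep(1L, nrow(df))
  data.frame(chrom = as.character(df[[1]]), pos0 = as.integer(df[[2]]),
             strand = as.character(df[[6]]), count = count)
}

.samJunctions <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM/BAM import requires the Rsamtools package")
  if (tolower(tools::file_ext(path)) == "sam")
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  st <- as.character(b$strand)[keep]
  pos0 <- ifelse(st == "+", b$pos[keep] - 1L,
                 b$pos[keep] - 1L + b$qwidth[keep])
  data.frame(chrom = as.character(b$rname)[keep], pos0 = as.integer(pos0),
             strand = st, count = 1L)
}
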