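#' Build a strand-aware gene + promoter annotation index
#'
#' Promoter windows are the \code{upstream} bp (default 5,000) immediately
#' upstream of each gene's transcription start site on the gene's strand,
#' clipped at chromosome bounds. Gene and promoter interval sets are kept
#' queryable independently.
#'
#' @param genes gene annotation: a stranded \code{GRanges} (with optional
#'   \code{gene_id}), a \code{\link{GenomeModel}}, or the path to a BED6 file
#' @param upstream promoter window size in bp
#' @return an \code{\link{AnnotationIndex}}
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
#'                             strand = "+")
#' buildAnnotationIndex(g)   # promoter is [5001, 10000]
#' @export
buildAnnotationIndex <- function(genes, upstream = 5000L) {
  if (is(genes, "GenomeModel")) {
    gm <- genes
    genes <- geneAnnotation(gm)
    GenomeInfoDb::seqlengths(genes) <-
      stats::setNames(Biostrings::width(genomeSequences(gm)),
                      names(genomeSequences(gm)))
  } else if (is.character(genes)) {
    genes <- rtracklayer::import(genes, format = "BED")
  }
  if (length(genes) && any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("gene records without strand are rejected")
  if (is.null(genes$gene_id)) {
    genes$gene_id <- if (!is.null(genes$name)) genes$name else
      sprintf("gene%04d", seq_along(genes))
  }
  # windows at chromosome edges are out of bound until clipped; the
  # intermediate validity warnings are expected and silenced
  prom <- suppressWarnings({
    p <- GenomicRanges::promoters(genes, upstream = upstream, downstream = 0L)
    p <- GenomicRanges::restrict(p, start = 1L)   # clip at the left edge
    GenomicRanges::trim(p)                        # and at seqlengths, if set
  })
  prom <- prom[GenomicRanges::width(prom) > 0L]
  prom$gene_strand <- as.character(GenomicRanges::strand(prom))
  ai <- new("AnnotationIndex", genes = genes, promoters = prom,
            upstream = as.integer(upstream))
  validObject(ai)
  ai
}

#' Locate insertions in genes, promoters or intergenic space
#'
#' Point query of each insertion's junction base against the index. An
#' insertion inside a gene body is \code{genic}; otherwise inside a promoter
#' window, \code{promoter}; otherwise \code{intergenic} (genic takes
#' precedence over promoter so the compartments partition the insertions).
#' For genic and promoter insertions the orientation call is \code{co} when
#' the element strand equals the gene strand, else \code{counter}; it is
#' \code{NA} for intergenic insertions. Insertions on a chromosome unknown to
#' the index are counted intergenic with a warning.
#'
#' @param insertions a stranded \code{GRanges} of width-1 junction loci (e.g.
#'   \code{insertionEvents()} of a classified set), or an
#'   \code{\link{InsertionSet}}
#' @param index an \code{\link{AnnotationIndex}}
#' @return a \code{data.frame} with one row per insertion:
#'   \code{compartment}, \code{orientation}, \code{gene_id}; the compartment
#'   tallies are attached as \code{attr(, "tallies")}
#' @export
locateInsertions <- function(insertions, index) {
  if (is(insertions, "InsertionSet"))
    insertions <- insertionEvents(insertions)
  n <- length(insertions)
  compartment <- rep("intergenic", n)
  orientation <- rep(NA_character_, n)
  geneId <- rep(NA_character_, n)
  if (n > 0L) {
    genes <- geneAnnotation(index)
    prom <- promoterRanges(index)
    known <- GenomeInfoDb::seqlevels(genes)
    unk <- !(as.character(GenomicRanges::seqnames(insertions)) %in% known) &
      length(genes) > 0L
    if (any(unk))
      warning(sum(unk), " insertion(s) on chromosomes unknown to the index; ",
              "counted intergenic")
    q <- GenomicRanges::granges(insertions)
    GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(q), known)
    gh <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE,
                                      select = "first")
    ph <- GenomicRanges::findOverlaps(q, prom, ignore.strand = TRUE,
                                      select = "first")
    isG <- !is.na(gh)
    isP <- !isG & !is.na(ph)
    compartment[isG] <- "genic"
    compartment[isP] <- "promoter"
    es <- as.character(GenomicRanges::strand(insertions))
    gs <- rep(NA_character_, n)
    gs[isG] <- as.character(GenomicRanges::strand(genes))[gh[isG]]
    gs[isP] <- prom$gene_strand[ph[isP]]
    geneId[isG] <- genes$gene_id[gh[isG]]
    geneId[isP] <- prom$gene_id[ph[isP]]
    inAnn <- isG | isP
    orientation[inAnn] <- ifelse(es[inAnn] == gs[inAnn], "co", "counter")
  }
  out <- data.frame(compartment = compartment, orientation = orientation,
                    gene_id = geneId)
  attr(out, "tallies") <- c(genic = sum(compartment == "genic"),
                            promoter = sum(compartment == "promoter"),
                            intergenic = sum(compartment == "intergenic"))
  out
}

#' Genic and promoter fractions of an annotation index
#'
#' Fraction of the genome covered by gene bodies and by promoter-only space
#' (promoter windows minus any genic overlap), used by the Monte-Carlo
#' genomic-distribution null.
#'
#' @param index an \code{\link{AnnotationIndex}}
#' @param genomeLength total genome length in bp (taken from the index
#'   seqlengths when missing)
#' @return named numeric: \code{genic}, \code{promoter}
#' @export
compartmentFractions <- function(index, genomeLength = NULL) {
  genes <- GenomicRanges::reduce(geneAnnotation(index), ignore.strand = TRUE)
  prom <- GenomicRanges::reduce(promoterRanges(index), ignore.strand = TRUE)
  promOnly <- GenomicRanges::setdiff(prom, genes, ignore.strand = TRUE)
  if (is.null(genomeLength)) {
    sl <- GenomeInfoDb::seqlengths(geneAnnotation(index))
    if (any(is.na(sl))) stop("genomeLength missing and seqlengths unset")
    genomeLength <- sum(as.numeric(sl))
  }
  c(genic = sum(as.numeric(GenomicRanges::width(genes))) / genomeLength,
    promoter = sum(as.numeric(GenomicRanges::width(promOnly))) / genomeLength)
}
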