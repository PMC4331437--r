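#' Build a synthetic reference genome
#'
#' Generates random chromosome sequences, lays down a non-overlapping gene
#' annotation covering approximately \code{geneFraction} of each chromosome,
#' and embeds reference retroelement copies (the family terminus sequence,
#' oriented by element strand) at random loci. Deterministic for a fixed seed.
#'
#' Gene placement draws gene lengths uniformly from \code{geneLengthRange}
#' until the genic target of a chromosome is met (so realised genic coverage
#' is within one gene length of the target) and then distributes the
#' intergenic residue randomly between the genes.
#'
#' @param config a \code{\link{SimulationConfig}}
#' @param seed integer seed
#' @return a \code{\link{GenomeModel}}
#' @examples
#' g <- buildGenome(simulationConfig(chromLengths = c(chrA = 60000L),
#'                                   refCount = c(L1Hs = 4L, AluYa5 = 4L)),
#'                  seed = 1)
#' g
#' @export
buildGenome <- function(config, seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(seed, {
    lens <- config@chromLengths
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    genes <- .placeGenes(lens, config@geneFraction, config@geneLengthRange)
    refRE <- .plantReferenceREs(lens, genes, config)

    seqs <- .embedTermini(seqs, refRE)
    gm <- new("GenomeModel",
              sequences = Biostrings::DNAStringSet(seqs),
              genes = genes, refRE = refRE)
    validObject(gm)
    gm
  })
}

.placeGenes <- function(lens, fraction, lenRange) {
  if (fraction <= 0) {
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(lens),
                                                                  unname(lens))))
  }
  pieces <- list()
  gid <- 0L
  for (chr in names(lens)) {
    L <- lens[[chr]]
    target <- fraction * L
    glens <- integer()
    while (sum(glens) < target) {
      glens <- c(glens, sample(seq(lenRange[1], lenRange[2]), 1L))
    }
    # distribute the non-genic residue as gaps (min 200 bp) between genes
    n <- length(glens)
    residue <- L - sum(glens)
    if (residue < 200L * (n + 1L)) {        # genome too full; drop last gene
      glens <- glens[-n]
      n <- n - 1L
      residue <- L - sum(glens)
    }
    if (n == 0L) next
    free <- residue - 200L * (n + 1L)
    cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
    gaps <- 200L + diff(c(0L, cuts, free))
    starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(glens))[seq_len(n)] + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- gid + seq_len(n)
    pieces[[chr]] <- GenomicRanges::GRanges(
      factor(rep(chr, n), levels = names(lens)),
      IRanges::IRanges(start = starts, width = glens), strand = strand,
      gene_id = sprintf("gene%04d", ids))
    gid <- max(ids)
  }
  if (length(pieces) == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(lens),
                                                                  unname(lens))))
  gr <- do.call(c, unname(pieces))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- unname(lens)
  gr
}

.plantReferenceREs <- function(lens, genes, config) {
  out <- list()
  margin <- config@maxFragment + 200L
  taken <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(lens),
                                                                  unname(lens)))
  for (fam in config@families) {
    model <- familyModel(fam)
    tl <- length(model@terminus)
    n <- config@refCount[[fam]]
    if (n == 0L) next
    chrs <- sample(names(lens), n, replace = TRUE,
                   prob = as.numeric(lens) / sum(as.numeric(lens)))
    starts <- vapply(chrs, function(chr) {
      sample(seq(margin, lens[[chr]] - margin - tl), 1L)
    }, numeric(1))
    gr <- GenomicRanges::GRanges(
      factor(chrs, levels = names(lens)),
      IRanges::IRanges(start = starts, width = tl),
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = fam, re_id = sprintf("%s_ref%04d", fam, seq_len(n)))
    # re-draw copies that collide with already-placed copies
    for (tries in 1:20) {
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, taken, maxgap = 200L,
                                    ignore.strand = TRUE)))
      self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                          drop.redundant = TRUE,
                                          maxgap = 200L, ignore.strand = TRUE)
      hit <- unique(c(hit, S4Vectors::queryHits(self)))
      if (length(hit) == 0L) break
      for (i in hit) {
        chr <- sample(names(lens), 1L, prob = as.numeric(lens) / sum(as.numeric(lens)))
        gr[i] <- GenomicRanges::GRanges(
          factor(chr, levels = names(lens)),
          IRanges::IRanges(sample(seq(margin, lens[[chr]] - margin - tl), 1L),
                           width = tl),
          strand = sample(c("+", "-"), 1L),
          family = fam, re_id = gr$re_id[i])
      }
    }
    taken <- c(taken, GenomicRanges::granges(gr))
    out[[fam]] <- gr
  }
  if (length(out) == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(lens),
                                                                  unname(lens))))
  gr <- do.call(c, unname(out))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- unname(lens)
  sort(gr, ignore.strand = TRUE)
}

## Overwrite the genome sequence at each reference-RE locus with the family
## terminus. Junction side: right for (3p, +) and (5p, -), else left; the
## terminus (stored in read orientation) is written forward when the junction
## is at the right end, reverse-complemented otherwise.
.embedTermini <- function(seqs, refRE) {
  if (length(refRE) == 0L) return(seqs)
  for (i in seq_along(refRE)) {
    fam <- refRE$family[i]
    model <- familyModel(fam)
    term <- as.character(model@terminus)
    s <- as.character(GenomicRanges::strand(refRE)[i])
    right <- (model@flankedEnd == "3p") == (s == "+")
    ins <- if (right) term else revcompChar(term)
    chr <- as.character(GenomicRanges::seqnames(refRE)[i])
    substr(seqs[[chr]], GenomicRanges::start(refRE)[i],
           GenomicRanges::end(refRE)[i]) <- ins
  }
  seqs
}

#' Write a genome model to disk
#'
#' Emits the chromosome FASTA plus BED6 gene and reference-RE annotation.
#'
#' @param genome a \code{\link{GenomeModel}}
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genomeSequences(genome), fa)
  gbed <- file.path(dir, "genes.bed")
  rtracklayer::export(.asBedGR(geneAnnotation(genome), "gene_id"), gbed)
  rbed <- file.path(dir, "reference_re.bed")
  rtracklayer::export(.asBedGR(refREAnnotation(genome), "re_id"), rbed)
  invisible(c(fa, gbed, rbed))
}

.asBedGR <- function(gr, nameCol) {
  out <- GenomicRanges::granges(gr)
  if (length(gr)) {
    out$name <- if (nameCol %in% colnames(S4Vectors::mcols(gr)))
      S4Vectors::mcols(gr)[[nameCol]] else as.character(seq_along(gr))
    out$score <- 0L
  }
  out
}
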