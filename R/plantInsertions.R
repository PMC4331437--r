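#' Plant germline and somatic insertion events on a genome
#'
#' Generates the truth set of non-reference insertions: germline events
#' (carried by every tissue) and tissue-specific somatic events, whose count
#' per tissue and family is Poisson with mean \code{rate x genome Mb}.
#' Insertion points are 0-based inter-base coordinates sampled uniformly over
#' the genome, with gene intervals reweighted by the family's genic-targeting
#' multiplier. An event overlapping a gene is co-oriented with that gene with
#' the configured probability; intergenic events get a uniform random strand.
#' Events landing within 20 bp of one another are resampled (with a warning)
#' so every junction is individually resolvable. Reference-RE copies already
#' embedded in the genome are returned as reference-class events (carried by
#' every tissue), giving downstream digestion one uniform event list.
#'
#' @param genome a \code{\link{GenomeModel}}
#' @param config a \code{\link{SimulationConfig}}
#' @param seed integer seed
#' @return an \code{\link{InsertionSet}}; each event is a width-1 range at the
#'   base immediately right of the junction (0-based junction =
#'   \code{start - 1}), with metadata \code{family}, \code{class},
#'   \code{tissues}, \code{event_id}
#' @export
plantInsertions <- function(genome, config, seed) {
  stopifnot(is(genome, "GenomeModel"), is(config, "SimulationConfig"))
  withSeed(seed, {
    lens <- config@chromLengths
    mb <- sum(as.numeric(lens)) / 1e6
    pieces <- list()
    for (fam in config@families) {
      n_g <- config@germlineCount[[fam]]
      n_s <- stats::rpois(length(config@tissues),
                          config@somaticRate[, fam] * mb)
      names(n_s) <- config@tissues
      n <- n_g + sum(n_s)
      if (n == 0L) next
      pos <- .samplePositions(n, genome, config@genicMultiplier[[fam]])
      pos <- .resolveCollisions(pos, genome, config@genicMultiplier[[fam]],
                                minGap = 20L)
      strand <- .assignStrand(pos, genome, config@coOrientProb[[fam]])
      cls <- c(rep("germline", n_g), rep("somatic", sum(n_s)))
      tiss <- c(rep(list(config@tissues), n_g),
                rep(as.list(config@tissues), times = n_s))
      gr <- GenomicRanges::GRanges(
        factor(pos$chrom, levels = names(lens)),
        IRanges::IRanges(start = pos$pos0 + 1L, width = 1L),
        strand = strand,
        family = fam, class = cls,
        tissues = IRanges::CharacterList(tiss),
        event_id = sprintf("%s_%s%05d", fam,
                           ifelse(cls == "germline", "g", "s"), seq_len(n)))
      pieces[[fam]] <- gr
    }
    refRE <- refREAnnotation(genome)
    if (length(refRE)) {
      fe <- vapply(refRE$family, function(f) familyModel(f)@flankedEnd,
                   character(1))
      rj <- vapply(seq_along(refRE),
                   function(i) refJunctionPos0(refRE[i], fe[i]), numeric(1))
      grr <- GenomicRanges::GRanges(
        factor(as.character(GenomicRanges::seqnames(refRE)),
               levels = names(lens)),
        IRanges::IRanges(start = rj + 1L, width = 1L),
        strand = GenomicRanges::strand(refRE),
        family = refRE$family, class = "reference",
        tissues = IRanges::CharacterList(rep(list(config@tissues),
                                             length(refRE))),
        event_id = refRE$re_id)
      pieces[["__ref__"]] <- grr
    }
    ev <- if (length(pieces)) do.call(c, unname(pieces)) else
      GenomicRanges::GRanges(family = character(), class = character(),
                             tissues = IRanges::CharacterList(),
                             event_id = character())
    GenomeInfoDb::seqlevels(ev) <- names(lens)
    GenomeInfoDb::seqlengths(ev) <- unname(lens)
    out <- new("InsertionSet", events = ev)
    validObject(out)
    out
  })
}

## Sample n insertion points (0-based inter-base) with gene intervals
## reweighted by `mult`. Returns data.frame(chrom, pos0).
.samplePositions <- function(n, genome, mult) {
  lens <- Biostrings::width(genomeSequences(genome))
  names(lens) <- names(genomeSequences(genome))
  genes <- geneAnnotation(genome)
  G <- sum(as.numeric(GenomicRanges::width(genes)))
  Tot <- sum(as.numeric(lens))
  I <- Tot - G
  pGenic <- if (G > 0) (mult * G) / (mult * G + I) else 0
  inGene <- stats::runif(n) < pGenic
  chrom <- character(n)
  pos0 <- integer(n)
  ng <- sum(inGene)
  if (ng > 0) {
    gi <- sample.int(length(genes), ng, replace = TRUE,
                     prob = GenomicRanges::width(genes))
    off <- pmin(floor(stats::runif(ng) * GenomicRanges::width(genes)[gi]),
                GenomicRanges::width(genes)[gi] - 1L)
    chrom[inGene] <- as.character(GenomicRanges::seqnames(genes))[gi]
    pos0[inGene] <- GenomicRanges::start(genes)[gi] - 1L + off
  }
  ni <- n - ng
  if (ni > 0) {
    # complement of genes per chromosome
    inter <- GenomicRanges::gaps(GenomicRanges::reduce(genes, ignore.strand = TRUE))
    inter <- inter[GenomicRanges::strand(inter) == "*"]
    if (length(genes) == 0L) {
      inter <- GenomicRanges::GRanges(names(lens),
                                      IRanges::IRanges(1L, unname(lens)))
    }
    ii <- sample.int(length(inter), ni, replace = TRUE,
                     prob = GenomicRanges::width(inter))
    off <- pmin(floor(stats::runif(ni) * GenomicRanges::width(inter)[ii]),
                GenomicRanges::width(inter)[ii] - 1L)
    chrom[!inGene] <- as.character(GenomicRanges::seqnames(inter))[ii]
    pos0[!inGene] <- GenomicRanges::start(inter)[ii] - 1L + off
  }
  data.frame(chrom = chrom, pos0 = as.integer(pos0))
}

.resolveCollisions <- function(pos, genome, mult, minGap = 20L) {
  for (tries in 1:50) {
    bad <- logical(nrow(pos))
    sp <- split(seq_len(nrow(pos)), pos$chrom)
    for (idx in sp) {
      o <- idx[order(pos$pos0[idx])]
      close <- which(diff(pos$pos0[o]) < minGap)
      bad[o[close + 1L]] <- TRUE
    }
    if (!any(bad)) return(pos)
    if (tries == 1L)
      warning(sum(bad), " colliding insertion point(s) resampled")
    repl <- .samplePositions(sum(bad), genome, mult)
    pos$chrom[bad] <- repl$chrom
    pos$pos0[bad] <- repl$pos0
  }
  pos
}

.assignStrand <- function(pos, genome, coProb) {
  genes <- geneAnnotation(genome)
  gr <- GenomicRanges::GRanges(pos$chrom,
                               IRanges::IRanges(pos$pos0 + 1L, width = 1L))
  strand <- sample(c("+", "-"), nrow(pos), replace = TRUE)
  if (length(genes)) {
    hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE,
                                        select = "first")
    inGene <- !is.na(hits)
    if (any(inGene)) {
      gs <- as.character(GenomicRanges::strand(genes))[hits[inGene]]
      co <- stats::runif(sum(inGene)) < coProb
      strand[inGene] <- ifelse(co, gs, chartr("+-", "-+", gs))
    }
  }
  strand
}
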