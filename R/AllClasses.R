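#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet XStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' REFamilyModel: sequence model of a targeted retroelement subfamily
#'
#' Describes the junction-proximal terminus of an L1Hs- or AluYa5-like
#' subfamily as recovered by a suppression-PCR junction library: the terminus
#' consensus in *read orientation* (the sequence a junction read traverses
#' before crossing into genomic flank), the subfamily-diagnostic primer sites
#' it must contain, which element end abuts the recovered flank, and the
#' restriction enzymes used to fragment the genome for that family.
#'
#' @slot family character, family label ("L1Hs" or "AluYa5")
#' @slot terminus \code{DNAString}, terminus consensus in read orientation;
#'   its last base is the last element base before the junction
#' @slot primers named \code{DNAStringSet} of primer sites, each an exact
#'   substring of \code{terminus}
#' @slot nestedPrimer name of the primer whose 5' end defines where junction
#'   reads begin within \code{terminus}
#' @slot flankedEnd which element end abuts the recovered flank: \code{"3p"}
#'   (L1 3'-terminus libraries) or \code{"5p"} (Alu 5'-flank libraries)
#' @slot enzymes character vector of blunt-cutter recognition sequences
#'   (palindromic 4-cutters, cut mid-site)
#' @export
setClass("REFamilyModel", representation(
  family = "character",
  terminus = "DNAString",
  primers = "DNAStringSet",
  nestedPrimer = "character",
  flankedEnd = "character",
  enzymes = "character"
))

setValidity("REFamilyModel", function(object) {
  msg <- character()
  if (length(object@family) != 1L) msg <- c(msg, "family must be length 1")
  if (length(object@terminus) < 60L)
    msg <- c(msg, "terminus must be at least 60 bp")
  if (!object@flankedEnd %in% c("3p", "5p"))
    msg <- c(msg, "flankedEnd must be '3p' or '5p'")
  term <- as.character(object@terminus)
  for (i in seq_along(object@primers)) {
    p <- as.character(object@primers[[i]])
    if (!grepl(p, term, fixed = TRUE))
      msg <- c(msg, sprintf("primer '%s' is not a substring of the terminus",
                            names(object@primers)[i]))
  }
  if (!object@nestedPrimer %in% names(object@primers))
    msg <- c(msg, "nestedPrimer must name one of the primers")
  if (length(object@enzymes) < 1L ||
      !all(grepl("^[ACGT]+$", object@enzymes)))
    msg <- c(msg, "enzymes must be ACGT recognition sequences")
  if (length(msg)) msg else TRUE
})

#' GenomeModel: a toy reference genome with gene and reference-RE annotation
#'
#' Synthetic stand-in for a reference assembly: chromosome sequences, a
#' non-overlapping gene annotation (with strand, hence TSS), and the loci of
#' reference retroelement copies whose junction-proximal terminus sequence is
#' embedded in the chromosome sequence.
#'
#' @slot sequences \code{DNAStringSet}, one entry per chromosome
#' @slot genes \code{GRanges} with strand and \code{gene_id} metadata
#' @slot refRE \code{GRanges} of embedded reference-RE termini with
#'   \code{family} metadata; strand is the element strand
#' @export
setClass("GenomeModel", representation(
  sequences = "DNAStringSet",
  genes = "GRanges",
  refRE = "GRanges"
))

setValidity("GenomeModel", function(object) {
  msg <- character()
  len <- Biostrings::width(object@sequences)
  if (any(len < 50000L))
    msg <- c(msg, "all chromosomes must be at least 50 kb")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "chromosomes must have unique names")
  chk <- function(gr, what) {
    if (length(gr) == 0L) return(NULL)
    sn <- as.character(GenomicRanges::seqnames(gr))
    if (!all(sn %in% names(object@sequences)))
      return(sprintf("%s on unknown chromosome", what))
    L <- len[match(sn, names(object@sequences))]
    if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > L))
      return(sprintf("%s outside chromosome bounds", what))
    NULL
  }
  msg <- c(msg, chk(object@genes, "gene interval"), chk(object@refRE, "reference-RE interval"))
  if (length(object@genes) > 1L) {
    self <- GenomicRanges::findOverlaps(object@genes, drop.self = TRUE,
                                        ignore.strand = TRUE)
    if (length(self) > 0L) msg <- c(msg, "genes must not overlap one another")
  }
  if (length(object@refRE) && is.null(object@refRE$family))
    msg <- c(msg, "refRE must carry a 'family' column")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the junction-library simulation
#'
#' Holds every tunable of the synthetic five-tissue study: genome geometry,
#' per-tissue somatic insertion rates (events per Mb per family), germline and
#' reference-RE copy numbers, orientation and genic-targeting biases, read
#' geometry and depth, sequencing error rate, and the restriction enzymes used
#' per family. Defaults emulate the study conditions at toy genome scale; see
#' the package vignette for the rationale behind each value.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp)
#' @slot geneFraction fraction of the genome covered by genes
#' @slot geneLengthRange min/max gene length (bp)
#' @slot tissues tissue (library) names
#' @slot focalTissue tissue compared against the pooled rest in rate tests
#' @slot families families simulated ("L1Hs", "AluYa5")
#' @slot somaticRate tissue x family matrix of somatic event rates (per Mb)
#' @slot germlineCount named per-family count of non-reference germline events
#' @slot refCount named per-family count of reference-RE copies
#' @slot coOrientProb named per-family probability that a genic insertion is
#'   co-oriented with its gene
#' @slot genicMultiplier named per-family reweighting of insertion-point
#'   sampling toward gene intervals (1 = uniform)
#' @slot readLength read length in bp
#' @slot depthFactor multiplies every per-event read multiplicity (0 = no reads)
#' @slot germlineReadMean Poisson mean of per-library reads for germline and
#'   reference events
#' @slot somaticMultiplicity named numeric, categorical distribution of reads
#'   per somatic event (names are multiplicities)
#' @slot errorRate substitution error rate per sequenced base
#' @slot minFlank minimum informative flank length of an amplifiable fragment
#' @slot maxFragment suppression cap: maximum junction-to-cut-site distance
#' @slot enzymes named list, per-family recognition sequences
#' @slot adapter character, suppression-adapter sequence used for read-through
#' @export
setClass("SimulationConfig", representation(
  chromLengths = "integer",
  geneFraction = "numeric",
  geneLengthRange = "integer",
  tissues = "character",
  focalTissue = "character",
  families = "character",
  somaticRate = "matrix",
  germlineCount = "integer",
  refCount = "integer",
  coOrientProb = "numeric",
  genicMultiplier = "numeric",
  readLength = "integer",
  depthFactor = "numeric",
  germlineReadMean = "numeric",
  somaticMultiplicity = "numeric",
  errorRate = "numeric",
  minFlank = "integer",
  maxFragment = "integer",
  enzymes = "list",
  adapter = "character"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@chromLengths < 50000L))
    msg <- c(msg, "chromosome lengths must be >= 50 kb")
  if (object@geneFraction < 0 || object@geneFraction > 1)
    msg <- c(msg, "geneFraction must lie in [0, 1]")
  if (length(object@tissues) < 2L || anyDuplicated(object@tissues))
    msg <- c(msg, "need at least two distinct tissues")
  if (!object@focalTissue %in% object@tissues)
    msg <- c(msg, "focalTissue must be one of the tissues")
  if (!all(rownames(object@somaticRate) == object@tissues) ||
      !all(colnames(object@somaticRate) == object@families))
    msg <- c(msg, "somaticRate must be a tissues x families matrix")
  if (any(object@somaticRate < 0)) msg <- c(msg, "somatic rates must be >= 0")
  pr <- c(object@coOrientProb, object@errorRate)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@readLength < 50L) msg <- c(msg, "readLength must be >= 50")
  if (object@depthFactor < 0) msg <- c(msg, "depthFactor must be >= 0")
  if (abs(sum(object@somaticMultiplicity) - 1) > 1e-8 ||
      any(object@somaticMultiplicity < 0))
    msg <- c(msg, "somaticMultiplicity must be a probability distribution")
  if (!all(object@families %in% names(object@enzymes)))
    msg <- c(msg, "enzymes must be given for every simulated family")
  if (object@minFlank < 1L || object@maxFragment < object@minFlank)
    msg <- c(msg, "need 1 <= minFlank <= maxFragment")
  if (length(msg)) msg else TRUE
})

#' InsertionSet: planted or classified retroelement insertions
#'
#' A thin wrapper around a \code{GRanges} of single-base junction loci. Each
#' record carries \code{family}, \code{class} (\code{reference},
#' \code{germline}, \code{somatic}, or for classified call sets additionally
#' \code{ambiguous_multi_tissue}) and a \code{tissues} \code{CharacterList} of
#' the carrying libraries. Positions are 1-based inside the \code{GRanges};
#' the equivalent 0-based junction coordinate is \code{start - 1}.
#'
#' @slot events \code{GRanges} with metadata columns \code{family},
#'   \code{class}, \code{tissues}
#' @export
setClass("InsertionSet", representation(events = "GRanges"))

setValidity("InsertionSet", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@events)
  need <- c("family", "class", "tissues")
  if (!all(need %in% colnames(mc)))
    return(sprintf("events must carry columns: %s", paste(need, collapse = ", ")))
  ok <- c("reference", "germline", "somatic", "ambiguous_multi_tissue")
  if (!all(mc$class %in% ok))
    msg <- c(msg, "unknown class label")
  nt <- lengths(mc$tissues)
  if (any(mc$class == "somatic" & nt != 1L))
    msg <- c(msg, "somatic events must carry exactly one tissue")
  if (length(msg)) msg else TRUE
})

#' CallSet: deduplicated insertion calls of one library
#'
#' Per-library junction calls after collapsing reads that map within a small
#' window: single-base junction loci (strand = inferred element strand) with
#' supporting read counts and a representative flank sequence.
#'
#' @slot tissue library tissue
#' @slot family targeted family
#' @slot calls \code{GRanges} (width-1) with metadata \code{count},
#'   \code{flank}
#' @slot tallies named numeric bookkeeping (reads in, accepted, mapped, ...)
#' @export
setClass("CallSet", representation(
  tissue = "character",
  family = "character",
  calls = "GRanges",
  tallies = "numeric"
))

setValidity("CallSet", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@calls)
  if (!all(c("count", "flank") %in% colnames(mc)))
    return("calls must carry 'count' and 'flank' columns")
  if (length(object@calls)) {
    if (any(mc$count < 1L)) msg <- c(msg, "read counts must be >= 1")
    key <- paste(GenomicRanges::seqnames(object@calls),
                 GenomicRanges::start(object@calls),
                 GenomicRanges::strand(object@calls))
    if (anyDuplicated(key))
      msg <- c(msg, "call positions must be unique per chromosome and strand")
    if (any(as.character(GenomicRanges::strand(object@calls)) == "*"))
      msg <- c(msg, "calls must be stranded")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationIndex: strand-aware gene + promoter interval index
#'
#' Gene bodies plus their promoter windows (5,000 bp immediately upstream of
#' each TSS on the gene's strand, clipped at chromosome bounds), queryable
#' independently by point overlap.
#'
#' @slot genes \code{GRanges} with strand and \code{gene_id}
#' @slot promoters \code{GRanges} with \code{gene_id} and \code{gene_strand}
#' @slot upstream promoter window size (bp)
#' @export
setClass("AnnotationIndex", representation(
  genes = "GRanges",
  promoters = "GRanges",
  upstream = "integer"
))

setValidity("AnnotationIndex", function(object) {
  if (length(object@genes) &&
      any(as.character(GenomicRanges::strand(object@genes)) == "*"))
    return("gene records must be stranded")
  if (length(object@promoters) &&
      !all(c("gene_id", "gene_strand") %in%
           colnames(S4Vectors::mcols(object@promoters))))
    return("promoters must carry gene_id and gene_strand")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "REFamilyModel", function(object) {
  cat("REFamilyModel:", object@family, "\n")
  cat("  terminus:", length(object@terminus), "bp (read orientation),",
      "flanked end:", object@flankedEnd, "\n")
  cat("  primers:", paste(names(object@primers), collapse = ", "),
      "(nested:", paste0(object@nestedPrimer, ")"), "\n")
  cat("  enzymes:", paste(object@enzymes, collapse = ", "), "\n")
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@sequences), "chromosome(s),",
      sum(Biostrings::width(object@sequences)), "bp total\n")
  cat("  genes:", length(object@genes),
      sprintf("(%.1f%% of genome)", 100 * sum(GenomicRanges::width(object@genes)) /
                sum(Biostrings::width(object@sequences))), "\n")
  cat("  reference REs:", length(object@refRE), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", sum(object@chromLengths), "bp genome,",
      length(object@tissues), "tissues,",
      paste(object@families, collapse = "+"), "\n")
  cat("  somatic rates (events/Mb):\n")
  print(object@somaticRate)
  cat("  read length:", object@readLength, "bp; error rate:", object@errorRate, "\n")
})

setMethod("show", "InsertionSet", function(object) {
  cat("InsertionSet with", length(object@events), "events\n")
  if (length(object@events))
    print(table(S4Vectors::mcols(object@events)$class))
})

setMethod("show", "CallSet", function(object) {
  cat("CallSet:", object@tissue, "/", object@family, "-",
      length(object@calls), "calls,",
      sum(S4Vectors::mcols(object@calls)$count), "supporting reads\n")
})

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex:", length(object@genes), "genes,",
      length(object@promoters), "promoter windows (",
      object@upstream, "bp upstream )\n")
})
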