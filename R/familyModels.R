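## Built-in subfamily models.
##
## The terminus consensus strings are synthetic stand-ins for the true
## junction-proximal subfamily consensus; what matters for the simulation and
## the caller is that (i) they embed the genuine subfamily-diagnostic primer
## sequences used for library construction, (ii) the segment between the
## nested primer and the junction carries no recognition site of the family's
## restriction enzymes (so amplifiable fragments are not systematically cut
## between primer and junction), and (iii) they are >= 60 bp.

# enzyme recognition sequences (all palindromic blunt 4-cutters, cut mid-site)
.ENZYMES <- c(AluI = "AGCT", HaeIII = "GGCC", RsaI = "GTAC")

.L1_PRIMERS <- c(
  outer  = "GAGATATACCTAATGCTAGATGACAC",
  nested = "GCACATGTACCCTAAAACTTAGAGTA"
)

.ALU_PRIMERS <- c(
  outer  = "TCACCGTTTTAGCCGGGA",
  middle = "AGGCGTGAGCCACCGCGC",
  nested = "GAGCCACCGCGCCCGGC"
)

.ADAPTER <- "TGTAGCGTGAAGACGACAGAAAGGGCGTGGTGCGGAGGGCGGT"

#' Built-in retroelement subfamily models
#'
#' \code{l1hsFamilyModel()} models an L1Hs-style library built from L1
#' 3'-termini and their downstream flanks, digested with AluI + HaeIII.
#' \code{aluYa5FamilyModel()} models an AluYa5-style library built from Alu
#' 5'-flanking sequences (avoiding the 3' polyA tail), digested with
#' AluI + RsaI. Both embed the subfamily-diagnostic primer sites actually used
#' for suppression-PCR library construction inside a synthetic terminus
#' consensus, stored in read orientation (the junction is immediately after
#' the terminus's last base).
#'
#' @return a \code{\link{REFamilyModel}}
#' @examples
#' l1hsFamilyModel()
#' @export
l1hsFamilyModel <- function() {
  terminus <- paste0(
    "TTCAATTACAGTTATCGTAG",        # filler (no AluI/HaeIII site)
    .L1_PRIMERS[["outer"]],
    "TTCAAT",
    .L1_PRIMERS[["nested"]],
    "CATTTAAT"                      # element tail before the junction
  )
  new("REFamilyModel",
      family = "L1Hs",
      terminus = Biostrings::DNAString(terminus),
      primers = Biostrings::DNAStringSet(.L1_PRIMERS),
      nestedPrimer = "nested",
      flankedEnd = "3p",
      enzymes = unname(.ENZYMES[c("AluI", "HaeIII")]))
}

#' @rdname l1hsFamilyModel
#' @export
aluYa5FamilyModel <- function() {
  terminus <- paste0(
    "CTTGAACCCAGGAGGCGGAG",        # filler (no AluI/RsaI site)
    .ALU_PRIMERS[["outer"]],
    "TTGCA",
    .ALU_PRIMERS[["middle"]],      # nested primer is a suffix-overlapping site
    "CCGGC",
    "TTACTAAAT"                    # element tail before the junction
  )
  new("REFamilyModel",
      family = "AluYa5",
      terminus = Biostrings::DNAString(terminus),
      primers = Biostrings::DNAStringSet(.ALU_PRIMERS),
      nestedPrimer = "nested",
      flankedEnd = "5p",
      enzymes = unname(.ENZYMES[c("AluI", "RsaI")]))
}

#' @rdname l1hsFamilyModel
#' @param family family label, \code{"L1Hs"} or \code{"AluYa5"}
#' @export
familyModel <- function(family) {
  switch(family,
         L1Hs = l1hsFamilyModel(),
         AluYa5 = aluYa5FamilyModel(),
         stop("unknown family: ", family))
}

## Read-start segment of the terminus: from the 5' end of the nested primer
## through the junction. Every junction read begins with this.
terminusFromPrimer <- function(model) {
  term <- as.character(model@terminus)
  p <- as.character(model@primers[[model@nestedPrimer]])
  o <- regexpr(p, term, fixed = TRUE)[1]
  substring(term, o)
}

## Offset (0-based) of the nested primer within the terminus.
nestedPrimerOffset <- function(model) {
  term <- as.character(model@terminus)
  p <- as.character(model@primers[[model@nestedPrimer]])
  as.integer(regexpr(p, term, fixed = TRUE)[1]) - 1L
}
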