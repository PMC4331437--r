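#' Construct a simulation configuration
#'
#' Builds a validated \code{\link{SimulationConfig}}. Defaults reproduce the
#' study conditions at toy scale: a 3 x 1 Mb genome, five libraries
#' (cerebellum, frontal cortex, SVZ, dentate gyrus, myocardium), both
#' families, a somatic base rate of 50 events/Mb with the dentate gyrus L1
#' rate at 1.5x the others (and the dentate-gyrus/frontal-cortex Alu rates
#' elevated 2x/1.6x), germline and reference copy numbers scaled to the toy
#' genome, and the restriction enzymes used for each family (AluI + HaeIII for
#' L1, AluI + RsaI for Alu). See the vignette for the rationale behind every
#' default.
#'
#' @param chromLengths named integer vector of chromosome lengths (>= 50 kb)
#' @param geneFraction fraction of the genome covered by genes
#' @param geneLengthRange length-2 integer, min/max gene length
#' @param tissues library names
#' @param focalTissue tissue compared against the pooled rest
#' @param families subset of \code{c("L1Hs", "AluYa5")}
#' @param somaticRate tissue x family matrix of somatic rates (events per Mb),
#'   or \code{NULL} for the defaults described above
#' @param germlineCount named per-family germline event counts
#' @param refCount named per-family reference-RE copy numbers
#' @param coOrientProb named per-family genic co-orientation probabilities
#' @param genicMultiplier named per-family genic targeting multipliers
#' @param readLength read length (bp)
#' @param depthFactor global multiplier on per-event read multiplicities
#' @param germlineReadMean Poisson mean of per-library germline/reference reads
#' @param somaticMultiplicity categorical distribution of somatic read counts
#' @param errorRate per-base substitution error rate
#' @param minFlank minimum amplifiable flank (bp)
#' @param maxFragment suppression cap on junction-to-cut distance (bp)
#' @param enzymes named list of per-family recognition sequences
#' @param adapter suppression-adapter sequence
#' @return a \code{SimulationConfig}
#' @examples
#' cfg <- simulationConfig(families = "L1Hs")
#' cfg
#' @export
simulationConfig <- function(
    chromLengths = c(chr1 = 1000000L, chr2 = 1000000L, chr3 = 1000000L),
    geneFraction = 0.40,
    geneLengthRange = c(10000L, 60000L),
    tissues = c("cerebellum", "frontal_cortex", "SVZ", "dentate_gyrus",
                "myocardium"),
    focalTissue = "dentate_gyrus",
    families = c("L1Hs", "AluYa5"),
    somaticRate = NULL,
    germlineCount = c(L1Hs = 30L, AluYa5 = 30L),
    refCount = c(L1Hs = 60L, AluYa5 = 150L),
    coOrientProb = c(L1Hs = 0.41, AluYa5 = 0.48),
    genicMultiplier = c(L1Hs = 1.25, AluYa5 = 1.0),
    readLength = 101L,
    depthFactor = 1,
    germlineReadMean = 12,
    somaticMultiplicity = c("1" = 0.85, "2" = 0.08, "3" = 0.04,
                            "4" = 0.02, "5" = 0.01),
    errorRate = 0.001,
    minFlank = 25L,
    maxFragment = 3000L,
    enzymes = list(L1Hs = c("AGCT", "GGCC"), AluYa5 = c("AGCT", "GTAC")),
    adapter = .ADAPTER) {

  if (is.null(somaticRate)) {
    somaticRate <- matrix(50, nrow = length(tissues), ncol = length(families),
                          dimnames = list(tissues, families))
    if ("dentate_gyrus" %in% tissues) {
      if ("L1Hs" %in% families) somaticRate["dentate_gyrus", "L1Hs"] <- 75
      if ("AluYa5" %in% families) somaticRate["dentate_gyrus", "AluYa5"] <- 100
    }
    if ("frontal_cortex" %in% tissues && "AluYa5" %in% families)
      somaticRate["frontal_cortex", "AluYa5"] <- 80
  }
  if (is.null(rownames(somaticRate)) || is.null(colnames(somaticRate)))
    dimnames(somaticRate) <- list(tissues, families)

  cl <- chromLengths
  storage.mode(cl) <- "integer"
  if (is.null(names(cl)))
    names(cl) <- paste0("chr", seq_along(cl))
  if (any(cl < 50000L))
    stop("all chromosome lengths must be at least 50 kb")

  new("SimulationConfig",
      chromLengths = cl,
      geneFraction = geneFraction,
      geneLengthRange = as.integer(geneLengthRange),
      tissues = tissues,
      focalTissue = focalTissue,
      families = families,
      somaticRate = somaticRate[tissues, families, drop = FALSE],
      germlineCount = vapply(families, function(f) as.integer(germlineCount[[f]]),
                             integer(1)),
      refCount = vapply(families, function(f) as.integer(refCount[[f]]),
                        integer(1)),
      coOrientProb = vapply(families, function(f) coOrientProb[[f]], numeric(1)),
      genicMultiplier = vapply(families, function(f) genicMultiplier[[f]],
                               numeric(1)),
      readLength = as.integer(readLength),
      depthFactor = depthFactor,
      germlineReadMean = germlineReadMean,
      somaticMultiplicity = somaticMultiplicity,
      errorRate = errorRate,
      minFlank = as.integer(minFlank),
      maxFragment = as.integer(maxFragment),
      enzymes = enzymes[families],
      adapter = adapter)
}
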