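#' Emit junction-library read pairs from digested fragments
#'
#' For every amplifiable fragment and every tissue carrying its event, draws a
#' read multiplicity (categorical \code{somaticMultiplicity} for somatic
#' events; Poisson \code{germlineReadMean} for germline and reference events,
#' both scaled by \code{depthFactor}) and emits that many read pairs. Read 1
#' starts at the nested primer within the element terminus, crosses the
#' junction into the genomic flank and, on short fragments, reads through into
#' the suppression adapter. Read 2 starts from the adapter end of the fragment
#' and reads inward. Substitution errors are injected at \code{errorRate};
#' qualities are a constant Q40.
#'
#' @param fragments result of \code{\link{digestEvents}} (the \code{fragments}
#'   DataFrame, or the whole list)
#' @param config a \code{\link{SimulationConfig}}
#' @param seed integer seed
#' @return a list with \code{reads} (a \code{DataFrame}: \code{tissue},
#'   \code{family}, \code{read_id}, \code{event_id}, \code{read1},
#'   \code{read2}) and \code{tallies} (reads emitted per tissue)
#' @export
emitReads <- function(fragments, config, seed) {
  if (is.list(fragments) && !is(fragments, "DataFrame"))
    fragments <- fragments$fragments
  withSeed(seed, {
    n <- nrow(fragments)
    if (n == 0L || config@depthFactor == 0) {
      reads <- S4Vectors::DataFrame(tissue = character(), family = character(),
                                    read_id = character(), event_id = character(),
                                    read1 = character(), read2 = character())
      return(list(reads = reads,
                  tallies = stats::setNames(integer(length(config@tissues)),
                                            config@tissues)))
    }
    fam <- fragments$family[1]
    model <- familyModel(fam)
    sT <- terminusFromPrimer(model)
    rl <- config@readLength
    adapterPad <- paste(rep(config@adapter, ceiling(rl / nchar(config@adapter)) + 1L),
                        collapse = "")

    # expand fragment x carrying tissue
    nt <- lengths(fragments$tissues)
    idx <- rep.int(seq_len(n), nt)
    tissue <- unlist(fragments$tissues, use.names = FALSE)
    cls <- fragments$class[idx]

    mult <- integer(length(idx))
    isSom <- cls == "somatic"
    if (any(isSom)) {
      vals <- as.integer(names(config@somaticMultiplicity))
      mult[isSom] <- sample(vals, sum(isSom), replace = TRUE,
                            prob = config@somaticMultiplicity)
    }
    if (any(!isSom))
      mult[!isSom] <- stats::rpois(sum(!isSom), config@germlineReadMean)
    mult <- as.integer(round(mult * config@depthFactor))

    ridx <- rep.int(seq_along(idx), mult)       # one entry per read pair
    if (length(ridx) == 0L) {
      reads <- S4Vectors::DataFrame(tissue = character(), family = character(),
                                    read_id = character(), event_id = character(),
                                    read1 = character(), read2 = character())
      return(list(reads = reads,
                  tallies = stats::setNames(integer(length(config@tissues)),
                                            config@tissues)))
    }
    fi <- idx[ridx]
    template1 <- substr(paste0(sT, fragments$flank_seq, adapterPad), 1L, rl)
    frag2 <- paste0(sT, fragments$flank_seq)
    template2 <- substr(paste0(revcompChar(frag2), adapterPad), 1L, rl)

    r1 <- injectErrors(template1[fi], config@errorRate)
    r2 <- injectErrors(template2[fi], config@errorRate)
    tiss <- tissue[ridx]
    within <- stats::ave(seq_along(ridx), ridx, FUN = seq_along)
    reads <- S4Vectors::DataFrame(
      tissue = tiss,
      family = fam,
      read_id = sprintf("%s:%s:%s:r%d", tiss, fam, fragments$event_id[fi], within),
      event_id = fragments$event_id[fi],
      read1 = r1, read2 = r2)
    tal <- stats::setNames(integer(length(config@tissues)), config@tissues)
    tt <- table(tiss)
    tal[names(tt)] <- as.integer(tt)
    list(reads = reads, tallies = tal)
  })
}

#' Simulate a full multi-tissue junction-library experiment
#'
#' Runs \code{\link{buildGenome}}, \code{\link{plantInsertions}},
#' \code{\link{digestEvents}} and \code{\link{emitReads}} for every configured
#' family, and optionally writes genome FASTA, annotation BED, per-library
#' paired FASTQ, a truth BED of all planted events, and a YAML echo of the
#' configuration. All randomness derives from \code{seed}; identical seed and
#' configuration give byte-identical outputs.
#'
#' @param config a \code{\link{SimulationConfig}}
#' @param seed integer seed
#' @param outDir output directory, or \code{NULL} to keep everything in memory
#' @return a list: \code{genome}, \code{events} (\code{InsertionSet}),
#'   per-family \code{fragments}, \code{reads}, \code{tallies}, and the file
#'   paths written (if any)
#' @export
simulateLibraries <- function(config, seed, outDir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  seeds <- subSeeds(seed, 2L + 2L * length(config@families))
  genome <- buildGenome(config, seeds[1])
  events <- plantInsertions(genome, config, seeds[2])
  fragments <- list()
  reads <- list()
  tallies <- list()
  k <- 2L
  for (fam in config@families) {
    dg <- digestEvents(genome, events, fam, config)
    em <- emitReads(dg$fragments, config, seeds[k + 1L])
    fragments[[fam]] <- dg$fragments
    reads[[fam]] <- em$reads
    tallies[[fam]] <- c(dg$tallies, emitted = sum(em$tallies))
    k <- k + 2L
  }
  out <- list(genome = genome, events = events, fragments = fragments,
              reads = reads, tallies = tallies, config = config, seed = seed)
  if (!is.null(outDir)) out$paths <- writeSimulation(out, outDir)
  out
}

#' Write simulation outputs to disk
#'
#' @param sim result of \code{\link{simulateLibraries}}
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeGenome(sim$genome, dir)
  cfg <- sim$config
  for (fam in names(sim$reads)) {
    rd <- sim$reads[[fam]]
    for (tis in cfg@tissues) {
      sel <- rd$tissue == tis
      for (mate in 1:2) {
        fq <- file.path(dir, sprintf("%s_%s_R%d.fastq", tis, fam, mate))
        sr <- Biostrings::DNAStringSet(rd[[paste0("read", mate)]][sel])
        names(sr) <- rd$read_id[sel]
        .writeConstantQualFastq(sr, fq)
        paths <- c(paths, fq)
      }
    }
  }
  truth <- file.path(dir, "truth.bed")
  writeTruthBed(sim, truth)
  yml <- file.path(dir, "config.yaml")
  yaml::write_yaml(.configAsList(cfg), yml)
  invisible(c(paths, truth, yml))
}

.writeConstantQualFastq <- function(dss, path, qual = "I") {
  if (length(dss) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  q <- Biostrings::BStringSet(vapply(Biostrings::width(dss), function(w)
    paste(rep(qual, w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write the truth BED of planted events
#'
#' BED6+3: chrom, 0-based half-open junction interval, name = family,
#' score = total emitted read pairs for the event, strand, then class, tissue
#' set (comma-joined) and family again.
#'
#' @param sim result of \code{\link{simulateLibraries}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeTruthBed <- function(sim, path) {
  ev <- insertionEvents(sim$events)
  counts <- integer(length(ev))
  names(counts) <- ev$event_id
  for (fam in names(sim$reads)) {
    tt <- table(sim$reads[[fam]]$event_id)
    counts[names(tt)] <- as.integer(tt)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ev)),
    start = GenomicRanges::start(ev) - 1L,
    end = GenomicRanges::start(ev),
    name = ev$family,
    score = unname(counts),
    strand = as.character(GenomicRanges::strand(ev)),
    class = ev$class,
    tissues = vapply(ev$tissues, paste, character(1), collapse = ","),
    family = ev$family)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.configAsList <- function(cfg) {
  list(chromLengths = as.list(cfg@chromLengths),
       geneFraction = cfg@geneFraction,
       geneLengthRange = cfg@geneLengthRange,
       tissues = cfg@tissues,
       focalTissue = cfg@focalTissue,
       families = cfg@families,
       somaticRate = apply(cfg@somaticRate, 1, as.list, simplify = FALSE),
       germlineCount = as.list(cfg@germlineCount),
       refCount = as.list(cfg@refCount),
       coOrientProb = as.list(cfg@coOrientProb),
       genicMultiplier = as.list(cfg@genicMultiplier),
       readLength = cfg@readLength,
       depthFactor = cfg@depthFactor,
       germlineReadMean = cfg@germlineReadMean,
       somaticMultiplicity = as.list(cfg@somaticMultiplicity),
       errorRate = cfg@errorRate,
       minFlank = cfg@minFlank,
       maxFragment = cfg@maxFragment,
       enzymes = cfg@enzymes,
       adapter = cfg@adapter)
}
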