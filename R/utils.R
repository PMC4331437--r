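## Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Printed tables in this field round 0.5 up, whereas \code{round()} rounds to
#' even; all printed-precision comparisons in the package go through this.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate expr with a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of sub-seeds from one master seed, kept below 2^31.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Reverse complement of a plain character vector.
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming mismatches between equal-length strings a (vector) and b (scalar).
mismatchToRef <- function(a, b) {
  if (length(a) == 0L) return(integer())
  stopifnot(all(nchar(a) == nchar(b)))
  bm <- strsplit(b, "", fixed = TRUE)[[1]]
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = nchar(b))
  as.integer(colSums(am != bm))
}

## Pairwise Hamming mismatches between equal-length string vectors a and b.
mismatchPairwise <- function(a, b) {
  stopifnot(length(a) == length(b), all(nchar(a) == nchar(b)))
  if (length(a) == 0L) return(integer())
  out <- integer(length(a))
  for (w in unique(nchar(a))) {
    i <- which(nchar(a) == w)
    am <- matrix(unlist(strsplit(a[i], "", fixed = TRUE), use.names = FALSE), nrow = w)
    bm <- matrix(unlist(strsplit(b[i], "", fixed = TRUE), use.names = FALSE), nrow = w)
    out[i] <- as.integer(colSums(am != bm))
  }
  out
}

## Single-linkage 1D clustering: positions (sorted or not) chain-merge while
## consecutive gaps are <= window. Returns integer cluster ids in input order.
chainCluster <- function(pos, window) {
  if (length(pos) == 0L) return(integer())
  o <- order(pos)
  p <- pos[o]
  brk <- c(TRUE, diff(p) > window)
  id <- cumsum(brk)
  out <- integer(length(pos))
  out[o] <- id
  out
}

## Modal value; ties broken toward the smallest. Optionally weighted.
modalValue <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  tab <- rowsum(w, x)
  vals <- as.numeric(rownames(tab))
  vals[which.max(tab[, 1])]  # which.max takes the first (= smallest) on ties
}

## Inject substitution errors at rate `rate` into a character vector of reads.
injectErrors <- function(reads, rate) {
  if (length(reads) == 0L || rate <= 0) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # replace with one of the three other bases, uniformly
    cur <- match(flat[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    flat[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)),
         paste, character(1), collapse = "")
}

## 0-based junction coordinate of a reference-RE terminus interval:
## right end for (3p, +) and (5p, -); left end otherwise.
refJunctionPos0 <- function(gr, flankedEnd) {
  s <- as.character(GenomicRanges::strand(gr))
  right <- (flankedEnd == "3p") == (s == "+")
  ifelse(right, GenomicRanges::end(gr), GenomicRanges::start(gr) - 1L)
}

## Write a data.frame as TSV without quoting; deterministic formatting.
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
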