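## The four test families: exact conditional Poisson rate comparison,
## Monte-Carlo genomic-distribution null, chi-square overdispersion test on
## grouped proportions, and exact binomial orientation tests. All exact
## two-sided p-values use the minimum-likelihood convention: sum the
## probabilities of every outcome no more likely than the observed one.

## two-sided minlike binomial p-value, own construction (stats::binom.test is
## kept as an independent oracle in the test suite)
.minlikeBinomP <- function(x, size, prob, relErr = 1 + 1e-7) {
  if (size == 0L) return(1)
  d <- stats::dbinom(0:size, size, prob)
  keep <- d <= d[x + 1L] * relErr
  if (all(keep)) return(1)      # observed the modal outcome: complete sum
  min(1, sum(d[keep]))
}

#' Exact conditional two-sample Poisson rate test
#'
#' Compares two event rates \code{x1/n1} and \code{x2/n2} (events over
#' exposure, e.g. somatic-representing reads over total library reads) with
#' the exact conditional construction: given the total \code{T = x1 + x2},
#' \code{x1} is Binomial(\code{T}, \code{n1/(n1+n2)}) under the null of equal
#' rates; the two-sided p-value sums all outcome probabilities no larger than
#' that of the observed outcome. Symmetric in the two groups. \code{x1 = x2 =
#' 0} gives p = 1.
#'
#' @param x1,x2 event counts (>= 0)
#' @param n1,n2 exposures (> 0)
#' @return an object of class \code{htest}
#' @examples
#' poissonRateTest(1376, 11978540, 1353, 10921385)  # p = 0.0506
#' @export
poissonRateTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0)
  T <- x1 + x2
  p0 <- n1 / (n1 + n2)
  p <- .minlikeBinomP(x1, T, p0)
  rr <- if (x2 > 0) (x1 / n1) / (x2 / n2) else NA_real_
  structure(list(
    statistic = c(count1 = x1),
    parameter = c("conditional total" = T, "null proportion" = p0),
    p.value = p,
    estimate = c("rate ratio" = rr),
    null.value = c("rate ratio" = 1),
    alternative = "two.sided",
    method = "Exact conditional two-sample Poisson rate test (minlike)",
    data.name = sprintf("%g/%g vs %g/%g", x1, n1, x2, n2)),
    class = "htest")
}

#' One library against the pooled rest
#'
#' Runs \code{\link{poissonRateTest}} of library \code{i}'s rate against the
#' element-wise pooled counts and exposures of all other libraries.
#'
#' @param x numeric vector of event counts per library
#' @param n numeric vector of exposures per library
#' @param i index (or name) of the focal library
#' @return an object of class \code{htest}
#' @export
rateVsPooledTest <- function(x, n, i) {
  stopifnot(length(x) == length(n), length(x) >= 2L)
  if (is.character(i)) i <- match(i, names(x))
  poissonRateTest(x[[i]], n[[i]], sum(x[-i]), sum(n[-i]))
}

#' All pairwise exact Poisson rate tests
#'
#' @param x,n per-library counts and exposures (named)
#' @return data.frame of library pairs with two-sided p-values
#' @export
pairwiseRateTests <- function(x, n) {
  stopifnot(length(x) == length(n))
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  cmb <- utils::combn(length(x), 2)
  out <- apply(cmb, 2, function(ij) {
    ht <- poissonRateTest(x[[ij[1]]], n[[ij[1]]], x[[ij[2]]], n[[ij[2]]])
    data.frame(lib1 = nm[ij[1]], lib2 = nm[ij[2]], p.value = ht$p.value)
  })
  do.call(rbind, out)
}

#' Exact binomial orientation-bias test
#'
#' Tests whether co-oriented insertions (element strand equal to the strand
#' of the overlapped gene) occur at a proportion different from 0.5, with an
#' exact binomial two-sided (minimum-likelihood) p-value.
#'
#' @param co number of co-oriented insertions
#' @param total total insertions in the compartment
#' @return an object of class \code{htest}
#' @examples
#' orientationTest(691, 1465)   # p = 0.032
#' @export
orientationTest <- function(co, total) {
  stopifnot(total >= 1, co >= 0, co <= total)
  p <- .minlikeBinomP(co, total, 0.5)
  structure(list(
    statistic = c("co-oriented" = co),
    parameter = c(total = total, "null proportion" = 0.5),
    p.value = p,
    estimate = c("co-oriented fraction" = co / total),
    null.value = c("co-oriented fraction" = 0.5),
    alternative = "two.sided",
    method = "Exact binomial orientation test (minlike)",
    data.name = sprintf("%d of %d co-oriented", co, total)),
    class = "htest")
}

#' Overdispersion test for grouped proportions
#'
#' Tests whether per-group success proportions \code{x_i/n_i} vary more than
#' binomial sampling allows, with the chi-square statistic
#' \deqn{D = \sum_i (x_i - n_i \bar p)^2 / (n_i \bar p (1 - \bar p)),}
#' where \eqn{\bar p = \sum x / \sum n}, on \code{k - 1} degrees of freedom
#' (upper tail). Large p-values indicate proportions as homogeneous as, or
#' more homogeneous than, binomial variation.
#'
#' @param x successes per group
#' @param n trials per group
#' @return an object of class \code{htest}
#' @examples
#' overdispersionTest(c(3, 7), c(10, 10))   # D = 3.2
#' @export
overdispersionTest <- function(x, n) {
  stopifnot(length(x) == length(n), length(x) >= 2L, all(n > 0), all(x >= 0),
            all(x <= n))
  k <- length(x)
  pbar <- sum(x) / sum(n)
  if (pbar == 0 || pbar == 1) {
    D <- 0
  } else {
    D <- sum((x - n * pbar)^2 / (n * pbar * (1 - pbar)))
  }
  p <- stats::pchisq(D, df = k - 1, lower.tail = FALSE)
  structure(list(
    statistic = c(D = D),
    parameter = c(df = k - 1, "pooled proportion" = pbar),
    p.value = p,
    alternative = "overdispersed (upper tail)",
    method = "Chi-square overdispersion test for grouped proportions",
    data.name = sprintf("%d groups, %g/%g pooled", k, sum(x), sum(n))),
    class = "htest")
}

#' Monte-Carlo genomic-distribution test
#'
#' Draws \code{R} simulated coordinate sets of the same size \code{N} as the
#' observed insertion set, uniformly over the genome (chromosome chosen
#' proportional to its length, offset uniform), counts genic and promoter
#' hits per replicate (genic precedence, as in
#' \code{\link{locateInsertions}}), and reports empirical enrichment and
#' depletion p-values with the add-one estimator
#' \code{(1 + #extreme)/(R + 1)}, plus the simulated mean and SD.
#'
#' @param N number of insertions in the observed set
#' @param index an \code{\link{AnnotationIndex}}
#' @param genomeLengths named numeric of chromosome lengths (or a
#'   \code{\link{GenomeModel}})
#' @param observedGenic observed genic count
#' @param observedPromoter observed promoter count
#' @param R number of replicates
#' @param seed integer seed (recorded in the result)
#' @return list with components \code{genic} and \code{promoter}, each of
#'   class \code{htest} with \code{p.value} (enrichment),
#'   \code{p.deplete}, \code{sim.mean}, \code{sim.sd}, \code{replicates},
#'   \code{seed}
#' @export
monteCarloDistributionTest <- function(N, index, genomeLengths,
                                       observedGenic, observedPromoter,
                                       R = 1000L, seed = 1L) {
  stopifnot(N >= 1L, R >= 1L)
  if (R < 100L) warning("fewer than 100 replicates gives unstable p-values")
  if (is(genomeLengths, "GenomeModel")) {
    gl <- Biostrings::width(genomeSequences(genomeLengths))
    names(gl) <- names(genomeSequences(genomeLengths))
    genomeLengths <- gl
  }
  genes <- GenomicRanges::reduce(geneAnnotation(index), ignore.strand = TRUE)
  prom <- GenomicRanges::reduce(promoterRanges(index), ignore.strand = TRUE)
  counts <- withSeed(seed, {
    tot <- sum(as.numeric(genomeLengths))
    gCount <- integer(R)
    pCount <- integer(R)
    chunk <- max(1L, min(R, floor(2e6 / N)))
    done <- 0L
    while (done < R) {
      r <- min(chunk, R - done)
      m <- N * r
      chr <- sample(names(genomeLengths), m, replace = TRUE,
                    prob = as.numeric(genomeLengths) / tot)
      off <- pmin(floor(stats::runif(m) * genomeLengths[chr]),
                  genomeLengths[chr] - 1)   # 0-based position
      q <- GenomicRanges::GRanges(chr, IRanges::IRanges(off + 1, width = 1L))
      GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(q),
                                          GenomeInfoDb::seqlevels(genes))
      inG <- GenomicRanges::countOverlaps(q, genes) > 0L
      inP <- !inG & GenomicRanges::countOverlaps(q, prom) > 0L
      rep_id <- rep(seq_len(r), each = N)
      gCount[done + seq_len(r)] <- as.integer(rowsum(as.integer(inG), rep_id))
      pCount[done + seq_len(r)] <- as.integer(rowsum(as.integer(inP), rep_id))
      done <- done + r
    }
    list(genic = gCount, promoter = pCount)
  })
  mk <- function(sim, obs, what) {
    structure(list(
      statistic = c(observed = obs),
      parameter = c(N = N, R = R),
      p.value = (1 + sum(sim >= obs)) / (R + 1),
      p.deplete = (1 + sum(sim <= obs)) / (R + 1),
      sim.mean = mean(sim),
      sim.sd = stats::sd(sim),
      replicates = R,
      seed = seed,
      alternative = "enrichment (p.value) / depletion (p.deplete)",
      method = sprintf("Monte-Carlo genomic-distribution test (%s)", what),
      data.name = sprintf("%g of %d insertions in %s", obs, N, what)),
      class = "htest")
  }
  list(genic = mk(counts$genic, observedGenic, "genes"),
       promoter = mk(counts$promoter, observedPromoter, "promoters"))
}
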