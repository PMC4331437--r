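test_that("equal counts and exposures give p = 1", {
  expect_identical(poissonRateTest(7, 100, 7, 100)$p.value, 1)
  expect_identical(poissonRateTest(0, 50, 0, 80)$p.value, 1)
})

test_that("small-case p equals the hand-enumerated binomial sum", {
  # x1 = 8 of n1 = 100 vs x2 = 1 of n2 = 100: condition on T = 9, p0 = 0.5;
  # enumerate all 10 outcomes and sum those no more likely than 8
  d <- dbinom(0:9, 9, 0.5)
  want <- sum(d[d <= d[9] * (1 + 1e-7)])   # FP-safe minlike inclusion
  expect_equal(poissonRateTest(8, 100, 1, 100)$p.value, want)
})

test_that("exact tests match brute-force pmf enumeration for totals <= 50", {
  set.seed(81)
  for (i in 1:60) {
    T <- sample(1:50, 1)
    x1 <- sample(0:T, 1)
    n1 <- runif(1, 10, 5000)
    n2 <- runif(1, 10, 5000)
    # independent oracle: stats::binom.test (minlike two-sided)
    want <- binom.test(x1, T, n1 / (n1 + n2))$p.value
    expect_equal(poissonRateTest(x1, n1, T - x1, n2)$p.value, want,
                 tolerance = 1e-12)
  }
  for (i in 1:40) {
    T <- sample(1:50, 1)
    co <- sample(0:T, 1)
    expect_equal(orientationTest(co, T)$p.value,
                 binom.test(co, T, 0.5)$p.value, tolerance = 1e-12)
  }
  # and against the two-sample Poisson oracle on larger counts
  expect_equal(poissonRateTest(1376, 11978540, 1353, 10921385)$p.value,
               poisson.test(c(1376, 1353), c(11978540, 10921385))$p.value,
               tolerance = 1e-10)
})

test_that("the rate test is symmetric in its two groups", {
  set.seed(82)
  for (i in 1:100) {
    x1 <- rpois(1, 20); x2 <- rpois(1, 10)
    n1 <- runif(1, 100, 1e6); n2 <- runif(1, 100, 1e6)
    expect_equal(poissonRateTest(x1, n1, x2, n2)$p.value,
                 poissonRateTest(x2, n2, x1, n1)$p.value, tolerance = 1e-12)
  }
})

test_that("pooled comparison reduces to the two-sample test on summed rest", {
  x <- c(a = 10, b = 20, c = 30)
  n <- c(a = 1000, b = 2000, c = 3000)
  ht <- rateVsPooledTest(x, n, "a")
  expect_equal(ht$p.value, poissonRateTest(10, 1000, 50, 5000)$p.value)
  # proportional counts: p = 1
  expect_identical(ht$p.value, 1)
})

test_that("overdispersion statistic matches the hand computation", {
  # x = (3, 7), n = (10, 10): pbar = 0.5, D = sum((x-5)^2/2.5) = 3.2
  ht <- overdispersionTest(c(3, 7), c(10, 10))
  expect_equal(unname(ht$statistic), 3.2)
  expect_equal(ht$p.value, pchisq(3.2, 1, lower.tail = FALSE))
  expect_identical(unname(overdispersionTest(c(5, 5), c(10, 10))$statistic), 0)
  # exactly proportional counts: D = 0, p = 1
  ht2 <- overdispersionTest(c(2, 4, 6), c(10, 20, 30))
  expect_identical(unname(ht2$statistic), 0)
  expect_identical(ht2$p.value, 1)
})

test_that("orientation test is 1 at the symmetric maximum", {
  expect_identical(orientationTest(5, 10)$p.value, 1)
})

test_that("Monte-Carlo p is exactly 1/(R+1) at the extreme", {
  idx <- buildAnnotationIndex(tinyGenome())
  lens <- Biostrings::width(genomeSequences(tinyGenome()))
  names(lens) <- names(genomeSequences(tinyGenome()))
  mc <- monteCarloDistributionTest(40, idx, lens, observedGenic = 40,
                                   observedPromoter = 0, R = 1000, seed = 5)
  expect_identical(mc$genic$p.value, 1 / 1001)
  expect_identical(mc$genic$p.deplete, 1)
  expect_warning(
    monteCarloDistributionTest(5, idx, lens, 1, 1, R = 50, seed = 1),
    "unstable")
})

test_that("simulated Monte-Carlo moments match the binomial oracle", {
  g <- tinyGenome()
  idx <- buildAnnotationIndex(g)
  lens <- Biostrings::width(genomeSequences(g))
  names(lens) <- names(genomeSequences(g))
  f <- compartmentFractions(idx)[["genic"]]
  N <- 400L; R <- 1000L
  mc <- monteCarloDistributionTest(N, idx, lens, observedGenic = round(N * f),
                                   observedPromoter = 0, R = R, seed = 83)
  expect_lt(abs(mc$genic$sim.mean - N * f), 3 * mc$genic$sim.sd / sqrt(R))
  expect_lt(abs(mc$genic$sim.sd - sqrt(N * f * (1 - f))),
            0.2 * sqrt(N * f * (1 - f)))
})

test_that("empirical p is super-uniform-bounded under a true null", {
  g <- tinyGenome()
  idx <- buildAnnotationIndex(g)
  lens <- Biostrings::width(genomeSequences(g))
  names(lens) <- names(genomeSequences(g))
  f <- compartmentFractions(idx)[["genic"]]
  N <- 30L; R <- 99L
  set.seed(84)
  obs <- rbinom(200, N, f)      # null draws from the same sampling law
  ps <- vapply(seq_along(obs), function(i) suppressWarnings(
    monteCarloDistributionTest(N, idx, lens, obs[i], 0, R = R,
                               seed = 9000 + i))$genic$p.value, numeric(1))
  for (alpha in c(0.05, 0.1, 0.2))
    expect_lte(mean(ps <= alpha), alpha + 2 / sqrt(R))
})

test_that("monte-carlo results are reproducible from the recorded seed", {
  idx <- buildAnnotationIndex(tinyGenome())
  lens <- Biostrings::width(genomeSequences(tinyGenome()))
  names(lens) <- names(genomeSequences(tinyGenome()))
  a <- monteCarloDistributionTest(50, idx, lens, 20, 3, R = 200, seed = 7)
  b <- monteCarloDistributionTest(50, idx, lens, 20, 3, R = 200, seed = 7)
  expect_identical(a$genic$p.value, b$genic$p.value)
  expect_identical(a$promoter$sim.mean, b$promoter$sim.mean)
  expect_identical(a$genic$seed, 7)
})
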