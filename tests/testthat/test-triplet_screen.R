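test_that("Poisson GOF p-value behaves as a calibrated Monte-Carlo test", {
  # order invariance
  set.seed(2)
  x <- rpois(21, 9)
  expect_equal(poissonGofPvalue(x, seed = 7),
               poissonGofPvalue(sample(x), seed = 7))

  # zero-variance sample (50 copies of 7) is decisively non-Poisson
  expect_lt(poissonGofPvalue(rep(7L, 50), seed = 3), 0.01)

  # overdispersed counts are rejected far more often than Poisson
  set.seed(8)
  pNB <- vapply(1:40, function(i) {
    mu <- 12
    poissonGofPvalue(rnbinom(21, size = mu / 2, mu = mu), nMC = 1000,
                     seed = i)
  }, 0)
  expect_gt(mean(pNB <= 0.10), 0.5)

  expect_error(poissonGofPvalue(c(0L, 0L)), "at least 3")
  expect_error(poissonGofPvalue(rpois(10, 4), nMC = 10), "at least 1000")
})

test_that("separation Bayes factor matches a numerical Jeffreys oracle", {
  # oracle: formal marginal under the Jeffreys prior by 1-D integration
  # (common 1/prod(y!) factor omitted, as it cancels in the ratio)
  numMarg <- function(counts, n = 200001, upper = 100) {
    lam <- seq(1e-8, upper, length.out = n)
    lf <- -0.5 * log(lam) + sum(counts) * log(lam) - length(counts) * lam
    m <- max(lf)
    m + log(sum(exp(lf - m)) * (lam[2] - lam[1]))
  }
  oracleBN10 <- function(a, b)
    numMarg(a) + numMarg(b) - numMarg(c(a, b))
  set.seed(5)
  a <- rpois(20, 20); b <- rpois(20, 5)
  implBN10 <- spikemux:::.lmargJeffreys(sum(a), 20) +
    spikemux:::.lmargJeffreys(sum(b), 20) -
    spikemux:::.lmargJeffreys(sum(a) + sum(b), 40)
  expect_equal(implBN10, oracleBN10(a, b), tolerance = 1e-6)

  # separated rates: strong evidence, BF > 3 for both constructions
  expect_gt(separationBayesFactor(a, b, method = "intrinsic"), 3)
  expect_gt(separationBayesFactor(a, b, method = "fractional"), 3)

  # identical samples: evidence for a common rate, BF < 1
  expect_lt(separationBayesFactor(a, a, method = "intrinsic"), 1)
  expect_lt(separationBayesFactor(a, a, method = "fractional"), 1)

  # symmetric in exchanging the conditions
  expect_equal(separationBayesFactor(a, b), separationBayesFactor(b, a))

  # monotone in mean separation at fixed total rate (deterministic
  # Poisson-quantile samples so the sample means track the rates exactly)
  total <- 24
  bf <- vapply(c(0, 2, 4, 8), function(d) {
    separationBayesFactor(qpois(ppoints(20), (total + d) / 2),
                          qpois(ppoints(20), (total - d) / 2))
  }, 0)
  expect_true(all(diff(log(bf)) > 0))
})

test_that("screening applies both criteria and reports reasons", {
  t1 <- makeTriplet(regime = "mixture", seed = 12)
  s1 <- screenTriplet(t1, seed = 1)
  expect_true(passed(s1))
  expect_length(failReasons(s1), 0)

  # overdispersed A-condition fails the Poisson rule
  set.seed(12)
  t2 <- Triplet("u", "c", injectOverdispersion(rpois(50, 20), 3, seed = 4),
                rpois(21, 5), rpois(18, 12))
  s2 <- screenTriplet(t2, seed = 1)
  if (!passed(s2)) expect_true("A not Poisson" %in% failReasons(s2))

  # equal rates fail separation
  set.seed(13)
  x <- rpois(21, 10)
  t3 <- Triplet("u", "c", x, sample(x), rpois(18, 10))
  s3 <- screenTriplet(t3, seed = 1)
  expect_false(passed(s3))
  expect_true("rates not separated" %in% failReasons(s3))

  # too few trials is reported
  t4 <- Triplet("u", "c", rpois(4, 20), rpois(21, 5), rpois(18, 12))
  s4 <- screenTriplet(t4, seed = 1)
  expect_true("too few trials" %in% failReasons(s4))

  # ScreenResult invariant: passed is consistent with the criteria
  expect_error(new("ScreenResult", gofPA = 0.5, gofPB = 0.5,
                   separationBF = 10, passed = FALSE,
                   failReasons = character(0),
                   gofThreshold = 0.1, bfThreshold = 3),
               "inconsistent")
})

test_that("screen pass rate under truly Poisson inputs is near 0.81", {
  # two independent GOF rules at the 0.10 level: 0.9^2, separation guaranteed
  set.seed(14)
  passes <- vapply(1:150, function(i) {
    t <- Triplet("u", "c", rpois(21, 20), rpois(21, 5), rpois(18, 12))
    passed(screenTriplet(t, nMC = 1000, seed = i))
  }, TRUE)
  expect_gt(mean(passes), 0.70)
  expect_lt(mean(passes), 0.92)
})
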