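test_that("rate posterior is the Jeffreys conjugate update", {
  p <- ratePosterior(rep(0L, 10))
  expect_equal(c(p@shape, p@rate), c(0.5, 10))
  expect_equal(ratePosterior(c(10L, 12L, 20L))@shape, 42.5)
  expect_equal(posteriorMean(ratePosterior(c(10L, 12L, 20L))), 42.5 / 3)
  # posterior mean approaches the sample mean as n grows
  big <- rep(c(7L, 9L), 500)
  expect_equal(posteriorMean(ratePosterior(big)), mean(big),
               tolerance = 1e-3)
  expect_error(ratePosterior(integer(0)), "non-empty")
})

test_that("single-hypothesis marginal is exact", {
  # empty product
  expect_equal(logMargSingle(integer(0), ratePosterior(1:3)), 0)
  # matches fine-grid integration
  post <- new("GammaPosterior", shape = 20.5, rate = 5)
  expect_equal(logMargSingle(3L, post), oracleSingle(3L, post),
               tolerance = 1e-6)
  # equals the sum of sequential one-step-ahead predictive log-probabilities
  set.seed(6)
  y <- rpois(7, 4)
  seqlp <- 0
  p <- ratePosterior(rpois(10, 4))
  pp <- p
  for (j in seq_along(y)) {
    seqlp <- seqlp + logMargSingle(y[j], pp)
    pp <- new("GammaPosterior", shape = pp@shape + y[j], rate = pp@rate + 1)
  }
  expect_equal(logMargSingle(y, p), seqlp, tolerance = 1e-10)
})

test_that("range and mixture marginals agree with brute-force oracles", {
  set.seed(31)
  q <- quadOracle()
  for (i in 1:4) {
    pA <- ratePosterior(rpois(20, 18)); pB <- ratePosterior(rpois(20, 5))
    y <- rpois(3, sample(c(18, 11, 5), 1))
    expect_equal(logMargIntermediate(y, pA, pB, q)$logml,
                 oracleRegion(y, pA, pB, "intermediate"), tolerance = 1e-3)
    expect_equal(logMargOutside(y, pA, pB, q)$logml,
                 oracleRegion(y, pA, pB, "outside"), tolerance = 1e-3)
    expect_equal(logMargMixture(y, pA, pB, q, details = FALSE)$logml,
                 oracleMixture(y, pA, pB), tolerance = 1e-3)
  }
  # default Monte-Carlo mode is consistent with the oracle within MC error
  pA <- ratePosterior(rpois(20, 18)); pB <- ratePosterior(rpois(20, 5))
  y <- rpois(4, 11)
  lm <- logMargMixture(y, pA, pB, mixtureQuad(), seed = 2)
  expect_lt(abs(lm$logml - oracleMixture(y, pA, pB)),
            4 * lm$mcSE + 1e-3)
})

test_that("degenerate limits collapse to the single marginal", {
  # near point-mass posteriors: mixture of identical components and a
  # zero-width intermediate interval both reduce to the shared single model
  sharp <- new("GammaPosterior", shape = 20000.5, rate = 1000)
  y <- c(18L, 22L, 20L)
  lmS <- logMargSingle(y, sharp)
  lmM <- logMargMixture(y, sharp, sharp, quadFast(), seed = 3)$logml
  lmI <- logMargIntermediate(y, sharp, sharp, quadFast(), seed = 3)$logml
  expect_equal(lmM, lmS, tolerance = 5e-3)
  expect_equal(lmI, lmS, tolerance = 5e-3)
})

test_that("classifier recovers each generating regime on seeded examples", {
  q <- quadFast()
  # AB counts literally a reshuffled copy of counts_A -> 'single'
  set.seed(41)
  cA <- rpois(20, 20)
  tr <- Triplet("u", "c", cA, rpois(20, 5), sample(cA, 20))
  expect_equal(winner(classifyTriplet(tr, q, seed = 1, force = TRUE)),
               "single")
  # half from Poi(20), half from Poi(5) -> 'mixture'
  tr2 <- makeTriplet(nAB = 20, alpha = 0.5, seed = 42)
  expect_equal(winner(classifyTriplet(tr2, q, seed = 1, force = TRUE)),
               "mixture")
  # counts at the midpoint rate -> 'intermediate'
  tr3 <- makeTriplet(regime = "intermediate", nAB = 20, seed = 43)
  expect_equal(winner(classifyTriplet(tr3, q, seed = 1, force = TRUE)),
               "intermediate")
  # counts at twice the larger rate -> 'outside'
  set.seed(44)
  tr4 <- Triplet("u", "c", rpois(20, 20), rpois(20, 5), rpois(20, 40))
  expect_equal(winner(classifyTriplet(tr4, q, seed = 1, force = TRUE)),
               "outside")
  # outside data below the interval loses to intermediate data comparison
  set.seed(45)
  trMid <- Triplet("u", "c", rpois(20, 20), rpois(20, 5), rpois(20, 12))
  mp <- classifyTriplet(trMid, q, seed = 1, force = TRUE)
  expect_lt(logMarglik(mp)["outside"], logMarglik(mp)["intermediate"])

  # posterior probabilities sum to one, winner attains winProb
  expect_equal(sum(modelPosterior(mp)), 1)
  expect_equal(unname(modelPosterior(mp)[winner(mp)]), winProb(mp))

  # unscreened triplets are refused
  set.seed(46)
  x <- rpois(21, 10)
  bad <- Triplet("u", "c", x, sample(x), rpois(18, 10))
  expect_error(classifyTriplet(bad, q, seed = 1), "failed the inclusion")
})

test_that("swapping A and B labels flips scores exactly and keeps the category", {
  q <- quadFast()
  for (s in 1:5) {
    tr <- makeTriplet(regime = sample(c("mixture", "single",
                                        "intermediate"), 1),
                      nAB = 12, seed = 100 + s)
    sw <- swapTripletLabels(tr)
    m1 <- classifyTriplet(tr, q, seed = 7, force = TRUE)
    m2 <- classifyTriplet(sw, q, seed = 7, force = TRUE)
    expect_identical(winner(m1), winner(m2))
    expect_identical(unname(modelPosterior(m1)), unname(modelPosterior(m2)))
    expect_identical(assignmentScores(m2), 1 - assignmentScores(m1))
    expect_identical(alphaMean(m2), 1 - alphaMean(m1))
    expect_identical(alphaCI(m2), rev(1 - alphaCI(m1)))
  }
})

test_that("assignment scores behave as component posteriors", {
  # plug-in variant at alpha = 0.5 where the two pmfs cross -> exactly 0.5
  lamA <- 20; lamB <- 5
  yEq <- which.min(abs(dpois(0:40, lamA) - dpois(0:40, lamB))[8:14]) + 6
  s <- pluginAssignmentScores(c(0L, yEq, 40L), 0.5, lamA, lamB)
  expect_equal(s[2],
               dpois(yEq, lamA) / (dpois(yEq, lamA) + dpois(yEq, lamB)),
               tolerance = 1e-12)
  # likelihood-ratio limits: large counts -> 1, small counts -> 0
  expect_gt(s[3], 0.999)
  expect_lt(s[1], 0.01)
  expect_true(all(s >= 0 & s <= 1))

  # fully Bayesian scores increase with the count and stay in [0, 1]
  tr <- makeTriplet(nAB = 15, seed = 51)
  mp <- classifyTriplet(tr, quadFast(), seed = 8, force = TRUE)
  sc <- assignmentScores(mp)
  expect_length(sc, 15)
  expect_true(all(sc >= 0 & sc <= 1))
  ord <- order(countsAB(tr))
  expect_true(all(diff(sc[ord]) >= -1e-9))
})

test_that("outside upper bound doubling moves the winner probability little", {
  deltas <- vapply(1:6, function(s) {
    tr <- makeTriplet(regime = sample(c("mixture", "single", "outside"), 1),
                      seed = 200 + s)
    outsideSensitivity(tr, quadFast(), seed = 9, force = TRUE)$deltaWinProb
  }, 0)
  expect_lt(max(deltas), 0.5)
})
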