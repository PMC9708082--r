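test_that("unit rates respect the separation and preference constraints", {
  cfg <- populationConfig(nUnits = 200, seed = 3)
  set.seed(cfg$seed)
  r <- sampleUnitRates(cfg)
  ratio <- pmax(r$lamA, r$lamB) / pmin(r$lamA, r$lamB)
  expect_true(all(ratio >= 3))
  expect_true(all(pmax(r$lamA, r$lamB) <= 40 & pmin(r$lamA, r$lamB) >= 2))
  expect_equal(mean(r$preference == "A"), 0.5)
  # preferred stimulus carries the larger rate
  expect_true(all(ifelse(r$preference == "A", r$lamA > r$lamB,
                         r$lamB > r$lamA)))
  # all-A preference
  set.seed(1)
  expect_true(all(sampleUnitRates(populationConfig(prefAFraction = 1),
                                  n = 30)$preference == "A"))
  # infeasible range is refused
  expect_error(populationConfig(rateRange = c(10, 20), minRateRatio = 3),
               "cannot accommodate")
})

test_that("latent states are independent Bernoulli draws with bias beta", {
  set.seed(2)
  st <- sampleLatentStates(populationConfig(biasBeta = 1), nTrials = 50)
  expect_true(all(st == "A"))
  st2 <- sampleLatentStates(populationConfig(biasBeta = 0.5),
                            nTrials = 10000)
  expect_equal(mean(st2 == "A"), 0.5, tolerance = 0.02)
  # lag-1 autocorrelation near zero
  z <- as.numeric(st2 == "A")
  expect_lt(abs(cor(z[-1], z[-length(z)])), 0.03)
})

test_that("generated triplets honor their regimes and truth records", {
  cfg <- populationConfig(nUnits = 40, trialsAB = 200, seed = 7,
                          regimeProportions = c(single = 0.25,
                                                outside = 0.25,
                                                intermediate = 0.25,
                                                mixture = 0.25))
  ds <- generateTriplets(cfg)
  tt <- truth(ds)
  expect_equal(nrow(tt), 40)
  expect_equal(as.vector(table(tt$regime)[c("single", "outside",
                                            "intermediate", "mixture")]),
               rep(10L, 4))
  expect_equal(length(latentStates(ds)$s01), 200)

  for (i in seq_len(nrow(tt))) {
    tr <- triplets(ds)[[paste0(tt$unit_id[i], "/", tt$condition_key[i])]]
    mAB <- mean(countsAB(tr))
    lamA <- tt$lamA[i]; lamB <- tt$lamB[i]
    tol <- 4 * sqrt(max(lamA, lamB) * 1.5 / 200)
    target <- switch(tt$regime[i],
      single = if (tt$single_target[i] == "A") lamA else lamB,
      outside = if (tt$outside_direction[i] == "above")
        1.5 * max(lamA, lamB) else 0.5 * min(lamA, lamB),
      intermediate = (lamA + lamB) / 2,
      mixture = NA)
    if (!is.na(target)) expect_lt(abs(mAB - target), max(tol, 1.5))
    if (tt$regime[i] == "mixture") {
      # empirical AB mean between the rates; alpha formula verified against
      # the realized latent-state frequencies
      expect_gt(mAB, min(lamA, lamB) - 1.5)
      expect_lt(mAB, max(lamA, lamB) + 1.5)
      expect_equal(tt$alpha_true[i],
                   cfg$biasBeta * cfg$fidelityPhi +
                     (1 - cfg$biasBeta) * (1 - cfg$fidelityPhi))
    }
  }
})

test_that("truth alpha matches simulated encoding frequencies", {
  cfg <- populationConfig(nUnits = 1, trialsAB = 5000, biasBeta = 0.7,
                          fidelityPhi = 0.9, seed = 11,
                          regimeProportions = c(single = 0, outside = 0,
                                                intermediate = 0,
                                                mixture = 1))
  ds <- generateTriplets(cfg)
  st <- latentStates(ds)$s01
  # P(encode A) = beta*phi + (1-beta)*(1-phi)
  expect_equal(truth(ds)$alpha_true[1], 0.7 * 0.9 + 0.3 * 0.1)
  expect_equal(mean(st == "A"), 0.7, tolerance = 0.03)
})

test_that("overdispersion injection preserves the mean and breaks the GOF", {
  set.seed(5)
  x <- rpois(200, 15)
  y <- injectOverdispersion(x, 2, seed = 9)
  expect_equal(mean(y), mean(x), tolerance = 1.2)
  expect_gt(var(y) / mean(y), 1.8)      # index of dispersion near 1 + 2
  # Poisson retention: GOF passes ~90% when overdispersion is off
  set.seed(6)
  pPois <- vapply(1:100, function(i)
    poissonGofPvalue(rpois(21, 12), nMC = 1000, seed = i), 0)
  expect_gt(mean(pPois > 0.10), 0.80)
  # strong overdispersion mostly fails
  pOD <- vapply(1:60, function(i)
    poissonGofPvalue(injectOverdispersion(rpois(50, 15), 2, seed = i),
                     nMC = 1000, seed = i), 0)
  expect_gt(mean(pOD <= 0.10), 0.5)
})

test_that("synthetic eye traces respect bounds and log injected events", {
  g0 <- generateEyeTraces(30, saccadeProb = 0, seed = 13)
  expect_equal(nrow(g0$events), 0)
  for (tr in g0$traces)
    expect_true(all(abs(tr$x) <= 0.5 & abs(tr$y) <= 0.5))
  # zero jitter, no events: detector finds nothing
  gFlat <- generateEyeTraces(5, driftSD = 0, seed = 14)
  expect_true(all(vapply(gFlat$traces, function(tr)
    nrow(detectMicrosaccades(tr)) == 0, TRUE)))
  # injected events are detected (recall checked properly in acceptance)
  gS <- generateEyeTraces(30, saccadeProb = 1, seed = 15)
  hits <- vapply(gS$traces, function(tr)
    nrow(detectMicrosaccades(tr)) > 0, TRUE)
  expect_gt(mean(hits), 0.9)
})
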