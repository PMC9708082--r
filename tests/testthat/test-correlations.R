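test_that("preference follows the higher mean count, ties flagged", {
  expect_equal(preference(c(12L, 12L), c(4L, 4L))$preferred, "A")
  expect_equal(preference(c(4L, 4L), c(12L, 12L))$preferred, "B")
  tie <- preference(c(4L, 6L), c(5L, 5L))
  expect_true(tie$tie)
  expect_true(is.na(tie$preferred))
})

test_that("spike-count correlation applies the 3-SD outlier rule", {
  # hand-computed Pearson value
  res <- spikeCountCorrelation(c(2L, 0L, 4L, 2L), c(1L, 3L, 1L, 3L))
  expect_equal(res$r, -sqrt(0.5), tolerance = 1e-3)
  expect_equal(res$nUsed, 4)

  # identical vectors with nonzero variance
  set.seed(3)
  x <- rpois(15, 8)
  expect_equal(spikeCountCorrelation(x, x)$r, 1)

  # a presentation is dropped iff either count deviates > 3 SD
  set.seed(4)
  x <- rpois(30, 10); y <- rpois(30, 10)
  x[1] <- 60L    # gross outlier in x only
  res2 <- spikeCountCorrelation(x, y)
  expect_equal(res2$nUsed, 29)
  expect_equal(res2$r, cor(x[-1], y[-1]))

  # on clean data the exclusion is a no-op
  set.seed(5)
  for (i in 1:10) {
    a <- rpois(20, 12); b <- rpois(20, 12)
    keepAll <- spikeCountCorrelation(a, b, outlierSD = 1e6)
    std <- spikeCountCorrelation(a, b)
    if (std$nUsed == 20) expect_equal(std$r, keepAll$r)
  }

  # zero variance after exclusion -> missing with flag
  expect_true(is.na(spikeCountCorrelation(rep(3L, 10), rpois(10, 5))$r))
  expect_equal(spikeCountCorrelation(rep(3L, 10), rpois(10, 5))$flag,
               "zero_variance")
})

test_that("assignment-score correlation tracks shared fluctuation", {
  s <- runif(12)
  expect_equal(assignmentCorrelation(s, s)$r, 1)
  expect_true(is.na(assignmentCorrelation(rep(0.4, 8), runif(8))$r))

  # congruent pair: r_as has the same sign as r_sc; incongruent: opposite.
  # Build a coordinated pair explicitly from a shared latent state.
  set.seed(9)
  st <- runif(40) < 0.5
  mkUnit <- function(prefA) {
    enc <- ifelse(runif(40) < 0.9, st, !st)
    lam <- if (prefA) ifelse(enc, 20, 5) else ifelse(enc, 5, 20)
    counts <- rpois(40, lam)
    list(counts = counts,
         scores = pluginAssignmentScores(counts, 0.5,
                                         if (prefA) 20 else 5,
                                         if (prefA) 5 else 20))
  }
  u1 <- mkUnit(TRUE); u2 <- mkUnit(TRUE); u3 <- mkUnit(FALSE)
  rsc_cong <- spikeCountCorrelation(u1$counts, u2$counts)$r
  ras_cong <- assignmentCorrelation(u1$scores, u2$scores)$r
  rsc_inc <- spikeCountCorrelation(u1$counts, u3$counts)$r
  ras_inc <- assignmentCorrelation(u1$scores, u3$scores)$r
  expect_equal(sign(ras_cong), sign(rsc_cong))
  expect_equal(sign(ras_inc), -sign(rsc_inc))
})

test_that("pair labels combine preference and model class", {
  expect_equal(labelPair("A", "A", "mixture", "single")$congruence,
               "congruent")
  expect_equal(labelPair("B", "B", "single", "single")$congruence,
               "congruent")
  expect_equal(labelPair("A", "B", "mixture", "mixture")$congruence,
               "incongruent")
  # class combo is unordered
  expect_equal(labelPair("A", "A", "mixture", "single")$classCombo,
               labelPair("A", "A", "single", "mixture")$classCombo)
  expect_error(labelPair("A", "B", "mixture", "mixture", "c1", "c2"),
               "different condition keys")
})

test_that("median shuffle test is valid and deterministic", {
  # identical groups: observed difference 0, p = 1
  g <- c(0.1, 0.2, 0.3, -0.1)
  res <- medianShuffleTest(g, g, nShuffles = 500, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)

  # deterministic given seed
  set.seed(10)
  a <- rnorm(25, 0.4, 0.2); b <- rnorm(25, -0.1, 0.2)
  r1 <- medianShuffleTest(a, b, nShuffles = 1000, seed = 5)
  r2 <- medianShuffleTest(a, b, nShuffles = 1000, seed = 5)
  expect_identical(r1$p, r2$p)

  # an observed difference beyond every shuffle: p = 1/(n+1) < 1/n
  expect_lt(r1$p, 1 / 1000 + 1e-12)
  expect_error(medianShuffleTest(numeric(0), 1:3), "non-empty")
})

test_that("population summary reports the congruence/class grid", {
  set.seed(20)
  ds <- generateTriplets(populationConfig(
    nUnits = 10, regimeProportions = c(single = 0.3, outside = 0,
                                       intermediate = 0, mixture = 0.7),
    fidelityPhi = 0.95, seed = 22))
  trip <- triplets(ds)
  screens <- lapply(seq_along(trip), function(i)
    screenTriplet(trip[[i]], nMC = 1000, seed = i))
  keep <- which(vapply(screens, passed, TRUE))
  cls <- lapply(keep, function(i)
    classifyTriplet(trip[[i]], quadFast(), seed = i, screen = screens[[i]]))
  rec <- pairRecords(trip[keep], cls)
  expect_true(all(c("AB", "A_alone", "B_alone") %in% rec$stimulus_set))
  expect_true(all(rec$r_sc >= -1 & rec$r_sc <= 1, na.rm = TRUE))
  # symmetric in pair order by construction: one record per unordered pair
  expect_false(any(duplicated(
    rec[, c("unit_i", "unit_j", "stimulus_set")])))

  summ <- summarizePopulation(rec, nShuffles = 200, seed = 2)
  expect_true(all(c("stimulus_set", "class_combo", "congruence",
                    "median_r_sc", "n") %in% names(summ$medians)))
  # single-stimulus baseline rows are pooled
  expect_true("single_stimulus" %in% summ$medians$stimulus_set)
  # records all sharing one value give that value as the cell median
  rec2 <- rec[rec$stimulus_set == "AB", ][1:3, ]
  rec2$r_sc <- 0.3
  expect_equal(
    summarizePopulation(rec2, nShuffles = 200, seed = 1)$medians$median_r_sc,
    rep(0.3, nrow(summarizePopulation(rec2, nShuffles = 200,
                                      seed = 1)$medians)))
})
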