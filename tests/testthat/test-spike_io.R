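test_that("spike counting uses the half-open area window", {
  meta <- data.frame(presentation_id = c("p1", "p2"),
                     condition = c("A", "B"), stim_A = c("g1", ""),
                     stim_B = c("", "g2"), correct = TRUE,
                     attended_in_rf = FALSE, session_id = "s1")
  w <- areaWindow("V1")
  expect_equal(c(w$startMs, w$endMs), c(30, 230))
  expect_equal(with(areaWindow("V4"), c(startMs, endMs)), c(50, 250))

  spikes <- data.frame(
    unit_id = c("u1", "u1", "u1", "u2", "u2", "u2"),
    presentation_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    time_ms = c(35, 100, 225, 10, 245, 230))
  sce <- countSpikesInWindow(spikes, meta, w)
  cts <- spikeCounts(sce)
  expect_equal(cts["u1", "p1"], 3L)   # all inside 30-230
  expect_equal(cts["u2", "p1"], 0L)   # 10 ms is before the window
  expect_equal(cts["u2", "p2"], 0L)   # 245 outside; 230 excluded (half-open)

  # presentation without spikes gets an explicit zero
  expect_equal(cts["u1", "p2"], 0L)
})

test_that("counting is invariant under joint time translation", {
  meta <- data.frame(presentation_id = "p1", condition = "A",
                     stim_A = "g", stim_B = "", correct = TRUE,
                     attended_in_rf = FALSE, session_id = "s")
  set.seed(42)
  for (rep in 1:5) {
    times <- sort(runif(40, 0, 300))
    off <- runif(1, -50, 50)
    spikes <- data.frame(unit_id = "u", presentation_id = "p1",
                         time_ms = times)
    w1 <- list(area = "V1", startMs = 30, endMs = 230)
    w2 <- list(area = "V1", startMs = 30 + off, endMs = 230 + off)
    spikes2 <- transform(spikes, time_ms = time_ms + off)
    expect_equal(spikeCounts(countSpikesInWindow(spikes, meta, w1)),
                 spikeCounts(countSpikesInWindow(spikes2, meta, w2)))
  }
})

test_that("microsaccade detector applies the 6-SD velocity rule", {
  # constant-position trace: zero velocity, no events
  expect_equal(nrow(detectMicrosaccades(flatTrace())), 0)

  # injected 1-degree step on a quiet baseline: exactly one event at the step
  tr <- stepTrace(at = 50, amp = 1)
  ev <- detectMicrosaccades(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - (50 - 1) / 500 * 1000), 10)

  # explicit baseline stats: threshold is mean + 6 SD (event only above it)
  n <- 60; rate <- 1000
  x <- rep(0, n); x[30] <- 0.05   # brief excursion
  tr2 <- eyeTrace("p", rate, x, rep(0, n))
  sp <- spikemux:::.eyeSpeed(tr2)
  peak <- max(sp)
  below <- detectMicrosaccades(tr2, baseline = list(mean = 0,
                                                    sd = peak / 6 * 1.01))
  above <- detectMicrosaccades(tr2, baseline = list(mean = 0,
                                                    sd = peak / 6 * 0.99))
  expect_equal(nrow(below), 0)
  expect_gt(nrow(above), 0)

  # detection count non-decreasing in amplitude
  amps <- c(0.05, 0.2, 0.5, 1)
  counts <- vapply(amps, function(a)
    nrow(detectMicrosaccades(stepTrace(amp = a, noise = 1e-3))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("presentation filtering applies rules in order and partitions", {
  meta <- data.frame(
    presentation_id = c("p1", "p2", "p3", "p4", "p5"),
    condition = "AB", stim_A = "g1", stim_B = "g2",
    correct = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    attended_in_rf = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    session_id = "s1")
  traces <- list(
    p1 = flatTrace(id = "p1"),
    p2 = flatTrace(id = "p2"),          # incorrect trial, perfect fixation
    p4 = eyeTrace("p4", 500, c(rep(0, 50), rep(0.6, 50)), rep(0, 100)),
    p5 = stepTrace(id = "p5", amp = 0.3, at = 40))
  res <- filterPresentations(meta, traces)
  expect_equal(res$kept, "p1")
  reasons <- setNames(res$exclusions$reason, res$exclusions$presentation_id)
  expect_equal(unname(reasons["p2"]), "incorrect")
  expect_equal(unname(reasons["p3"]), "attended_in_rf")
  expect_equal(unname(reasons["p4"]), "fixation_break")
  expect_equal(unname(reasons["p5"]), "microsaccade")
  # kept + excluded partition the presentations
  expect_setequal(c(res$kept, res$exclusions$presentation_id),
                  meta$presentation_id)
  expect_length(intersect(res$kept, res$exclusions$presentation_id), 0)
  # missing trace: kept but flagged
  res2 <- filterPresentations(meta[1, ], traces = list())
  expect_equal(res2$kept, "p1")
  expect_equal(res2$flags$flag, "no_eye_trace")
})

test_that("eye-rate correlation projects onto the stimulus axis", {
  meta <- data.frame(presentation_id = paste0("p", 1:6), condition = "AB",
                     stim_A = "g1", stim_B = "g2", correct = TRUE,
                     attended_in_rf = FALSE, session_id = "s1")
  xs <- seq(-0.2, 0.3, length.out = 6)
  traces <- lapply(seq_len(6), function(i)
    eyeTrace(paste0("p", i), 500, rep(xs[i], 20), rep(0.4, 20)))
  names(traces) <- paste0("p", 1:6)
  # counts exactly linear in the projected (x) position -> r = 1
  cts <- matrix(as.integer(round(10 + 20 * xs)), nrow = 2, ncol = 6,
                byrow = TRUE, dimnames = list(c("u1", "u2"), paste0("p", 1:6)))
  cts["u2", ] <- 7L   # constant counts -> undefined, flagged
  sce <- makeSpikeCountExperiment(cts, meta)
  res <- eyeRateCorrelation(sce, traces, stimulusAxis = c(1, 0))
  expect_equal(res$r[res$unit_id == "u1"], 1)
  expect_true(is.na(res$r[res$unit_id == "u2"]))
  expect_equal(res$flag[res$unit_id == "u2"], "zero_variance")
})

test_that("CSV round trip: counts written by the generator are re-ingested", {
  ds <- generateTriplets(populationConfig(nUnits = 3, trialsA = 6,
                                          trialsB = 6, trialsAB = 5,
                                          seed = 21))
  dir <- tempfile(); paths <- writeSyntheticData(ds, dir)
  sce <- readCountTable(paths["counts"], paths["meta"])
  expect_s4_class(sce, "SpikeCountExperiment")
  trip <- makeTriplets(sce, minTrials = 5)
  expect_length(trip, 3)
  orig <- triplets(ds)
  for (nm in names(orig))
    expect_equal(countsAB(trip[[nm]]), countsAB(orig[[nm]]))
  # spike-event path: synthesize event times matching a count table
  meta <- ds@meta[1:3, ]
  spikes <- data.frame(unit_id = "u1",
                       presentation_id = rep(meta$presentation_id, 2:4),
                       time_ms = 100)
  sce2 <- countSpikesInWindow(spikes, meta, areaWindow("V1"))
  expect_equal(as.integer(spikeCounts(sce2)), 2:4)
})
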