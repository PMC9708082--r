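#' Configuration for a synthetic coordinated population
#'
#' The generator emulates the statistical structure the analysis assumes:
#' Poisson single-stimulus responses with well-separated rates, the four
#' dual-stimulus response regimes, and population coordination through a
#' single per-trial latent state. Defaults follow the recorded-data
#' conventions: 21 single-stimulus and 18 dual-stimulus presentations per
#' triplet, regime proportions with 'single' dominant and a one-third
#' 'mixture' minority, and a strongly coordinated population (fidelity 0.95,
#' no per-trial bias).
#'
#' @param nUnits units per session (default 20).
#' @param nSessions independent sessions; latent states are shared within and
#'   independent across sessions (default 1).
#' @param trialsA,trialsB,trialsAB presentations per condition (defaults 21,
#'   21, 18).
#' @param rateRange range of single-stimulus rates, counts per 200 ms window
#'   (default c(2, 40)).
#' @param minRateRatio minimum preferred/non-preferred rate ratio (default
#'   3).
#' @param regimeProportions named 4-vector of regime probabilities summing to
#'   1 (single, outside, intermediate, mixture).
#' @param prefAFraction fraction of units preferring stimulus A (default
#'   0.5).
#' @param biasBeta per-trial probability that the population latent state is
#'   A (default 0.5).
#' @param fidelityPhi probability that a mixture unit encodes the population
#'   state on a trial (in [0.5, 1]; 0.5 = independent units; default 0.95).
#' @param overdispersion optional dispersion: counts become
#'   negative-binomial with variance mean * (1 + overdispersion); NULL keeps
#'   Poisson.
#' @param seed RNG seed (default 1).
#' @return validated config list.
#' @export
populationConfig <- function(nUnits = 20, nSessions = 1,
                             trialsA = 21, trialsB = 21, trialsAB = 18,
                             rateRange = c(2, 40), minRateRatio = 3,
                             regimeProportions = c(single = 0.50,
                                                   outside = 0.10,
                                                   intermediate = 0.07,
                                                   mixture = 0.33),
                             prefAFraction = 0.5, biasBeta = 0.5,
                             fidelityPhi = 0.95, overdispersion = NULL,
                             seed = 1) {
  if (abs(sum(regimeProportions) - 1) > 1e-9)
    stop("regimeProportions must sum to 1")
  if (!all(c("single", "outside", "intermediate", "mixture") %in%
           names(regimeProportions)))
    stop("regimeProportions must name single, outside, intermediate, mixture")
  if (min(trialsA, trialsB, trialsAB) < 5) stop("need at least 5 trials per condition")
  if (any(rateRange <= 0) || rateRange[2] <= rateRange[1])
    stop("rateRange must be a positive increasing interval")
  if (rateRange[2] / rateRange[1] < minRateRatio)
    stop("rateRange cannot accommodate minRateRatio")
  if (fidelityPhi < 0.5 || fidelityPhi > 1)
    stop("fidelityPhi must lie in [0.5, 1]")
  if (biasBeta < 0 || biasBeta > 1) stop("biasBeta must lie in [0, 1]")
  list(nUnits = nUnits, nSessions = nSessions, trialsA = trialsA,
       trialsB = trialsB, trialsAB = trialsAB, rateRange = rateRange,
       minRateRatio = minRateRatio,
       regimeProportions = regimeProportions[c("single", "outside",
                                               "intermediate", "mixture")],
       prefAFraction = prefAFraction, biasBeta = biasBeta,
       fidelityPhi = fidelityPhi, overdispersion = overdispersion,
       seed = seed)
}

#' Sample per-unit single-stimulus rates and preferences
#'
#' Rates are log-uniform on \code{rateRange}, resampled until the
#' preferred/non-preferred ratio reaches \code{minRateRatio} so that every
#' unit's rates are substantially separated. A fraction
#' \code{prefAFraction} of units (rounded) prefer stimulus A.
#'
#' @param cfg a \code{\link{populationConfig}}.
#' @param n number of units (defaults to \code{cfg$nUnits}).
#' @return data.frame with lamA, lamB, preference.
#' @export
sampleUnitRates <- function(cfg, n = cfg$nUnits) {
  lr <- log(cfg$rateRange)
  hi <- exp(stats::runif(n, lr[1], lr[2]))
  lo <- exp(stats::runif(n, lr[1], lr[2]))
  bad <- which(pmax(hi, lo) / pmin(hi, lo) < cfg$minRateRatio)
  while (length(bad)) {
    hi[bad] <- exp(stats::runif(length(bad), lr[1], lr[2]))
    lo[bad] <- exp(stats::runif(length(bad), lr[1], lr[2]))
    bad <- bad[pmax(hi[bad], lo[bad]) / pmin(hi[bad], lo[bad]) <
                 cfg$minRateRatio]
  }
  pref <- rep("B", n)
  nA <- round(cfg$prefAFraction * n)
  if (nA > 0) pref[seq_len(nA)] <- "A"
  lamPref <- pmax(hi, lo); lamNon <- pmin(hi, lo)
  data.frame(lamA = ifelse(pref == "A", lamPref, lamNon),
             lamB = ifelse(pref == "A", lamNon, lamPref),
             preference = pref)
}

#' Sample per-trial population latent states
#'
#' Independent Bernoulli states per dual-stimulus trial: "A" with
#' probability \code{biasBeta}.
#'
#' @param cfg a \code{\link{populationConfig}}.
#' @param nTrials number of dual-stimulus trials (defaults to
#'   \code{cfg$trialsAB}).
#' @return character vector of "A"/"B" states.
#' @export
sampleLatentStates <- function(cfg, nTrials = cfg$trialsAB) {
  ifelse(stats::runif(nTrials) < cfg$biasBeta, "A", "B")
}

## Poisson draws, optionally replaced by same-mean negative binomial with
## variance mu * (1 + dispersion)
.rcounts <- function(n, mu, dispersion = NULL) {
  if (is.null(dispersion) || dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = mu / dispersion, mu = mu)
}

## deterministic regime composition: exact proportions up to rounding,
## assignment order shuffled
.regimeAssignment <- function(props, n) {
  k <- floor(props * n)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(props * n - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  sample(rep(names(props), times = k))
}

#' Generate a ground-truth-labelled synthetic population
#'
#' Draws, for every unit: A-alone counts from Poisson(lamA), B-alone counts
#' from Poisson(lamB), and dual-stimulus counts according to the unit's
#' regime -- 'single' (one fixed stimulus's rate, winner/loser-take-all),
#' 'outside' (1.5 x max or 0.5 x min, per unit), 'intermediate' (the
#' midpoint), or 'mixture' (the unit encodes the per-trial population state
#' with probability \code{fidelityPhi}, else the other stimulus, and emits
#' Poisson counts at the encoded stimulus's rate). The implied mixture
#' weight, recorded in the truth table, is
#' \eqn{\alpha = \beta\phi + (1-\beta)(1-\phi)} (probability that a count
#' came from the A component).
#'
#' @param cfg a \code{\link{populationConfig}}.
#' @return A \linkS4class{SyntheticDataset}; its \code{meta} and
#'   \code{counts} slots use the same schemas the CSV readers consume.
#' @examples
#' ds <- generateTriplets(populationConfig(nUnits = 4, seed = 7))
#' truth(ds)
#' @export
generateTriplets <- function(cfg) {
  withSeed(cfg$seed, {
    allTrip <- list(); truthRows <- list(); states <- list()
    metaRows <- list(); countRows <- list()
    for (s in seq_len(cfg$nSessions)) {
      sid <- sprintf("s%02d", s)
      ck <- paste0(sid, "_cond1")
      rates <- sampleUnitRates(cfg)
      regime <- .regimeAssignment(cfg$regimeProportions, cfg$nUnits)
      st <- sampleLatentStates(cfg)
      states[[sid]] <- st
      presA <- sprintf("%s_A_%03d", sid, seq_len(cfg$trialsA))
      presB <- sprintf("%s_B_%03d", sid, seq_len(cfg$trialsB))
      presAB <- sprintf("%s_AB_%03d", sid, seq_len(cfg$trialsAB))
      meta <- data.frame(
        presentation_id = c(presA, presB, presAB),
        condition = rep(c("A", "B", "AB"),
                        c(cfg$trialsA, cfg$trialsB, cfg$trialsAB)),
        stim_A = rep(c("gratingA", "", "gratingA"),
                     c(cfg$trialsA, cfg$trialsB, cfg$trialsAB)),
        stim_B = rep(c("", "gratingB", "gratingB"),
                     c(cfg$trialsA, cfg$trialsB, cfg$trialsAB)),
        correct = TRUE, attended_in_rf = FALSE, session_id = sid,
        condition_key = ck)
      metaRows[[sid]] <- meta
      for (u in seq_len(cfg$nUnits)) {
        uid <- sprintf("%s_u%03d", sid, u)
        lamA <- rates$lamA[u]; lamB <- rates$lamB[u]
        cA <- .rcounts(cfg$trialsA, lamA, cfg$overdispersion)
        cB <- .rcounts(cfg$trialsB, lamB, cfg$overdispersion)
        singleTarget <- NA_character_; outsideDir <- NA_character_
        alphaTrue <- NA_real_
        if (regime[u] == "single") {
          singleTarget <- sample(c("A", "B"), 1)
          mu <- if (singleTarget == "A") lamA else lamB
          cAB <- .rcounts(cfg$trialsAB, mu, cfg$overdispersion)
        } else if (regime[u] == "outside") {
          outsideDir <- sample(c("above", "below"), 1)
          mu <- if (outsideDir == "above") 1.5 * max(lamA, lamB)
                else 0.5 * min(lamA, lamB)
          cAB <- .rcounts(cfg$trialsAB, mu, cfg$overdispersion)
        } else if (regime[u] == "intermediate") {
          cAB <- .rcounts(cfg$trialsAB, (lamA + lamB) / 2,
                          cfg$overdispersion)
        } else {
          follow <- stats::runif(cfg$trialsAB) < cfg$fidelityPhi
          enc <- ifelse(follow, st, ifelse(st == "A", "B", "A"))
          mu <- ifelse(enc == "A", lamA, lamB)
          cAB <- .rcounts(cfg$trialsAB, mu, cfg$overdispersion)
          alphaTrue <- cfg$biasBeta * cfg$fidelityPhi +
            (1 - cfg$biasBeta) * (1 - cfg$fidelityPhi)
        }
        allTrip[[paste0(uid, "/", ck)]] <-
          Triplet(uid, ck, cA, cB, cAB,
                  presA = presA, presB = presB, presAB = presAB)
        truthRows[[uid]] <- data.frame(
          unit_id = uid, session_id = sid, condition_key = ck,
          regime = regime[u], lamA = lamA, lamB = lamB,
          preference = rates$preference[u], alpha_true = alphaTrue,
          single_target = singleTarget, outside_direction = outsideDir)
        countRows[[uid]] <- data.frame(
          unit_id = uid,
          presentation_id = c(presA, presB, presAB),
          count = c(cA, cB, cAB))
      }
    }
    new("SyntheticDataset", triplets = allTrip,
        truth = do.call(rbind, c(truthRows, list(make.row.names = FALSE))),
        latentStates = states,
        meta = do.call(rbind, c(metaRows, list(make.row.names = FALSE))),
        counts = do.call(rbind, c(countRows, list(make.row.names = FALSE))),
        config = cfg)
  })
}

#' Replace counts with overdispersed negative-binomial draws
#'
#' Redraws a count sample from a negative binomial with the same mean and
#' variance mean * (1 + dispersion); used to exercise the Poisson
#' goodness-of-fit exclusion.
#'
#' @param counts non-negative integer counts.
#' @param dispersion dispersion parameter (> 0).
#' @param seed optional RNG seed.
#' @return integer counts of the same length.
#' @export
injectOverdispersion <- function(counts, dispersion, seed = NULL) {
  stopifnot(dispersion > 0)
  counts <- .checkCounts(counts)
  mu <- mean(counts)
  if (mu == 0) return(counts)
  withSeed(seed, .rcounts(length(counts), mu, dispersion))
}

#' Generate synthetic fixational eye traces
#'
#' Smooth fixational drift (a mean-reverting AR(1) in each coordinate,
#' stationary SD \code{driftSD}, clipped inside the fixation window) with
#' optional injected microsaccades: step-like displacements of amplitude
#' \code{saccadeAmplitude} traversed over two samples at a known time,
#' logged in the returned truth table.
#'
#' @param nPresentations number of traces.
#' @param sampleRate Hz (default 500).
#' @param durationMs trace duration (default 200).
#' @param driftSD stationary drift SD, degrees (default 0.05).
#' @param arCoef AR(1) coefficient per sample (default 0.98).
#' @param saccadeProb probability a presentation contains one injected
#'   microsaccade (default 0).
#' @param saccadeAmplitude step amplitude, degrees (default 0.3).
#' @param fixationHalfwidth clipping bound, degrees (default 0.5).
#' @param seed optional RNG seed.
#' @return list with \code{traces} (named list of eye traces) and
#'   \code{events} (data.frame presentation_id, onset_ms).
#' @export
generateEyeTraces <- function(nPresentations, sampleRate = 500,
                              durationMs = 200, driftSD = 0.05,
                              arCoef = 0.98, saccadeProb = 0,
                              saccadeAmplitude = 0.3,
                              fixationHalfwidth = 0.5, seed = NULL) {
  n <- max(3L, as.integer(round(durationMs / 1000 * sampleRate)))
  innovSD <- driftSD * sqrt(1 - arCoef^2)
  withSeed(seed, {
    traces <- list(); ev <- list()
    for (p in seq_len(nPresentations)) {
      id <- sprintf("p%04d", p)
      drift <- function() {
        x <- numeric(n)
        x[1] <- stats::rnorm(1, 0, driftSD)
        for (i in 2:n) x[i] <- arCoef * x[i - 1] + stats::rnorm(1, 0, innovSD)
        x
      }
      x <- drift(); y <- drift()
      if (stats::runif(1) < saccadeProb) {
        at <- sample(seq(5, n - 5), 1)
        theta <- stats::runif(1, 0, 2 * pi)
        dx <- saccadeAmplitude * cos(theta)
        dy <- saccadeAmplitude * sin(theta)
        ramp <- c(rep(0, at - 1), 0.5, rep(1, n - at))
        x <- x - dx / 2 + dx * ramp
        y <- y - dy / 2 + dy * ramp
        ev[[id]] <- data.frame(presentation_id = id,
                               onset_ms = (at - 1) / sampleRate * 1000)
      }
      b <- fixationHalfwidth * 0.98
      traces[[id]] <- eyeTrace(id, sampleRate,
                               pmin(b, pmax(-b, x)), pmin(b, pmax(-b, y)))
    }
    list(traces = traces,
         events = if (length(ev)) do.call(rbind, ev)
                  else data.frame(presentation_id = character(),
                                  onset_ms = numeric()))
  })
}

#' Write a synthetic dataset to the CSV schemas the readers consume
#'
#' Writes counts.csv, meta.csv, condition_map.csv, truth.csv and
#' latent_states.csv so the synthetic data exercise the real input path.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
writeSyntheticData <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             meta = file.path(dir, "meta.csv"),
             condition_map = file.path(dir, "condition_map.csv"),
             truth = file.path(dir, "truth.csv"),
             latent_states = file.path(dir, "latent_states.csv"))
  utils::write.csv(ds@counts, paths["counts"], row.names = FALSE)
  utils::write.csv(ds@meta, paths["meta"], row.names = FALSE)
  cmap <- ds@meta[, c("presentation_id", "condition_key", "condition")]
  utils::write.csv(cmap, paths["condition_map"], row.names = FALSE)
  utils::write.csv(ds@truth, paths["truth"], row.names = FALSE)
  st <- do.call(rbind, lapply(names(ds@latentStates), function(sid)
    data.frame(session_id = sid,
               trial = seq_along(ds@latentStates[[sid]]),
               state = ds@latentStates[[sid]])))
  utils::write.csv(st, paths["latent_states"], row.names = FALSE)
  invisible(paths)
}
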