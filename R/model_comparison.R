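#' Jeffreys-prior posterior for a Poisson rate
#'
#' @param counts non-negative integer counts (length >= 1).
#' @return A \linkS4class{GammaPosterior} with shape \code{sum(counts) + 1/2}
#'   and rate \code{length(counts)}.
#' @examples
#' ratePosterior(c(4, 5, 3))  # Gamma(12.5, 3)
#' @export
ratePosterior <- function(counts) {
  counts <- .checkCounts(counts)
  new("GammaPosterior", shape = sum(counts) + 0.5, rate = as.numeric(length(counts)))
}

#' @rdname ratePosterior
#' @param x a \linkS4class{GammaPosterior}.
#' @return \code{posteriorMean}: the posterior mean shape/rate.
#' @export
posteriorMean <- function(x) x@shape / x@rate

#' Quadrature configuration for the mixture and range hypotheses
#'
#' @param nAlpha number of Simpson nodes for the mixing-weight integral
#'   (odd, >= 101; default 201).
#' @param nDraws number of Monte-Carlo draws of the single-stimulus rate pair
#'   (>= 2000; default 4000).
#' @param upperFactor finite upper bound of the 'outside' region, as a
#'   multiple of the larger single-stimulus rate (> 1; default 10).
#' @param rateMethod how the rate-pair integral is evaluated: "mc"
#'   (default) draws \code{nDraws} posterior samples; "quantile" uses a
#'   deterministic tensor grid of posterior quantile midpoints of about
#'   \code{nDraws} nodes, useful for high-precision validation against
#'   brute-force integration (no Monte-Carlo error).
#' @return list of quadrature settings.
#' @export
mixtureQuad <- function(nAlpha = 201, nDraws = 4000, upperFactor = 10,
                        rateMethod = c("mc", "quantile")) {
  if (nAlpha < 101 || nAlpha %% 2 == 0) stop("nAlpha must be odd and >= 101")
  if (nDraws < 2000) stop("nDraws must be >= 2000")
  if (upperFactor <= 1) stop("upperFactor must be > 1")
  list(nAlpha = as.integer(nAlpha), nDraws = as.integer(nDraws),
       upperFactor = upperFactor, rateMethod = match.arg(rateMethod))
}

## probability-cell breakpoints in (0, 1) for one dimension: uniform interior
## cells plus geometrically refined tails down to 1e-14, so posterior-tail
## contributions are not truncated
.uCells <- function(nInterior, perDecade) {
  lo <- 10^seq(-14, log10(0.05),
               length.out = max(2L, ceiling(12.7 * perDecade)))
  breaks <- sort(unique(c(0, lo, seq(0.05, 0.95, length.out = nInterior),
                          rev(1 - lo), 1)))
  list(mid = (breaks[-1] + breaks[-length(breaks)]) / 2, w = diff(breaks))
}

## rate-pair nodes from two gamma posteriors: posterior draws (ties rejected)
## with uniform log weights, or a deterministic tensor grid of
## tail-refined probability cells (node = cell-midpoint quantile, weight =
## cell mass); per-dim sizes differ so identical posteriors cannot tie
.ratePairs <- function(post1, post2, quad) {
  if (identical(quad$rateMethod, "quantile")) {
    n1 <- as.integer(ceiling(sqrt(quad$nDraws)))
    pd <- max(8L, as.integer(round(n1 / 5)))
    g1 <- .uCells(n1, pd)
    g2 <- .uCells(n1 + 1L, pd)
    q1 <- stats::qgamma(g1$mid, post1@shape, rate = post1@rate)
    q2 <- stats::qgamma(g2$mid, post2@shape, rate = post2@rate)
    return(list(l1 = rep(q1, times = length(q2)),
                l2 = rep(q2, each = length(q1)),
                logw = log(rep(g1$w, times = length(q2))) +
                  log(rep(g2$w, each = length(q1))),
                mc = FALSE))
  }
  l1 <- stats::rgamma(quad$nDraws, post1@shape, rate = post1@rate)
  l2 <- stats::rgamma(quad$nDraws, post2@shape, rate = post2@rate)
  bad <- which(l1 == l2)
  while (length(bad)) {
    l1[bad] <- stats::rgamma(length(bad), post1@shape, rate = post1@rate)
    l2[bad] <- stats::rgamma(length(bad), post2@shape, rate = post2@rate)
    bad <- bad[l1[bad] == l2[bad]]
  }
  list(l1 = l1, l2 = l2, logw = rep(-log(quad$nDraws), quad$nDraws),
       mc = TRUE)
}

## weighted log-sum-exp + delta-method Monte-Carlo SE on the log scale (SE is
## NA for deterministic quadrature nodes)
.logMeanExpSE <- function(lx, logw, mc = TRUE) {
  lx <- lx + logw
  m <- max(lx)
  if (!is.finite(m)) stop("all Monte-Carlo integrands underflowed")
  v <- exp(lx - m)
  list(logml = m + log(sum(v)),
       mcSE = if (mc) stats::sd(v) / (mean(v) * sqrt(length(v)))
              else NA_real_)
}

#' Log marginal likelihood under the 'single' hypothesis
#'
#' The dual-stimulus rate equals one single-stimulus rate exactly, so the AB
#' counts are scored by the gamma-Poisson (negative-binomial) posterior
#' predictive of that condition's rate posterior, in closed form.
#'
#' @param countsAB dual-stimulus counts (may be empty: log marginal 0).
#' @param post a \linkS4class{GammaPosterior} for the candidate rate.
#' @return log marginal likelihood.
#' @export
logMargSingle <- function(countsAB, post) {
  stopifnot(is(post, "GammaPosterior"))
  if (!length(countsAB)) return(0)
  y <- .checkCounts(countsAB, "countsAB")
  m <- length(y); S <- sum(y)
  post@shape * log(post@rate) - lgamma(post@shape) +
    lgamma(post@shape + S) - (post@shape + S) * log(post@rate + m) -
    sum(lgamma(y + 1))
}

## conditional log marginal of AB counts given a rate region (lo, hi) with a
## truncated, renormalized Jeffreys density; vectorized over draws
.lmargRegion <- function(S, m, lfac, lo, hi, lnorm) {
  lgamma(S + 0.5) - (S + 0.5) * log(m) +
    logPgammaDiff(lo, hi, S + 0.5, m) - lnorm + lfac
}

#' Log marginal likelihood under the 'intermediate' hypothesis
#'
#' The dual-stimulus rate lies strictly between the two single-stimulus
#' rates. For each Monte-Carlo draw of the rate pair from its posteriors, the
#' AB likelihood is integrated against a Jeffreys density truncated and
#' renormalized on the open interval between the drawn rates (closed form via
#' incomplete-gamma functions), then averaged over draws.
#'
#' @param countsAB dual-stimulus counts.
#' @param postA,postB \linkS4class{GammaPosterior} objects for the two
#'   single-stimulus rates.
#' @param quad quadrature settings from \code{\link{mixtureQuad}}.
#' @param seed optional RNG seed.
#' @return list with \code{logml} and \code{mcSE}.
#' @export
logMargIntermediate <- function(countsAB, postA, postB,
                                quad = mixtureQuad(), seed = NULL) {
  if (!length(countsAB)) return(list(logml = 0, mcSE = 0))
  y <- .checkCounts(countsAB, "countsAB")
  withSeed(seed, {
    d <- .ratePairs(postA, postB, quad)
    lo <- pmin(d$l1, d$l2); hi <- pmax(d$l1, d$l2)
    lx <- .lmargRegion(sum(y), length(y), -sum(lgamma(y + 1)), lo, hi,
                       log(2 * (sqrt(hi) - sqrt(lo))))
    .logMeanExpSE(lx, d$logw, d$mc)
  })
}

#' Log marginal likelihood under the 'outside' hypothesis
#'
#' The dual-stimulus rate lies outside the range spanned by the two
#' single-stimulus rates. The Jeffreys density is truncated and renormalized
#' on \code{(0, min) U (max, max * upperFactor)} per draw; the finite upper
#' bound is required because the Jeffreys prior is not normalizable on an
#' unbounded region, and sensitivity to it should be reported (see
#' \code{\link{outsideSensitivity}}).
#'
#' @inheritParams logMargIntermediate
#' @return list with \code{logml} and \code{mcSE}.
#' @export
logMargOutside <- function(countsAB, postA, postB, quad = mixtureQuad(),
                           seed = NULL) {
  if (!length(countsAB)) return(list(logml = 0, mcSE = 0))
  y <- .checkCounts(countsAB, "countsAB")
  U <- quad$upperFactor
  withSeed(seed, {
    d <- .ratePairs(postA, postB, quad)
    lo <- pmin(d$l1, d$l2); hi <- pmax(d$l1, d$l2)
    S <- sum(y); m <- length(y); lfac <- -sum(lgamma(y + 1))
    lnorm <- log(2 * sqrt(lo) + 2 * (sqrt(U * hi) - sqrt(hi)))
    lmassLow <- logPgammaDiff(numeric(length(lo)), lo, S + 0.5, m)
    lmassHigh <- logPgammaDiff(hi, U * hi, S + 0.5, m)
    lmass <- logAddExp(lmassLow, lmassHigh)
    lx <- lgamma(S + 0.5) - (S + 0.5) * log(m) + lmass - lnorm + lfac
    .logMeanExpSE(lx, d$logw, d$mc)
  })
}

#' Log marginal likelihood under the 'mixture' hypothesis
#'
#' Each dual-stimulus count arises from the A component with probability
#' \eqn{\alpha} and from the B component otherwise:
#' \eqn{\alpha\,\mathrm{Poi}(\lambda_A) + (1-\alpha)\,\mathrm{Poi}(\lambda_B)}
#' with a uniform prior on \eqn{\alpha} in [0, 1]. The \eqn{\alpha} integral
#' uses composite Simpson quadrature nested inside Monte-Carlo draws of the
#' rate pair from its single-stimulus posteriors. Also returns the posterior
#' summary of \eqn{\alpha} and per-presentation assignment scores computed
#' from the same draws and weights.
#'
#' @inheritParams logMargIntermediate
#' @param details also compute the mixing-weight posterior summary and the
#'   assignment scores (default TRUE; FALSE roughly halves the cost when
#'   only the marginal is needed).
#' @return list with \code{logml}, \code{mcSE}, \code{alphaMean},
#'   \code{alphaCI} and \code{scores}.
#' @export
logMargMixture <- function(countsAB, postA, postB, quad = mixtureQuad(),
                           seed = NULL, details = TRUE) {
  if (!length(countsAB))
    return(list(logml = 0, mcSE = 0, alphaMean = 0.5,
                alphaCI = c(0.025, 0.975), scores = numeric(0)))
  y <- .checkCounts(countsAB, "countsAB")
  withSeed(seed, {
    d <- .ratePairs(postA, postB, quad)
    res <- cpp_mixture_marglik(y, d$l1, d$l2, quad$nAlpha, d$logw, details)
    if (!d$mc) res$mc_se <- NA_real_
    list(logml = res$logml, mcSE = res$mc_se, alphaMean = res$alpha_mean,
         alphaCI = res$alpha_ci, scores = res$scores)
  })
}

#' Classify a triplet across the four dual-stimulus hypotheses
#'
#' Computes the posterior probability of each hypothesis for the AB
#' spike-count distribution -- 'single' (rate equals one single-stimulus
#' rate; an equal-weight average of the A and B sub-models), 'outside',
#' 'intermediate', and 'mixture' -- under the equal 1/4 model prior, with the
#' single-stimulus rates conditioned on the A-alone/B-alone data via their
#' Jeffreys conjugate posteriors. Reports the winner and its winning
#' probability (confidence conventions: >= 0.67 means the winner is at least
#' twice as likely as the best alternative; > 0.5 means at least as likely as
#' all alternatives combined), the mixing-weight posterior, and assignment
#' scores.
#'
#' Internally the computation always runs in a canonical orientation (the
#' condition with the higher posterior-mean rate first) so that swapping the
#' A and B labels gives bit-identical marginals, the same category, and
#' scores mapped exactly to \code{1 - s}.
#'
#' @param triplet a \linkS4class{Triplet}.
#' @param quad quadrature settings from \code{\link{mixtureQuad}}.
#' @param seed optional RNG seed (recorded in the result).
#' @param screen optional \linkS4class{ScreenResult} for the triplet; if
#'   omitted it is computed. Classification refuses triplets that fail the
#'   screen unless \code{force = TRUE}.
#' @param force classify even if the screen failed.
#' @param details also compute the mixing-weight posterior and assignment
#'   scores (default TRUE); FALSE is faster when only the posterior over
#'   hypotheses is needed.
#' @param ... passed to \code{\link{screenTriplet}} when screening here.
#' @return A \linkS4class{ModelPosterior}.
#' @examples
#' tr <- Triplet("u1", "c1", rpois(21, 20), rpois(21, 5),
#'               c(rpois(9, 20), rpois(9, 5)))
#' classifyTriplet(tr, seed = 1, force = TRUE)
#' @export
classifyTriplet <- function(triplet, quad = mixtureQuad(), seed = NULL,
                            screen = NULL, force = FALSE, details = TRUE,
                            ...) {
  stopifnot(is(triplet, "Triplet"))
  if (!force) {
    if (is.null(screen))
      screen <- screenTriplet(triplet, seed = childSeed(seed, 99), ...)
    if (!passed(screen))
      stop("triplet failed the inclusion screen (",
           paste(failReasons(screen), collapse = "; "),
           "); use force = TRUE to classify anyway")
  }
  postA <- ratePosterior(countsA(triplet))
  postB <- ratePosterior(countsB(triplet))
  y <- countsAB(triplet)

  ## canonical orientation: higher posterior-mean condition is component 1
  aFirst <- posteriorMean(postA) > posteriorMean(postB) ||
    (posteriorMean(postA) == posteriorMean(postB) &&
     postA@rate >= postB@rate)
  p1 <- if (aFirst) postA else postB
  p2 <- if (aFirst) postB else postA

  lmS1 <- logMargSingle(y, p1)
  lmS2 <- logMargSingle(y, p2)
  lmSingle <- log(0.5) + logSumExp(c(lmS1, lmS2))
  lmInt <- logMargIntermediate(y, p1, p2, quad, seed = childSeed(seed, 11))
  lmOut <- logMargOutside(y, p1, p2, quad, seed = childSeed(seed, 12))
  lmMix <- logMargMixture(y, p1, p2, quad, seed = childSeed(seed, 13),
                          details = details)

  lp <- c(single = lmSingle, outside = lmOut$logml,
          intermediate = lmInt$logml, mixture = lmMix$logml)
  post <- exp(lp - logSumExp(lp))   # equal 1/4 prior cancels
  post <- post / sum(post)
  win <- names(post)[which.max(post)]

  if (aFirst || !details) {
    aMean <- lmMix$alphaMean; aCI <- lmMix$alphaCI; sc <- lmMix$scores
  } else {
    aMean <- 1 - lmMix$alphaMean
    aCI <- rev(1 - lmMix$alphaCI)
    sc <- 1 - lmMix$scores
  }
  new("ModelPosterior", posterior = post, logml = lp, winner = win,
      winProb = unname(max(post)), mcSE = lmMix$mcSE,
      alphaMean = aMean, alphaCI = aCI, scores = sc,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      quad = quad)
}

#' @rdname assignmentScores
#' @param method "bayes" (stored fully Bayesian scores) or "plugin"
#'   (posterior-mean plug-in, see \code{\link{pluginAssignmentScores}}).
#' @export
setMethod("assignmentScores", "Triplet", function(x, method = c("bayes", "plugin"), ...) {
  method <- match.arg(method)
  mp <- classifyTriplet(x, ...)
  if (method == "bayes") return(mp@scores)
  pluginAssignmentScores(countsAB(x), alphaMean(mp),
                         posteriorMean(ratePosterior(countsA(x))),
                         posteriorMean(ratePosterior(countsB(x))))
})

#' Plug-in assignment scores
#'
#' The plug-in variant of the assignment score: the posterior probability
#' that each count arose from the A component, evaluated at point estimates
#' \eqn{\hat\alpha, \hat\lambda_A, \hat\lambda_B} instead of averaging over
#' the posterior.
#'
#' @param countsAB dual-stimulus counts.
#' @param alpha mixing weight on the A component.
#' @param lambdaA,lambdaB component rates.
#' @return numeric scores in [0, 1].
#' @examples
#' pluginAssignmentScores(0:10, 0.5, 20, 5)
#' @export
pluginAssignmentScores <- function(countsAB, alpha, lambdaA, lambdaB) {
  y <- .checkCounts(countsAB, "countsAB")
  la <- log(alpha) + stats::dpois(y, lambdaA, log = TRUE)
  lb <- log1p(-alpha) + stats::dpois(y, lambdaB, log = TRUE)
  1 / (1 + exp(lb - la))
}

#' Sensitivity of the classification to the 'outside' upper bound
#'
#' The 'outside' hypothesis needs a finite upper bound (default 10 times the
#' larger single-stimulus rate) to normalize its truncated Jeffreys density.
#' This diagnostic reclassifies with the bound doubled and reports the change
#' in the winner's posterior probability.
#'
#' @param triplet a \linkS4class{Triplet}.
#' @param quad quadrature settings.
#' @param seed optional RNG seed.
#' @param ... passed to \code{\link{classifyTriplet}}.
#' @return list with both fits and \code{deltaWinProb}, the absolute change
#'   in the original winner's posterior probability.
#' @export
outsideSensitivity <- function(triplet, quad = mixtureQuad(), seed = NULL,
                               ...) {
  fit1 <- classifyTriplet(triplet, quad = quad, seed = seed, ...)
  quad2 <- quad; quad2$upperFactor <- 2 * quad$upperFactor
  fit2 <- classifyTriplet(triplet, quad = quad2, seed = seed, ...)
  list(fit = fit1, fitDoubled = fit2,
       deltaWinProb = abs(modelPosterior(fit2)[winner(fit1)] -
                          winProb(fit1)))
}

#' Classify a list of triplets
#'
#' @param tripletList list of \linkS4class{Triplet} objects.
#' @param screens optional list of \linkS4class{ScreenResult} objects aligned
#'   with \code{tripletList}.
#' @param quad quadrature settings.
#' @param seed optional base seed; each triplet gets a derived child seed.
#' @param ... passed to \code{\link{classifyTriplet}}.
#' @return data.frame (one row per triplet: posteriors, winner, win_prob,
#'   alpha summaries, mc_se) with the \linkS4class{ModelPosterior} objects in
#'   attribute \code{"results"}.
#' @export
classifyTriplets <- function(tripletList, screens = NULL,
                             quad = mixtureQuad(), seed = NULL, ...) {
  res <- vector("list", length(tripletList))
  for (i in seq_along(tripletList))
    res[[i]] <- classifyTriplet(tripletList[[i]],
                                screen = if (!is.null(screens)) screens[[i]],
                                quad = quad, seed = childSeed(seed, i), ...)
  df <- data.frame(
    unit_id = vapply(tripletList, unitId, ""),
    condition_key = vapply(tripletList, conditionKey, ""),
    p_single = vapply(res, function(r) r@posterior["single"], 0),
    p_outside = vapply(res, function(r) r@posterior["outside"], 0),
    p_intermediate = vapply(res, function(r) r@posterior["intermediate"], 0),
    p_mixture = vapply(res, function(r) r@posterior["mixture"], 0),
    winner = vapply(res, winner, ""),
    win_prob = vapply(res, winProb, 0),
    alpha_mean = vapply(res, alphaMean, 0),
    alpha_lo = vapply(res, function(r) r@alphaCI[1], 0),
    alpha_hi = vapply(res, function(r) r@alphaCI[2], 0),
    mc_se = vapply(res, function(r) r@mcSE, 0))
  attr(df, "results") <- res
  df
}
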