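#' Monte-Carlo chi-square goodness of fit to a Poisson
#'
#' Tests whether a sample of spike counts is consistent with a Poisson
#' distribution at the sample-mean rate. The chi-square statistic is computed
#' on integer-valued bins (0, 1, ...) with the right tail pooled so its
#' expected count is at least 1, and the null distribution is simulated by
#' redrawing same-size samples from the fitted Poisson, refitting the rate
#' (and rebinning) for every simulated sample. The add-one correction keeps
#' the p-value strictly positive. Triplets are retained downstream when
#' p > 0.10.
#'
#' @param counts non-negative integer counts (length >= 3).
#' @param nMC number of Monte-Carlo simulations (>= 1000; default 2000).
#' @param seed optional RNG seed for reproducibility.
#' @return Monte-Carlo p-value in (0, 1].
#' @examples
#' poissonGofPvalue(rpois(21, 10), seed = 1)
#' @export
poissonGofPvalue <- function(counts, nMC = 2000, seed = NULL) {
  counts <- .checkCounts(counts)
  if (length(counts) < 3) stop("need at least 3 counts")
  if (nMC < 1000) stop("nMC must be at least 1000")
  withSeed(seed, cpp_gof_pvalue(counts, as.integer(nMC)))
}

## formal (Jeffreys) log marginal likelihood of a Poisson sample, without the
## 1/prod(y!) factor, which cancels in all Bayes-factor ratios below
.lmargJeffreys <- function(S, n) lgamma(S + 0.5) - (S + 0.5) * log(n)

#' Bayes factor for separated single-stimulus rates
#'
#' Evidence that the A and B single-stimulus Poisson rates differ:
#' BF(\eqn{\lambda_A \neq \lambda_B} vs \eqn{\lambda_A = \lambda_B}) under
#' Jeffreys priors, made proper either by the intrinsic device (arithmetic
#' average of the correction over minimal training samples, one observation
#' drawn from each condition) or by the fractional device (fractional Bayes
#' factor with per-condition training fraction 1/n). Downstream screening
#' requires BF > 3.
#'
#' @param countsA,countsB non-negative integer counts (length >= 2 each).
#' @param method "intrinsic" (default) or "fractional".
#' @return positive Bayes factor; values > 3 indicate substantial separation.
#' @details The intrinsic correction enumerates every minimal training
#' sample (all \eqn{n_A \times n_B} one-observation-per-condition pairs);
#' since each term is closed-form this is exact, deterministic and symmetric
#' in the two conditions, with no need for subsampling.
#' @examples
#' separationBayesFactor(rpois(20, 20), rpois(20, 5))
#' @export
separationBayesFactor <- function(countsA, countsB,
                                  method = c("intrinsic", "fractional")) {
  method <- match.arg(method)
  countsA <- .checkCounts(countsA, "countsA")
  countsB <- .checkCounts(countsB, "countsB")
  nA <- length(countsA); nB <- length(countsB)
  if (nA < 2 || nB < 2) stop("need at least 2 counts per condition")
  SA <- sum(countsA); SB <- sum(countsB)
  ## formal Bayes factor with improper Jeffreys priors
  logBN10 <- .lmargJeffreys(SA, nA) + .lmargJeffreys(SB, nB) -
    .lmargJeffreys(SA + SB, nA + nB)
  if (method == "intrinsic") {
    ## correction: average of m0(z)/m1(z) over all minimal training samples
    pairs <- expand.grid(u = countsA, v = countsB)
    lm0z <- .lmargJeffreys(pairs$u + pairs$v, 2)
    lm1z <- lgamma(pairs$u + 0.5) + lgamma(pairs$v + 0.5)
    logCF <- logMeanExp(lm0z - lm1z)
  } else {
    bA <- 1 / nA; bB <- 1 / nB
    lm1f <- .lmargJeffreys(bA * SA, bA * nA) + .lmargJeffreys(bB * SB, bB * nB)
    lm0f <- .lmargJeffreys(bA * SA + bB * SB, bA * nA + bB * nB)
    logCF <- lm0f - lm1f
  }
  exp(logBN10 + logCF)
}

#' Screen a triplet for inclusion
#'
#' Applies the two inclusion criteria used before any model comparison:
#' both single-stimulus count distributions must be consistent with a Poisson
#' (Monte-Carlo GOF p > 0.10 each) and the two rates must be substantially
#' separated (intrinsic Bayes factor > 3). A minimum trial count per
#' condition is also enforced.
#'
#' @param triplet a \linkS4class{Triplet}.
#' @param gofThreshold GOF retention threshold (default 0.10).
#' @param bfThreshold separation Bayes-factor threshold (default 3).
#' @param minTrials minimum presentations per condition (default 5).
#' @param nMC Monte-Carlo simulations for the GOF test (default 2000).
#' @param method Bayes-factor variant, see
#'   \code{\link{separationBayesFactor}}.
#' @param seed optional RNG seed.
#' @return A \linkS4class{ScreenResult}.
#' @export
screenTriplet <- function(triplet, gofThreshold = 0.10, bfThreshold = 3,
                          minTrials = 5, nMC = 2000,
                          method = c("intrinsic", "fractional"),
                          seed = NULL) {
  stopifnot(is(triplet, "Triplet"))
  method <- match.arg(method)
  pA <- poissonGofPvalue(countsA(triplet), nMC = nMC,
                         seed = childSeed(seed, 1))
  pB <- poissonGofPvalue(countsB(triplet), nMC = nMC,
                         seed = childSeed(seed, 2))
  bf <- separationBayesFactor(countsA(triplet), countsB(triplet),
                              method = method)
  reasons <- character(0)
  if (min(length(countsA(triplet)), length(countsB(triplet)),
          length(countsAB(triplet))) < minTrials)
    reasons <- c(reasons, "too few trials")
  if (pA <= gofThreshold) reasons <- c(reasons, "A not Poisson")
  if (pB <= gofThreshold) reasons <- c(reasons, "B not Poisson")
  if (bf <= bfThreshold) reasons <- c(reasons, "rates not separated")
  new("ScreenResult", gofPA = pA, gofPB = pB, separationBF = bf,
      passed = length(reasons) == 0L, failReasons = reasons,
      gofThreshold = gofThreshold, bfThreshold = bfThreshold)
}

#' Screen a list of triplets
#'
#' @param tripletList list of \linkS4class{Triplet} objects.
#' @param ... passed to \code{\link{screenTriplet}}.
#' @param seed optional base seed; each triplet gets a derived child seed.
#' @return data.frame with one row per triplet (unit, condition, p-values,
#'   BF, pass flag, collapsed reasons) and the ScreenResult objects as an
#'   attribute \code{"results"}.
#' @export
screenTriplets <- function(tripletList, ..., seed = NULL) {
  res <- vector("list", length(tripletList))
  for (i in seq_along(tripletList))
    res[[i]] <- screenTriplet(tripletList[[i]], ...,
                              seed = childSeed(seed, i))
  df <- data.frame(
    unit_id = vapply(tripletList, unitId, ""),
    condition_key = vapply(tripletList, conditionKey, ""),
    gof_p_A = vapply(res, function(r) r@gofPA, 0),
    gof_p_B = vapply(res, function(r) r@gofPB, 0),
    separation_bf = vapply(res, function(r) r@separationBF, 0),
    passed = vapply(res, passed, TRUE),
    fail_reasons = vapply(res, function(r)
      paste(r@failReasons, collapse = "; "), ""))
  attr(df, "results") <- res
  df
}

#' Assemble triplets from a count table and a condition map
#'
#' Groups kept presentations into (A, B, AB) triplets per unit and stimulus
#' pairing. Units x pairings with any condition missing or below
#' \code{minTrials} presentations are dropped and reported in the
#' \code{"dropped"} attribute.
#'
#' @param sce a \linkS4class{SpikeCountExperiment}.
#' @param conditionMap data.frame with \code{presentation_id},
#'   \code{condition_key}, \code{condition}; defaults to those columns of
#'   \code{colData(sce)}.
#' @param keep optional character vector of presentation ids retained by
#'   \code{\link{filterPresentations}}; defaults to all.
#' @param minTrials minimum presentations per condition (default 5).
#' @return list of \linkS4class{Triplet} objects.
#' @export
makeTriplets <- function(sce, conditionMap = NULL, keep = NULL,
                         minTrials = 5) {
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  if (is.null(conditionMap)) {
    if (!"condition_key" %in% names(cd))
      stop("colData lacks condition_key; supply a conditionMap")
    conditionMap <- data.frame(presentation_id = rownames(cd),
                               condition_key = cd$condition_key,
                               condition = cd$condition)
  }
  if (is.null(keep)) keep <- as.character(conditionMap$presentation_id)
  cm <- conditionMap[conditionMap$presentation_id %in% keep, , drop = FALSE]
  cts <- spikeCounts(sce)
  out <- list(); dropped <- character(0)
  for (ck in unique(cm$condition_key)) {
    sub <- cm[cm$condition_key == ck, ]
    ids <- lapply(c(A = "A", B = "B", AB = "AB"), function(cc)
      as.character(sub$presentation_id[sub$condition == cc]))
    for (u in rownames(cts)) {
      if (any(vapply(ids, length, 0L) < minTrials)) {
        dropped <- c(dropped, paste0(u, "/", ck)); next
      }
      out[[paste0(u, "/", ck)]] <- Triplet(
        u, ck,
        countsA = cts[u, ids$A], countsB = cts[u, ids$B],
        countsAB = cts[u, ids$AB],
        presA = ids$A, presB = ids$B, presAB = ids$AB)
    }
  }
  attr(out, "dropped") <- unique(dropped)
  out
}
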