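#' Trial-wise population score matrix
#'
#' Collects the per-trial assignment scores of units whose dual-stimulus
#' responses were classified as 'mixture' with winning probability above the
#' selection threshold (default 0.5: 'mixture' at least as likely as all
#' alternatives combined), across the shared dual-stimulus trials of one
#' condition. Rows are units, columns trials; red/blue style summaries read
#' scores near 1 as A-like and near 0 as B-like.
#'
#' @param classifications list of \linkS4class{ModelPosterior} objects for
#'   units sharing the same dual-stimulus trial set.
#' @param unitIds unit identifiers aligned with \code{classifications}.
#' @param selectionThreshold minimum mixture winning probability (default
#'   0.5).
#' @return A \linkS4class{TrialScoreMatrix}; zero rows (with an
#'   \code{empty} attribute) when no unit passes selection.
#' @export
buildTrialMatrix <- function(classifications, unitIds = NULL,
                             selectionThreshold = 0.5) {
  if (is.null(unitIds)) unitIds <- paste0("unit", seq_along(classifications))
  sel <- vapply(classifications, function(m)
    winner(m) == "mixture" && winProb(m) > selectionThreshold, TRUE)
  if (!any(sel)) {
    m <- new("TrialScoreMatrix",
             scores = matrix(numeric(0), 0, 0),
             selectionThreshold = selectionThreshold)
    attr(m, "empty") <- TRUE
    return(m)
  }
  sc <- lapply(classifications[sel], assignmentScores)
  nt <- unique(vapply(sc, length, 0L))
  if (length(nt) != 1)
    stop("selected units do not share the same trial set")
  mat <- do.call(rbind, sc)
  dimnames(mat) <- list(unitIds[sel], paste0("trial", seq_len(nt)))
  new("TrialScoreMatrix", scores = mat,
      selectionThreshold = selectionThreshold)
}

#' Per-trial and per-cell score histograms
#'
#' Bins the score matrix on uniform bins over [0, 1]: for each trial, how
#' many cells responded at each A-like/B-like level, and for each cell, on
#' how many trials it responded at each level. Per-trial histograms sum to
#' the number of units; per-cell histograms to the number of trials.
#'
#' @param m a \linkS4class{TrialScoreMatrix}.
#' @param nBins number of uniform bins (default 10).
#' @return list with matrices \code{perTrial} (trials x bins) and
#'   \code{perCell} (units x bins), and \code{breaks}.
#' @export
scoreHistograms <- function(m, nBins = 10) {
  sc <- scoreMatrix(m)
  if (!length(sc)) stop("empty score matrix")
  breaks <- seq(0, 1, length.out = nBins + 1)
  bin <- function(v) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE)
    tabulate(b, nbins = nBins)
  }
  perTrial <- t(apply(sc, 2, bin))
  perCell <- t(apply(sc, 1, bin))
  dimnames(perTrial) <- list(colnames(sc), paste0("bin", seq_len(nBins)))
  dimnames(perCell) <- list(rownames(sc), paste0("bin", seq_len(nBins)))
  list(perTrial = perTrial, perCell = perCell, breaks = breaks)
}

#' Attention-locked comparator simulation
#'
#' What the population matrix would look like if the trial-to-trial
#' fluctuations reflected a single covert factor (e.g. attention) shared by
#' all cells: each cell keeps its observed multiset of scores, but rows are
#' rank-aligned (each row sorted, then all columns shuffled by one shared
#' random permutation), which maximizes across-row correlation given the
#' marginals.
#'
#' @param m a \linkS4class{TrialScoreMatrix}.
#' @param seed optional RNG seed.
#' @return A \linkS4class{TrialScoreMatrix} of the same shape.
#' @export
simulateAttentionLocked <- function(m, seed = NULL) {
  sc <- scoreMatrix(m)
  if (!length(sc)) stop("empty score matrix")
  sorted <- t(apply(sc, 1, sort))
  perm <- withSeed(seed, sample.int(ncol(sc)))
  out <- sorted[, perm, drop = FALSE]
  dimnames(out) <- dimnames(sc)
  new("TrialScoreMatrix", scores = out,
      selectionThreshold = m@selectionThreshold)
}

#' Averaging comparator simulation
#'
#' What the population matrix would look like if cells did not fluctuate but
#' averaged their inputs: every cell x trial score is an independent draw
#' from a normal distribution (default mean 0.34, SD 0.10, matching the
#' observed score distribution it emulates), clipped to [0, 1].
#'
#' @param nUnits,nTrials matrix dimensions.
#' @param mean,sd normal parameters (defaults 0.34 and 0.10).
#' @param seed optional RNG seed.
#' @return A \linkS4class{TrialScoreMatrix}.
#' @export
simulateAveraging <- function(nUnits, nTrials, mean = 0.34, sd = 0.10,
                              seed = NULL) {
  stopifnot(nUnits >= 1, nTrials >= 1, sd >= 0)
  draws <- withSeed(seed, stats::rnorm(nUnits * nTrials, mean, sd))
  sc <- matrix(pmin(1, pmax(0, draws)), nUnits, nTrials,
               dimnames = list(paste0("unit", seq_len(nUnits)),
                               paste0("trial", seq_len(nTrials))))
  new("TrialScoreMatrix", scores = sc, selectionThreshold = NA_real_)
}

#' Mean pairwise across-row correlation of a score matrix
#'
#' @param m a \linkS4class{TrialScoreMatrix} (>= 2 rows).
#' @return mean Pearson correlation over all unordered row pairs (constant
#'   rows are skipped).
#' @export
meanPairwiseCorrelation <- function(m) {
  sc <- scoreMatrix(m)
  if (nrow(sc) < 2) stop("need at least 2 rows")
  keep <- apply(sc, 1, stats::sd) > 0
  cm <- stats::cor(t(sc[keep, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}

#' Normalized-rate trial scores
#'
#' Alternative per-trial score: the dual-stimulus count rescaled between the
#' two single-stimulus rate estimates,
#' \eqn{(y - \hat\lambda_B) / (\hat\lambda_A - \hat\lambda_B)}, clipped to
#' [0, 1]. Selectable in place of the assignment score for population views.
#'
#' @param triplet a \linkS4class{Triplet}.
#' @return numeric scores in [0, 1], one per AB presentation.
#' @export
normalizedRateScores <- function(triplet) {
  lamA <- posteriorMean(ratePosterior(countsA(triplet)))
  lamB <- posteriorMean(ratePosterior(countsB(triplet)))
  if (lamA == lamB) stop("single-stimulus rates are equal")
  pmin(1, pmax(0, (countsAB(triplet) - lamB) / (lamA - lamB)))
}
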