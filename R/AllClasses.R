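#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rpois
#' @useDynLib spikemux, .registration = TRUE
NULL

#' Gamma posterior for a Poisson rate
#'
#' Conjugate posterior of a Poisson rate under the Jeffreys prior
#' \eqn{\pi(\lambda) \propto \lambda^{-1/2}}: observing \eqn{n} counts with
#' sum \eqn{S} gives \eqn{\lambda \mid y \sim \mathrm{Gamma}(S + 1/2, n)}
#' (shape, rate).
#'
#' @slot shape positive shape parameter.
#' @slot rate positive rate parameter (the number of observations).
#' @export
setClass("GammaPosterior",
  representation(shape = "numeric", rate = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 1 || length(object@rate) != 1)
      return("shape and rate must be scalars")
    if (!is.finite(object@shape) || object@shape <= 0) return("shape must be > 0")
    if (!is.finite(object@rate) || object@rate <= 0) return("rate must be > 0")
    TRUE
  })

#' Spike-count triplet for one unit and stimulus pairing
#'
#' The atomic analysis unit: one unit's spike counts across A-alone, B-alone
#' and dual (AB) presentations of a given stimulus pairing. Presentation ids
#' are optional but required to align AB trials across units in pair and
#' population analyses.
#'
#' @slot unitId unit identifier.
#' @slot conditionKey identifier of the A/B stimulus pairing.
#' @slot countsA,countsB,countsAB non-negative integer spike counts.
#' @slot presA,presB,presAB presentation identifiers aligned with the counts
#'   (may be empty).
#' @export
setClass("Triplet",
  representation(unitId = "character", conditionKey = "character",
                 countsA = "integer", countsB = "integer",
                 countsAB = "integer",
                 presA = "character", presB = "character",
                 presAB = "character"),
  validity = function(object) {
    for (s in c("countsA", "countsB", "countsAB")) {
      x <- slot(object, s)
      if (!length(x)) return(paste(s, "must be non-empty"))
      if (anyNA(x) || any(x < 0)) return(paste(s, "must be non-negative"))
    }
    for (p in list(c("presA", "countsA"), c("presB", "countsB"),
                   c("presAB", "countsAB"))) {
      ids <- slot(object, p[1])
      if (length(ids) && length(ids) != length(slot(object, p[2])))
        return(paste(p[1], "must match", p[2], "in length"))
    }
    TRUE
  })

#' Screening result for a triplet
#'
#' Records the two inclusion criteria applied before model comparison:
#' Monte-Carlo chi-square goodness of fit to a Poisson for each
#' single-stimulus distribution (retain if p > 0.10), and an intrinsic Bayes
#' factor requiring the two single-stimulus rates to be substantially
#' separated (retain if BF > 3).
#'
#' @slot gofPA,gofPB Monte-Carlo GOF p-values for the A and B counts.
#' @slot separationBF Bayes factor for \eqn{\lambda_A \neq \lambda_B} vs
#'   \eqn{\lambda_A = \lambda_B}.
#' @slot passed logical; all criteria satisfied.
#' @slot failReasons character vector naming every failed rule.
#' @slot gofThreshold,bfThreshold the thresholds applied.
#' @export
setClass("ScreenResult",
  representation(gofPA = "numeric", gofPB = "numeric",
                 separationBF = "numeric", passed = "logical",
                 failReasons = "character",
                 gofThreshold = "numeric", bfThreshold = "numeric"),
  validity = function(object) {
    ok <- object@gofPA > object@gofThreshold &&
      object@gofPB > object@gofThreshold &&
      object@separationBF > object@bfThreshold &&
      !length(object@failReasons)
    if (!identical(ok, object@passed))
      return("passed flag inconsistent with criteria")
    TRUE
  })

#' Posterior over the four dual-stimulus response hypotheses
#'
#' Posterior probabilities (equal 1/4 prior) of the four hypotheses for the
#' dual-stimulus spike-count distribution -- 'single', 'outside',
#' 'intermediate', 'mixture' -- together with the winning hypothesis, its
#' probability, the mixture-weight posterior summary, and per-presentation
#' assignment scores (posterior probability that each AB count arose from the
#' A component).
#'
#' @slot posterior named numeric(4), summing to 1.
#' @slot logml named numeric(4), log marginal likelihoods.
#' @slot winner name of the maximum-posterior hypothesis.
#' @slot winProb posterior probability of the winner.
#' @slot mcSE Monte-Carlo standard error (log scale) of the mixture marginal.
#' @slot alphaMean posterior mean of the mixing weight on the A component.
#' @slot alphaCI equal-tail 95\% interval for the mixing weight.
#' @slot scores assignment scores, one per AB presentation, in [0, 1].
#' @slot seed,quad reproducibility metadata.
#' @export
setClass("ModelPosterior",
  representation(posterior = "numeric", logml = "numeric",
                 winner = "character", winProb = "numeric", mcSE = "numeric",
                 alphaMean = "numeric", alphaCI = "numeric",
                 scores = "numeric", seed = "integer", quad = "list"),
  validity = function(object) {
    p <- object@posterior
    if (length(p) != 4 || is.null(names(p))) return("posterior must be named numeric(4)")
    if (abs(sum(p) - 1) > 1e-9) return("posterior must sum to 1")
    if (abs(object@winProb - max(p)) > 1e-12) return("winProb must equal max posterior")
    if (!identical(unname(p[object@winner]), unname(object@winProb)) &&
        p[object@winner] != max(p)) return("winner must attain winProb")
    if (length(object@alphaCI) != 2) return("alphaCI must have length 2")
    if (!is.na(object@alphaMean) &&
        (object@alphaCI[1] > object@alphaMean + 1e-12 ||
         object@alphaCI[2] < object@alphaMean - 1e-12))
      return("alphaCI must contain alphaMean")
    if (length(object@scores) &&
        (any(object@scores < 0) || any(object@scores > 1)))
      return("scores must lie in [0, 1]")
    TRUE
  })

#' Spike-count container
#'
#' A \linkS4class{SummarizedExperiment} holding one "counts" assay of
#' non-negative integer spike counts (units x presentations) with the
#' presentation metadata in \code{colData}.
#'
#' @export
setClass("SpikeCountExperiment",
  contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      return("a 'counts' assay is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts) || any(cts < 0)) return("counts must be non-negative")
    TRUE
  })

#' Trial-wise population score matrix
#'
#' Assignment scores of selected (confident-mixture) units across the shared
#' dual-stimulus trials of one condition; the raw material for population
#' views and the attention-locked / averaging comparator simulations.
#'
#' @slot scores numeric matrix in [0, 1], units x trials.
#' @slot selectionThreshold minimum mixture winning probability for inclusion.
#' @export
setClass("TrialScoreMatrix",
  representation(scores = "matrix", selectionThreshold = "numeric"),
  validity = function(object) {
    s <- object@scores
    if (length(s) && (any(s < 0) || any(s > 1))) return("scores must be in [0, 1]")
    TRUE
  })

#' Ground-truth-labelled synthetic dataset
#'
#' @slot triplets list of \linkS4class{Triplet} objects, one per unit and
#'   session.
#' @slot truth data.frame with per-unit generating regime, rates, preference
#'   and implied mixing weight.
#' @slot latentStates list (per session) of per-AB-trial population states
#'   ("A"/"B").
#' @slot meta presentation metadata data.frame (the same schema the readers
#'   consume).
#' @slot counts long-format counts data.frame (unit_id, presentation_id,
#'   count).
#' @slot config the generating \code{populationConfig}.
#' @export
setClass("SyntheticDataset",
  representation(triplets = "list", truth = "data.frame",
                 latentStates = "list", meta = "data.frame",
                 counts = "data.frame", config = "list"),
  validity = function(object) {
    if (nrow(object@truth) != length(object@triplets))
      return("every triplet needs a truth record")
    TRUE
  })
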