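#' Construct a Triplet
#'
#' @param unitId,conditionKey identifiers.
#' @param countsA,countsB,countsAB non-negative integer spike counts for the
#'   A-alone, B-alone and dual-stimulus presentations.
#' @param presA,presB,presAB optional presentation ids aligned with the
#'   counts.
#' @return A \linkS4class{Triplet}.
#' @examples
#' Triplet("u1", "c1", countsA = rpois(21, 20), countsB = rpois(21, 5),
#'         countsAB = rpois(18, 12))
#' @export
Triplet <- function(unitId, conditionKey, countsA, countsB, countsAB,
                    presA = character(), presB = character(),
                    presAB = character()) {
  new("Triplet", unitId = as.character(unitId),
      conditionKey = as.character(conditionKey),
      countsA = .checkCounts(countsA, "countsA"),
      countsB = .checkCounts(countsB, "countsB"),
      countsAB = .checkCounts(countsAB, "countsAB"),
      presA = as.character(presA), presB = as.character(presB),
      presAB = as.character(presAB))
}

#' @rdname accessors
#' @export
setMethod("unitId", "Triplet", function(x) x@unitId)
#' @rdname accessors
#' @export
setMethod("conditionKey", "Triplet", function(x) x@conditionKey)
#' @rdname accessors
#' @export
setMethod("countsA", "Triplet", function(x) x@countsA)
#' @rdname accessors
#' @export
setMethod("countsB", "Triplet", function(x) x@countsB)
#' @rdname accessors
#' @export
setMethod("countsAB", "Triplet", function(x) x@countsAB)

setMethod("show", "Triplet", function(object) {
  cat("Triplet", object@unitId, "/", object@conditionKey, "\n")
  cat(sprintf("  A: n=%d mean=%.2f | B: n=%d mean=%.2f | AB: n=%d mean=%.2f\n",
              length(object@countsA), mean(object@countsA),
              length(object@countsB), mean(object@countsB),
              length(object@countsAB), mean(object@countsAB)))
})

#' @rdname accessors
#' @export
setMethod("passed", "ScreenResult", function(x) x@passed)
#' @rdname accessors
#' @export
setMethod("failReasons", "ScreenResult", function(x) x@failReasons)
#' @rdname accessors
#' @export
setMethod("separationBF", "ScreenResult", function(x) x@separationBF)
#' @rdname accessors
#' @export
setMethod("gofP", "ScreenResult",
          function(x) c(A = x@gofPA, B = x@gofPB))

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %s\n",
              if (object@passed) "PASSED" else "failed"))
  cat(sprintf("  GOF p: A=%.3f B=%.3f (retain if > %.2f)\n",
              object@gofPA, object@gofPB, object@gofThreshold))
  cat(sprintf("  separation BF: %.3g (retain if > %g)\n",
              object@separationBF, object@bfThreshold))
  if (length(object@failReasons))
    cat("  reasons:", paste(object@failReasons, collapse = "; "), "\n")
})

#' @rdname accessors
#' @export
setMethod("modelPosterior", "ModelPosterior", function(x) x@posterior)
#' @rdname accessors
#' @export
setMethod("logMarglik", "ModelPosterior", function(x) x@logml)
#' @rdname accessors
#' @export
setMethod("winner", "ModelPosterior", function(x) x@winner)
#' @rdname accessors
#' @export
setMethod("winProb", "ModelPosterior", function(x) x@winProb)
#' @rdname accessors
#' @export
setMethod("alphaMean", "ModelPosterior", function(x) x@alphaMean)
#' @rdname accessors
#' @export
setMethod("alphaCI", "ModelPosterior", function(x) x@alphaCI)
#' @export
#' @rdname assignmentScores
setMethod("assignmentScores", "ModelPosterior", function(x, ...) x@scores)

setMethod("show", "ModelPosterior", function(object) {
  cat("ModelPosterior\n")
  p <- object@posterior
  for (nm in names(p)) cat(sprintf("  %-13s %.4f\n", nm, p[nm]))
  cat(sprintf("  winner: %s (win prob %.3f%s)\n", object@winner,
              object@winProb,
              if (object@winProb >= 2 / 3) ", confident at 0.67"
              else if (object@winProb > 0.5) ", confident at 0.5" else ""))
  cat(sprintf("  mixing weight alpha: %.3f [%.3f, %.3f]\n",
              object@alphaMean, object@alphaCI[1], object@alphaCI[2]))
})

#' @rdname accessors
#' @export
setMethod("spikeCounts", "SpikeCountExperiment",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "TrialScoreMatrix", function(x) x@scores)

setMethod("show", "TrialScoreMatrix", function(object) {
  cat(sprintf("TrialScoreMatrix: %d units x %d trials (selection > %.2f)\n",
              nrow(object@scores), ncol(object@scores),
              object@selectionThreshold))
})

#' @rdname accessors
#' @export
setMethod("truth", "SyntheticDataset", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("latentStates", "SyntheticDataset", function(x) x@latentStates)
#' @rdname accessors
#' @export
setMethod("triplets", "SyntheticDataset", function(x) x@triplets)

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d triplets, %d session(s)\n",
              length(object@triplets), length(object@latentStates)))
  print(table(object@truth$regime))
})
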