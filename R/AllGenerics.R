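#' Accessors for spikemux classes
#'
#' Small accessor generics: slot access is internal to the package.
#'
#' @param x,object a spikemux object.
#' @param ... passed to methods.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("conditionKey", function(x) standardGeneric("conditionKey"))
#' @rdname accessors
#' @export
setGeneric("countsA", function(x) standardGeneric("countsA"))
#' @rdname accessors
#' @export
setGeneric("countsB", function(x) standardGeneric("countsB"))
#' @rdname accessors
#' @export
setGeneric("countsAB", function(x) standardGeneric("countsAB"))
#' @rdname accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))
#' @rdname accessors
#' @export
setGeneric("failReasons", function(x) standardGeneric("failReasons"))
#' @rdname accessors
#' @export
setGeneric("separationBF", function(x) standardGeneric("separationBF"))
#' @rdname accessors
#' @export
setGeneric("gofP", function(x) standardGeneric("gofP"))
#' @rdname accessors
#' @export
setGeneric("modelPosterior", function(x) standardGeneric("modelPosterior"))
#' @rdname accessors
#' @export
setGeneric("logMarglik", function(x) standardGeneric("logMarglik"))
#' @rdname accessors
#' @export
setGeneric("winner", function(x) standardGeneric("winner"))
#' @rdname accessors
#' @export
setGeneric("winProb", function(x) standardGeneric("winProb"))
#' @rdname accessors
#' @export
setGeneric("alphaMean", function(x) standardGeneric("alphaMean"))
#' @rdname accessors
#' @export
setGeneric("alphaCI", function(x) standardGeneric("alphaCI"))
#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("latentStates", function(x) standardGeneric("latentStates"))
#' @rdname accessors
#' @export
setGeneric("triplets", function(x) standardGeneric("triplets"))

#' Assignment scores
#'
#' Per-AB-presentation posterior probability, in [0, 1], that the spike count
#' arose from the unit's A-stimulus response component. For a
#' \linkS4class{ModelPosterior} the stored (fully Bayesian) scores are
#' returned; for a \linkS4class{Triplet} the classifier is run first.
#'
#' @param x a \linkS4class{ModelPosterior} or \linkS4class{Triplet}.
#' @param ... for the Triplet method, arguments passed to
#'   \code{\link{classifyTriplet}}.
#' @return numeric vector of scores in [0, 1].
#' @export
setGeneric("assignmentScores", function(x, ...) standardGeneric("assignmentScores"))
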