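#' @rdname AmplificationSet
#' @param x,object an object.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname AmplificationSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AmplificationSet
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' @rdname AmplificationSet
#' @export
setGeneric("ampData", function(x) standardGeneric("ampData"))

#' Extract one amplification curve
#'
#' @param x an [AmplificationSet-class].
#' @param featureId,sampleId identify the curve; unknown pairs are an error.
#' @return an [AmplificationCurve-class] with the full cycle range in order.
#' @export
setGeneric("extractCurve",
    function(x, featureId, sampleId) standardGeneric("extractCurve"))

#' @rdname CqSet
#' @export
setGeneric("cqValues", function(x) standardGeneric("cqValues"))

#' @rdname CqSet
#' @export
setGeneric("qualityScores", function(x) standardGeneric("qualityScores"))

#' @rdname CqSet
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname CqSet
#' @export
setGeneric("qualityThreshold", function(x) standardGeneric("qualityThreshold"))

#' @rdname CqSet
#' @export
setGeneric("sampleTypes", function(x) standardGeneric("sampleTypes"))

#' @rdname CqSet
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname MixtureDesign
#' @export
setGeneric("poolWeights", function(x) standardGeneric("poolWeights"))

#' @rdname MixtureDesign
#' @export
setGeneric("titrationSeries", function(x) standardGeneric("titrationSeries"))

#' @rdname MixtureDesign
#' @export
setGeneric("pureTypes", function(x) standardGeneric("pureTypes"))

#' @rdname MixtureDesign
#' @export
setGeneric("lowInputTypes", function(x) standardGeneric("lowInputTypes"))

#' Threshold cycle from a fitted curve: second-derivative maximum (cpD2)
#'
#' @param fit a [FittedCurve-class].
#' @param ... further arguments (grid step).
#' @return the cycle (reported to at least 3 decimals) at which the second
#'   derivative of the fitted curve is maximal, or \code{NA} for
#'   non-converged fits.
#' @export
setGeneric("cpd2", function(fit, ...) standardGeneric("cpd2"))
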