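#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' AmplificationSet: raw qPCR amplification curves
#'
#' Container for baseline-corrected fluorescence readings (\eqn{\Delta}Rn)
#' recorded at the end of each amplification cycle, for a set of features
#' (assays, typically miRNAs) measured across a set of samples.  All curves in
#' one set share the same contiguous cycle range \code{1..C}; fluorescence is
#' stored as a cycles-by-curves matrix with one column per (feature, sample)
#' pair.
#'
#' @slot fluor numeric matrix, \code{nCycles} rows (cycles 1..C) by one column
#'   per curve.
#' @slot curveInfo \code{DataFrame} with one row per curve: \code{featureId},
#'   \code{sampleId} (\code{"<type>:<replicate>"}), \code{sampleType},
#'   \code{replicate}.
#'
#' @seealso [AmplificationSet()], [readAmplificationTable()], [extractCurve()]
#' @exportClass AmplificationSet
setClass("AmplificationSet",
    representation(fluor = "matrix", curveInfo = "DataFrame"))

setValidity("AmplificationSet", function(object) {
    msg <- character()
    f <- object@fluor
    ci <- object@curveInfo
    if (!is.numeric(f))
        msg <- c(msg, "'fluor' must be a numeric matrix")
    if (nrow(f) < 1L)
        msg <- c(msg, "at least one cycle is required")
    if (ncol(f) != nrow(ci))
        msg <- c(msg, "'curveInfo' must have one row per fluorescence column")
    need <- c("featureId", "sampleId", "sampleType", "replicate")
    if (!all(need %in% colnames(ci)))
        msg <- c(msg, paste0("'curveInfo' must have columns ",
                             paste(need, collapse = ", ")))
    else {
        key <- paste(ci$featureId, ci$sampleId)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (feature, sample) curves")
        ## (sampleType, replicate) must identify sampleId uniquely, both ways
        tr <- paste(ci$sampleType, ci$replicate, sep = ":")
        map <- unique(data.frame(tr = tr, id = ci$sampleId))
        if (anyDuplicated(map$tr) || anyDuplicated(map$id))
            msg <- c(msg,
                "(sampleType, replicate) and sampleId must map one-to-one")
        if (!is.numeric(ci$sampleType) || !is.numeric(ci$replicate) ||
            any(ci$sampleType < 1) || any(ci$replicate < 1))
            msg <- c(msg, "'sampleType' and 'replicate' must be positive integers")
    }
    if (length(msg)) msg else TRUE
})

#' AmplificationCurve: one amplification trace
#'
#' A single fluorescence trajectory (\eqn{\Delta}Rn vs cycle) for one feature
#' in one sample.
#'
#' @slot featureId,sampleId character scalars identifying the curve.
#' @slot cycles integer vector of cycle numbers, strictly increasing.
#' @slot fluor numeric vector of fluorescence readings, same length.
#'
#' @exportClass AmplificationCurve
setClass("AmplificationCurve",
    representation(featureId = "character", sampleId = "character",
                   cycles = "numeric", fluor = "numeric"))

setValidity("AmplificationCurve", function(object) {
    msg <- character()
    if (length(object@cycles) != length(object@fluor))
        msg <- c(msg, "'cycles' and 'fluor' must have equal length")
    if (length(object@cycles) && any(diff(object@cycles) <= 0))
        msg <- c(msg, "'cycles' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' CqSet: paired expression and quality matrices
#'
#' A features-by-samples container holding threshold-cycle expression
#' estimates (cycle units; \code{NA} where estimation failed) together with a
#' same-shaped matrix of quality scores, produced either by
#' [estimateExpression()] or imported from an external algorithm's export
#' (e.g. vendor Crt/AmpScore tables).  Extends
#' \linkS4class{SummarizedExperiment} with assays \code{"expression"} and
#' \code{"quality"}; \code{colData} carries \code{sampleType} and
#' \code{replicate}.
#'
#' Quality orientation is a fixed contract: higher is better.
#'
#' @slot methodName character; which algorithm produced the estimates.
#' @slot qualityThreshold numeric; default good-quality cut for this method
#'   (e.g. 0.99 for an R-squared quality, 1.25 for an imported AmpScore).
#'
#' @seealso [CqSet()], [readCqSet()], [estimateExpression()]
#' @exportClass CqSet
setClass("CqSet",
    contains = "SummarizedExperiment",
    representation(methodName = "character", qualityThreshold = "numeric"))

setValidity("CqSet", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("expression", "quality") %in% an))
        return("assays 'expression' and 'quality' are required")
    e <- SummarizedExperiment::assay(object, "expression")
    q <- SummarizedExperiment::assay(object, "quality")
    if (any(is.na(q) & !is.na(e)))
        msg <- c(msg, "quality must never be missing where expression is present")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sampleType", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'sampleType' and 'replicate'")
    if (length(object@methodName) != 1L)
        msg <- c(msg, "'methodName' must be a single string")
    if (length(object@qualityThreshold) != 1L)
        msg <- c(msg, "'qualityThreshold' must be a single number")
    if (length(msg)) msg else TRUE
})

#' MixtureDesign: the two-pool mixture/dilution sample layout
#'
#' Describes the benchmark's sample types as non-negative weights of two RNA
#' pools (A and B) relative to the pure samples (weight 1), the two pure
#' types, the two titration series (one pool held constant at weight 1 while
#' the other doubles along the series) and the low-input dilution types.
#'
#' @slot weights data.frame with columns \code{sampleType}, \code{weightA},
#'   \code{weightB}.
#' @slot pureA,pureB integer sample types of the pure pools.
#' @slot seriesAConstant integer sample types in which pool A is constant and
#'   pool B is titrated, in order of increasing titrated weight.
#' @slot seriesBConstant likewise with pool B constant, pool A titrated.
#' @slot lowInput integer sample types of the equal-weight low-input dilutions.
#'
#' @seealso [defaultDesign()]
#' @exportClass MixtureDesign
setClass("MixtureDesign",
    representation(weights = "data.frame", pureA = "integer", pureB = "integer",
                   seriesAConstant = "integer", seriesBConstant = "integer",
                   lowInput = "integer"))

setValidity("MixtureDesign", function(object) {
    w <- object@weights
    msg <- character()
    if (!all(c("sampleType", "weightA", "weightB") %in% colnames(w)))
        return("weights must have columns sampleType, weightA, weightB")
    if (any(w$weightA < 0) || any(w$weightB < 0))
        msg <- c(msg, "pool weights must be non-negative")
    wOf <- function(type) unlist(w[match(type, w$sampleType),
                                   c("weightA", "weightB")])
    if (!isTRUE(all.equal(unname(wOf(object@pureA)), c(1, 0))))
        msg <- c(msg, "pure A type must have weights (1, 0)")
    if (!isTRUE(all.equal(unname(wOf(object@pureB)), c(0, 1))))
        msg <- c(msg, "pure B type must have weights (0, 1)")
    checkSeries <- function(types, constant) {
        ww <- w[match(types, w$sampleType), ]
        const <- if (constant == "A") ww$weightA else ww$weightB
        titr  <- if (constant == "A") ww$weightB else ww$weightA
        ok <- all(abs(const - 1) < 1e-12) &&
            length(titr) >= 2 &&
            isTRUE(all.equal(titr[-1], 2 * titr[-length(titr)]))
        ok
    }
    if (!checkSeries(object@seriesAConstant, "A"))
        msg <- c(msg, "series with A constant must hold weightA = 1 and double weightB")
    if (!checkSeries(object@seriesBConstant, "B"))
        msg <- c(msg, "series with B constant must hold weightB = 1 and double weightA")
    li <- w[match(object@lowInput, w$sampleType), ]
    if (!isTRUE(all.equal(li$weightA, li$weightB)))
        msg <- c(msg, "low-input types must have equal pool weights")
    if (length(msg)) msg else TRUE
})

#' FittedCurve: a fitted sigmoidal amplification model
#'
#' Result of [fitModel()]: model family, least-squares parameter estimates,
#' convergence flag and fit quality.  \code{rSquared} is
#' \eqn{1 - SS_{res}/SS_{tot}} computed on the fitted cycles.  When
#' \code{converged} is \code{FALSE} the parameters are unusable and the
#' downstream expression estimate is missing.
#'
#' @slot modelId one of the registered model identifiers (see [listModels()]).
#' @slot params named numeric vector of fitted parameters.
#' @slot converged logical flag.
#' @slot rSquared numeric in [0, 1] (\code{NA} if undefined).
#' @slot residSS residual sum of squares.
#' @slot cycleRange numeric length-2, the fitted cycle domain \code{c(1, C)}.
#'
#' @exportClass FittedCurve
setClass("FittedCurve",
    representation(modelId = "character", params = "numeric",
                   converged = "logical", rSquared = "numeric",
                   residSS = "numeric", cycleRange = "numeric"))

setValidity("FittedCurve", function(object) {
    msg <- character()
    if (length(object@cycleRange) != 2L ||
        object@cycleRange[1] >= object@cycleRange[2])
        msg <- c(msg, "'cycleRange' must be an increasing length-2 vector")
    r2 <- object@rSquared
    if (length(r2) == 1L && !is.na(r2) && (r2 < 0 || r2 > 1))
        msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
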