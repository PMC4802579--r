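#' Construct a MixtureDesign
#'
#' @param weights data.frame with columns \code{sampleType}, \code{weightA},
#'   \code{weightB}; pool weights are expressed relative to the pure samples
#'   (pure = 1).
#' @param pureA,pureB sample types of the pure pools.
#' @param seriesAConstant,seriesBConstant titration series (ordered sample
#'   types; the constant pool has weight 1 throughout, the titrated pool's
#'   weight doubles along the series).
#' @param lowInput sample types of the equal-weight low-input dilutions.
#' @return a [MixtureDesign-class].
#' @export
MixtureDesign <- function(weights, pureA, pureB, seriesAConstant,
                          seriesBConstant, lowInput) {
    obj <- new("MixtureDesign", weights = as.data.frame(weights),
               pureA = as.integer(pureA), pureB = as.integer(pureB),
               seriesAConstant = as.integer(seriesAConstant),
               seriesBConstant = as.integer(seriesBConstant),
               lowInput = as.integer(lowInput))
    methods::validObject(obj)
    obj
}

#' The default two-pool mixture/dilution design
#'
#' Ten sample types built from two RNA pools: the pure pools (types 1 and 5,
#' weights (1,0) and (0,1)), two titration series in which one pool is held
#' constant while the other doubles twice (types 2-4: weights (1, 0.2),
#' (1, 0.4), (1, 0.8); types 6-8: the mirror image) and two low-input
#' dilutions with equal weights for both pools (type 9: (0.1, 0.1); type 10:
#' (0.01, 0.01)).  Weights are relative to the pure samples, so the titrated
#' weights within each series are in exact ratio 1:2:4.
#'
#' @return a [MixtureDesign-class].
#' @examples
#' defaultDesign()
#' @export
defaultDesign <- function() {
    w <- data.frame(
        sampleType = 1:10,
        weightA = c(1, 1, 1, 1, 0, 0.2, 0.4, 0.8, 0.1, 0.01),
        weightB = c(0, 0.2, 0.4, 0.8, 1, 1, 1, 1, 0.1, 0.01))
    MixtureDesign(w, pureA = 1L, pureB = 5L,
                  seriesAConstant = 2:4, seriesBConstant = 6:8,
                  lowInput = c(9L, 10L))
}

#' @rdname MixtureDesign
#' @param x a \code{MixtureDesign}.
#' @export
setMethod("poolWeights", "MixtureDesign", function(x) x@weights)

#' @describeIn MixtureDesign the two titration series as a named list; each
#'   element carries the ordered sample \code{types} and which pool is
#'   \code{titrated} ("A" or "B").
#' @export
setMethod("titrationSeries", "MixtureDesign", function(x)
    list(A = list(types = x@seriesBConstant, titrated = "A"),
         B = list(types = x@seriesAConstant, titrated = "B")))

#' @rdname MixtureDesign
#' @export
setMethod("pureTypes", "MixtureDesign",
    function(x) c(A = x@pureA, B = x@pureB))

#' @rdname MixtureDesign
#' @export
setMethod("lowInputTypes", "MixtureDesign", function(x) x@lowInput)

setMethod("show", "MixtureDesign", function(object) {
    cat("MixtureDesign:", nrow(object@weights), "sample types; pure A =",
        object@pureA, ", pure B =", object@pureB, "\n")
    print(object@weights, row.names = FALSE)
})

#' Read/write a MixtureDesign as JSON
#'
#' @param x a [MixtureDesign-class].
#' @param path JSON file path.
#' @return \code{writeDesign} returns \code{path} invisibly;
#'   \code{readDesign} returns a \code{MixtureDesign}.
#' @export
writeDesign <- function(x, path) {
    jsonlite::write_json(list(
        weights = x@weights, pureA = x@pureA, pureB = x@pureB,
        seriesAConstant = x@seriesAConstant,
        seriesBConstant = x@seriesBConstant,
        lowInput = x@lowInput), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    MixtureDesign(j$weights, j$pureA, j$pureB, j$seriesAConstant,
                  j$seriesBConstant, j$lowInput)
}
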