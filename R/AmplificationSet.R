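## Long-format logical column names used across the raw-table interface.
.AMP_COLS <- c("feature", "sample_type", "replicate", "cycle", "deltaRn")

.sampleId <- function(sampleType, replicate)
    paste(as.integer(sampleType), as.integer(replicate), sep = ":")

#' Construct an AmplificationSet from a long-format table
#'
#' Validates and reshapes a long table of fluorescence readings (one row per
#' feature x sample x cycle) into an [AmplificationSet-class].  Every curve
#' must cover the contiguous cycle range \code{1..C} exactly once, with the
#' same maximum cycle \code{C} for all curves.
#'
#' @param data data.frame with columns \code{feature}, \code{sample_type},
#'   \code{replicate}, \code{cycle}, \code{deltaRn}.
#' @return an \code{AmplificationSet}.
#' @examples
#' d <- expand.grid(feature = c("a", "b"), sample_type = 1L, replicate = 1L,
#'                  cycle = 1:10)
#' d$deltaRn <- runif(nrow(d))
#' AmplificationSet(d)
#' @export
AmplificationSet <- function(data) {
    miss <- setdiff(.AMP_COLS, colnames(data))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    dt <- data.table::as.data.table(data[, .AMP_COLS])
    dt[, `:=`(feature = as.character(feature),
              sample_type = as.integer(sample_type),
              replicate = as.integer(replicate),
              cycle = as.integer(cycle))]
    dt[, sample_id := .sampleId(sample_type, replicate)]
    data.table::setorder(dt, feature, sample_type, replicate, cycle)
    C <- max(dt$cycle)
    ## contiguity: each curve must be exactly 1..C with one reading each
    chk <- dt[, list(ok = .N == C && identical(cycle, seq_len(C))),
              by = list(feature, sample_id)]
    if (any(!chk$ok)) {
        bad <- chk[!chk$ok]
        stop("non-contiguous or incomplete cycles for curve(s): ",
             paste(utils::head(paste0("(", bad$feature, ", ", bad$sample_id, ")"),
                               5L), collapse = ", "),
             if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L) else "")
    }
    info <- unique(dt[, list(featureId = feature, sampleId = sample_id,
                             sampleType = sample_type, replicate = replicate)])
    fl <- matrix(dt$deltaRn, nrow = C,
                 dimnames = list(seq_len(C), NULL))
    obj <- new("AmplificationSet", fluor = fl,
               curveInfo = S4Vectors::DataFrame(as.data.frame(info)))
    methods::validObject(obj)
    obj
}

## internal: build directly from a cycles-by-curves matrix (already validated
## by construction, e.g. by the simulator)
.newAmplificationSet <- function(fluor, info) {
    rownames(fluor) <- seq_len(nrow(fluor))
    new("AmplificationSet", fluor = fluor,
        curveInfo = S4Vectors::DataFrame(info))
}

#' @rdname AmplificationSet
#' @export
setMethod("featureIds", "AmplificationSet",
    function(x) unique(x@curveInfo$featureId))

#' @rdname AmplificationSet
#' @export
setMethod("sampleIds", "AmplificationSet",
    function(x) unique(x@curveInfo$sampleId))

#' @rdname AmplificationSet
#' @export
setMethod("nCycles", "AmplificationSet", function(x) nrow(x@fluor))

#' @describeIn AmplificationSet long-format view, sorted by
#'   (feature, sample, cycle).
#' @export
setMethod("ampData", "AmplificationSet", function(x) {
    ci <- as.data.frame(x@curveInfo)
    C <- nrow(x@fluor)
    data.frame(
        feature = rep(ci$featureId, each = C),
        sample_type = rep(ci$sampleType, each = C),
        replicate = rep(ci$replicate, each = C),
        cycle = rep.int(seq_len(C), nrow(ci)),
        deltaRn = as.vector(x@fluor),
        stringsAsFactors = FALSE)
})

setMethod("show", "AmplificationSet", function(object) {
    ci <- object@curveInfo
    cat("AmplificationSet:", length(unique(ci$featureId)), "features x",
        length(unique(ci$sampleId)), "samples,",
        nrow(object@fluor), "cycles (", ncol(object@fluor), "curves )\n")
})

#' @rdname extractCurve
#' @export
setMethod("extractCurve", "AmplificationSet",
    function(x, featureId, sampleId) {
        i <- which(x@curveInfo$featureId == featureId &
                   x@curveInfo$sampleId == sampleId)
        if (length(i) != 1L)
            stop("no curve for (", featureId, ", ", sampleId, ")")
        new("AmplificationCurve", featureId = featureId, sampleId = sampleId,
            cycles = as.numeric(seq_len(nrow(x@fluor))),
            fluor = as.numeric(x@fluor[, i]))
    })

setMethod("show", "AmplificationCurve", function(object) {
    cat("AmplificationCurve", paste0("(", object@featureId, ", ",
        object@sampleId, "):"), length(object@cycles), "cycles, deltaRn in [",
        signif(min(object@fluor), 3), ",", signif(max(object@fluor), 3), "]\n")
})

#' Read a long-format amplification table
#'
#' Reads a delimited text file (comma-separated, header row) of raw
#' fluorescence readings and returns a validated [AmplificationSet-class].
#' \code{columnMap} renames the file's native headers onto the required
#' logical columns, so exports with other naming conventions can be ingested
#' directly.
#'
#' @param path file path.
#' @param columnMap named character vector mapping the logical names
#'   \code{feature}, \code{sample_type}, \code{replicate}, \code{cycle},
#'   \code{deltaRn} to the file's column names.
#' @return an \code{AmplificationSet}, rows sorted by (feature, sample, cycle).
#' @seealso [writeAmplificationTable()]
#' @export
readAmplificationTable <- function(path,
        columnMap = stats::setNames(.AMP_COLS, .AMP_COLS)) {
    stopifnot(all(.AMP_COLS %in% names(columnMap)))
    raw <- data.table::fread(path, header = TRUE, data.table = FALSE)
    miss <- setdiff(unname(columnMap[.AMP_COLS]), colnames(raw))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    d <- raw[, unname(columnMap[.AMP_COLS])]
    colnames(d) <- .AMP_COLS
    AmplificationSet(d)
}

#' Write an AmplificationSet as a long-format CSV
#'
#' @param x an [AmplificationSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAmplificationTable <- function(x, path) {
    data.table::fwrite(ampData(x), path)
    invisible(path)
}
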