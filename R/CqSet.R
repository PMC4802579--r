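#' Construct a CqSet
#'
#' @param expression numeric matrix, features x samples, threshold-cycle
#'   expression estimates (\code{NA} allowed).
#' @param quality numeric matrix of the same shape; higher is better; must be
#'   non-missing wherever expression is present.
#' @param methodName character, name of the producing algorithm.
#' @param qualityThreshold default good-quality cut for this method.
#' @param sampleType,replicate integer vectors, one per column; parsed from
#'   column names of the form \code{"<type>:<replicate>"} when omitted.
#' @return a [CqSet-class].
#' @export
CqSet <- function(expression, quality, methodName = "unknown",
                  qualityThreshold = NA_real_,
                  sampleType = NULL, replicate = NULL) {
    stopifnot(is.matrix(expression), is.matrix(quality),
              all(dim(expression) == dim(quality)))
    if (is.null(sampleType) || is.null(replicate)) {
        parsed <- .parseSampleIds(colnames(expression))
        sampleType <- parsed$sampleType
        replicate <- parsed$replicate
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = expression, quality = quality),
        colData = S4Vectors::DataFrame(sampleType = as.integer(sampleType),
                                       replicate = as.integer(replicate),
                                       row.names = colnames(expression)))
    obj <- new("CqSet", se, methodName = methodName,
               qualityThreshold = as.numeric(qualityThreshold))
    methods::validObject(obj)
    obj
}

.parseSampleIds <- function(ids) {
    if (is.null(ids))
        stop("sample labels are required (\"<type>:<replicate>\")")
    parts <- strsplit(ids, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    st <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    rp <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (any(!ok) || anyNA(st) || anyNA(rp))
        stop("sample labels must follow \"<type>:<replicate>\"; first bad: ",
             ids[which(!ok | is.na(st) | is.na(rp))[1L]])
    list(sampleType = st, replicate = rp)
}

#' @rdname CqSet
#' @param x a \code{CqSet}.
#' @export
setMethod("cqValues", "CqSet",
    function(x) SummarizedExperiment::assay(x, "expression"))

#' @rdname CqSet
#' @export
setMethod("qualityScores", "CqSet",
    function(x) SummarizedExperiment::assay(x, "quality"))

#' @rdname CqSet
#' @export
setMethod("methodName", "CqSet", function(x) x@methodName)

#' @rdname CqSet
#' @export
setMethod("qualityThreshold", "CqSet", function(x) x@qualityThreshold)

#' @rdname CqSet
#' @export
setMethod("sampleTypes", "CqSet",
    function(x) SummarizedExperiment::colData(x)$sampleType)

#' @rdname CqSet
#' @export
setMethod("replicates", "CqSet",
    function(x) SummarizedExperiment::colData(x)$replicate)

#' @rdname CqSet
#' @export
setMethod("featureIds", "CqSet", function(x) rownames(x))

#' @rdname CqSet
#' @export
setMethod("sampleIds", "CqSet", function(x) colnames(x))

setMethod("show", "CqSet", function(object) {
    e <- cqValues(object)
    cat("CqSet [", object@methodName, "]: ", nrow(e), " features x ",
        ncol(e), " samples; ", sum(is.na(e)), " missing estimates; ",
        "quality threshold ", object@qualityThreshold, "\n", sep = "")
})

## good-quality mask: present estimate AND quality at or above threshold
.goodMask <- function(cq, threshold = qualityThreshold(cq)) {
    if (is.na(threshold))
        stop("a quality threshold is required (none stored in this CqSet)")
    e <- cqValues(cq)
    q <- qualityScores(cq)
    !is.na(e) & !is.na(q) & q >= threshold
}

#' Read paired expression/quality CSV exports
#'
#' Reads two CSV matrices (features in the first column, sample labels
#' \code{"<type>:<replicate>"} in the header) of expression estimates and
#' quality scores, as exported by an external expression-estimation algorithm.
#' Blank cells and the literal \code{NA} become missing expression.  The
#' quality matrix is aligned to the expression matrix by row and column
#' labels; a label set mismatch is an error naming the first disagreeing
#' label.
#'
#' @param exprPath,qualityPath CSV file paths.
#' @param methodName name recorded for the algorithm.
#' @param qualityThreshold default good-quality cut to store.
#' @return a [CqSet-class].
#' @seealso [writeCqSet()]
#' @export
readCqSet <- function(exprPath, qualityPath, methodName = "imported",
                      qualityThreshold = NA_real_) {
    readMat <- function(path) {
        d <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
        rn <- as.character(d[[1L]])
        m <- as.matrix(d[, -1L, drop = FALSE])
        m[m == "" | m == "NA"] <- NA
        storage.mode(m) <- "double"
        rownames(m) <- rn
        m
    }
    e <- readMat(exprPath)
    q <- readMat(qualityPath)
    alignBy <- function(have, want, what) {
        if (!setequal(have, want) || anyDuplicated(have)) {
            bad <- c(setdiff(have, want), setdiff(want, have))[1L]
            stop("expression/quality ", what, " labels disagree; first: ", bad)
        }
        match(want, have)
    }
    q <- q[alignBy(rownames(q), rownames(e), "feature"),
           alignBy(colnames(q), colnames(e), "sample"), drop = FALSE]
    CqSet(e, q, methodName = methodName, qualityThreshold = qualityThreshold)
}

#' Write a CqSet as paired expression/quality CSV files
#'
#' @param x a [CqSet-class].
#' @param exprPath,qualityPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeCqSet <- function(x, exprPath, qualityPath) {
    wr <- function(m, path) {
        d <- data.frame(feature = rownames(m), m, check.names = FALSE)
        data.table::fwrite(d, path)
    }
    wr(cqValues(x), exprPath)
    wr(qualityScores(x), qualityPath)
    invisible(c(exprPath, qualityPath))
}
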