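## Shared slope heuristics used by every model's initialization: the steepest
## observed rise locates the exponential phase.
.riseInit <- function(x, y) {
    dy <- diff(y)
    i <- which.max(dy)
    list(x0 = (x[i] + x[i + 1L]) / 2,
         slope = max(dy[i] / (x[i + 1L] - x[i]), 1e-8),
         amp = max(max(y) - min(y), 1e-8))
}

#' Fit a parametric model to one amplification curve
#'
#' Least-squares fit (Levenberg-Marquardt, \pkg{minpack.lm}) of a registered
#' model family to a single fluorescence trace.  Starting values are derived
#' from the data (baseline = min, plateau = max, location = cycle of steepest
#' observed rise, slope from the rise at that point); optimization is bounded
#' so that sigmoidal fits remain increasing.  A fit is flagged non-converged
#' (not an error) when the optimizer fails, the residual variance is
#' undefined (flat input), the fitted plateau does not exceed the baseline,
#' or the fitted curve is non-increasing over the cycle range.
#'
#' @param curve an [AmplificationCurve-class], or anything with numeric
#'   \code{cycles}/\code{fluor} fields.
#' @param modelId registered model identifier (see [listModels()]).
#' @return a [FittedCurve-class] carrying the parameter estimates, a
#'   convergence flag, the residual sum of squares and the fit
#'   \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#' @examples
#' x <- 1:46
#' y <- 0.1 + 2.9 / (1 + exp(-8 * (log(x) - log(30))))
#' fitModel(new("AmplificationCurve", featureId = "f", sampleId = "1:1",
#'              cycles = as.numeric(x), fluor = y), "l4")
#' @export
fitModel <- function(curve, modelId = "l4") {
    x <- if (methods::is(curve, "AmplificationCurve")) curve@cycles else curve$cycles
    y <- if (methods::is(curve, "AmplificationCurve")) curve@fluor else curve$fluor
    m <- modelSpec(modelId)
    if (length(x) < length(m$paramNames) + 2L)
        stop("too few points (", length(x), ") to fit '", modelId, "'")
    .fitXY(x, y, m)
}

.failedFit <- function(m, x) {
    new("FittedCurve", modelId = m$id,
        params = stats::setNames(rep(NA_real_, length(m$paramNames)),
                                 m$paramNames),
        converged = FALSE, rSquared = NA_real_, residSS = NA_real_,
        cycleRange = range(x))
}

.fitXY <- function(x, y, m) {
    ssTot <- sum((y - mean(y))^2)
    if (!is.finite(ssTot) || ssTot < 1e-12)   # flat curve: R^2 undefined
        return(.failedFit(m, x))
    p0 <- m$init(x, y, .riseInit(x, y))
    p0 <- pmin(pmax(p0, m$lower), m$upper)
    resid <- function(p) {
        names(p) <- m$paramNames
        r <- y - m$predict(p, x)
        r[!is.finite(r)] <- 1e6
        r
    }
    fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, lower = m$lower, upper = m$upper,
            fn = resid,
            control = minpack.lm::nls.lm.control(
                ftol = 1e-10, ptol = 1e-12, maxiter = 500)),
        error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4)
        return(.failedFit(m, x))
    p <- stats::setNames(as.numeric(fit$par), m$paramNames)
    yh <- m$predict(p, x)
    if (any(!is.finite(yh)))
        return(.failedFit(m, x))
    ## require a genuinely increasing fitted curve over [1, C]
    grid <- m$predict(p, seq(min(x), max(x), by = 0.5))
    if (!all(is.finite(grid)) || grid[length(grid)] <= grid[1L] + 1e-12 ||
        min(diff(grid)) < -1e-8)
        return(.failedFit(m, x))
    if (all(c("c", "d") %in% names(p)) && p["d"] <= p["c"])
        return(.failedFit(m, x))
    ssRes <- sum((y - yh)^2)
    r2 <- max(0, min(1, 1 - ssRes / ssTot))
    new("FittedCurve", modelId = m$id, params = p, converged = TRUE,
        rSquared = r2, residSS = ssRes, cycleRange = range(x))
}

setMethod("show", "FittedCurve", function(object) {
    cat("FittedCurve [", object@modelId, "] converged =", object@converged,
        "\n")
    if (object@converged) {
        print(signif(object@params, 6))
        cat("R-squared:", format(object@rSquared, digits = 10), "\n")
    }
})

#' @describeIn cpd2 second-derivative maximum of a fitted curve, located on a
#'   dense grid (default step 0.01 cycles) over the fitted cycle range and
#'   refined by root-finding on the numerically differentiated analytic
#'   second derivative (falling back to golden-section refinement when no
#'   sign change brackets the grid argmax).  Boundary maxima (as for the
#'   linear-exponential family, whose second derivative is monotone) return
#'   the boundary cycle.
#' @param gridStep spacing of the search grid in cycles.
#' @export
setMethod("cpd2", "FittedCurve", function(fit, gridStep = 0.01) {
    if (!fit@converged)
        return(NA_real_)
    m <- modelSpec(fit@modelId)
    lo <- fit@cycleRange[1L]
    hi <- fit@cycleRange[2L]
    p <- fit@params
    xs <- seq(lo, hi, by = gridStep)
    d2 <- m$d2(p, xs)
    i <- which.max(d2)
    if (i == 1L || i == length(xs))
        return(xs[i])
    ## refine: the third derivative (numeric, from the analytic d2) changes
    ## sign at the interior maximum
    d3 <- function(x) (m$d2(p, x + 1e-5) - m$d2(p, x - 1e-5)) / 2e-5
    a <- xs[i - 1L]; b <- xs[i + 1L]
    da <- d3(a); db <- d3(b)
    xstar <- if (is.finite(da) && is.finite(db) && da > 0 && db < 0)
        stats::uniroot(d3, c(a, b), tol = 1e-10)$root
    else
        stats::optimize(function(x) m$d2(p, x), c(a, b),
                        maximum = TRUE, tol = 1e-9)$maximum
    xstar
})

#' Batch expression estimation from raw amplification data
#'
#' Fits the chosen model to every curve in the dataset, takes the cpD2
#' second-derivative-maximum threshold cycle as the expression estimate and
#' the fit \eqn{R^2} as the quality score, and assembles a [CqSet-class].
#' Curves whose fit fails to converge get a missing expression estimate with
#' quality 0; the result is deterministic given identical inputs.
#'
#' @param x an [AmplificationSet-class].
#' @param modelId registered model identifier.
#' @param qualityThreshold default good-quality \eqn{R^2} cut stored in the
#'   result (0.99 unless overridden).
#' @return a [CqSet-class], features x samples, \code{methodName = modelId}.
#' @export
estimateExpression <- function(x, modelId = "l4", qualityThreshold = 0.99) {
    stopifnot(methods::is(x, "AmplificationSet"))
    m <- modelSpec(modelId)
    ci <- as.data.frame(x@curveInfo)
    feats <- unique(ci$featureId)
    samps <- unique(ci$sampleId[order(ci$sampleType, ci$replicate)])
    cyc <- as.numeric(seq_len(nrow(x@fluor)))
    expr <- qual <- matrix(NA_real_, length(feats), length(samps),
                           dimnames = list(feats, samps))
    fi <- match(ci$featureId, feats)
    si <- match(ci$sampleId, samps)
    for (k in seq_len(ncol(x@fluor))) {
        fit <- .fitXY(cyc, as.numeric(x@fluor[, k]), m)
        if (fit@converged) {
            expr[fi[k], si[k]] <- cpd2(fit)
            qual[fi[k], si[k]] <- fit@rSquared
        } else {
            qual[fi[k], si[k]] <- 0
        }
    }
    st <- ci$sampleType[match(samps, ci$sampleId)]
    rp <- ci$replicate[match(samps, ci$sampleId)]
    CqSet(expr, qual, methodName = modelId,
          qualityThreshold = qualityThreshold,
          sampleType = st, replicate = rp)
}
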