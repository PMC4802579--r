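## Sigmoidal amplification-curve model registry.
##
## Parameterizations (x = cycle):
##   b4:  f(x) = c + (d - c) / (1 + exp(b (x - e)))
##   l4:  f(x) = c + (d - c) / (1 + exp(b (log x - log e)))
##   b5:  f(x) = c + (d - c) / (1 + exp(b (x - e)))^f
##   l5:  f(x) = c + (d - c) / (1 + exp(b (log x - log e)))^f
##   linexp: f(x) = a exp(k x) + m x + o
## For increasing curves b < 0 (b-slope), k > 0.  Second derivatives are
## analytic (closed forms below); each is cross-checked against central
## differences in the test suite.

.mod_b4 <- list(
    id = "b4", paramNames = c("b", "c", "d", "e"),
    predict = function(p, x)
        p["c"] + (p["d"] - p["c"]) / (1 + exp(p["b"] * (x - p["e"]))),
    d2 = function(p, x) {
        g <- exp(p["b"] * (x - p["e"])); u <- 1 + g
        -(p["d"] - p["c"]) * p["b"]^2 * g * (1 - g) / u^3
    },
    init = function(x, y, sl) {
        c(b = unname(-4 * sl$slope / (sl$amp)), c = min(y), d = max(y),
          e = sl$x0)
    },
    lower = c(b = -Inf, c = -Inf, d = -Inf, e = -Inf),
    upper = c(b = -1e-6, c = Inf, d = Inf, e = Inf))

.mod_l4 <- list(
    id = "l4", paramNames = c("b", "c", "d", "e"),
    predict = function(p, x)
        p["c"] + (p["d"] - p["c"]) / (1 + exp(p["b"] * (log(x) - log(p["e"])))),
    d2 = function(p, x) {
        g <- exp(p["b"] * (log(x) - log(p["e"]))); u <- 1 + g
        -(p["d"] - p["c"]) * p["b"] * g * ((p["b"] - 1) * u - 2 * p["b"] * g) /
            (x^2 * u^3)
    },
    init = function(x, y, sl) {
        c(b = unname(-4 * sl$x0 * sl$slope / sl$amp), c = min(y), d = max(y),
          e = max(sl$x0, 1))
    },
    lower = c(b = -Inf, c = -Inf, d = -Inf, e = 1e-6),
    upper = c(b = -1e-6, c = Inf, d = Inf, e = Inf))

.mod_b5 <- list(
    id = "b5", paramNames = c("b", "c", "d", "e", "f"),
    predict = function(p, x)
        p["c"] + (p["d"] - p["c"]) / (1 + exp(p["b"] * (x - p["e"])))^p["f"],
    d2 = function(p, x) {
        g <- exp(p["b"] * (x - p["e"])); u <- 1 + g
        -(p["d"] - p["c"]) * p["f"] * p["b"]^2 * g * u^(-p["f"] - 2) *
            (u - (p["f"] + 1) * g)
    },
    init = function(x, y, sl)
        c(b = unname(-4 * sl$slope / sl$amp), c = min(y), d = max(y),
          e = sl$x0, f = 1),
    lower = c(b = -Inf, c = -Inf, d = -Inf, e = -Inf, f = 1e-3),
    upper = c(b = -1e-6, c = Inf, d = Inf, e = Inf, f = 20))

.mod_l5 <- list(
    id = "l5", paramNames = c("b", "c", "d", "e", "f"),
    predict = function(p, x)
        p["c"] + (p["d"] - p["c"]) /
            (1 + exp(p["b"] * (log(x) - log(p["e"]))))^p["f"],
    d2 = function(p, x) {
        g <- exp(p["b"] * (log(x) - log(p["e"]))); u <- 1 + g
        -(p["d"] - p["c"]) * p["f"] * p["b"] * g * u^(-p["f"] - 2) *
            ((p["b"] - 1) * u - (p["f"] + 1) * p["b"] * g) / x^2
    },
    init = function(x, y, sl)
        c(b = unname(-4 * sl$x0 * sl$slope / sl$amp), c = min(y), d = max(y),
          e = max(sl$x0, 1), f = 1),
    lower = c(b = -Inf, c = -Inf, d = -Inf, e = 1e-6, f = 1e-3),
    upper = c(b = -1e-6, c = Inf, d = Inf, e = Inf, f = 20))

.mod_linexp <- list(
    id = "linexp", paramNames = c("a", "k", "m", "o"),
    predict = function(p, x) p["a"] * exp(p["k"] * x) + p["m"] * x + p["o"],
    d2 = function(p, x) p["a"] * p["k"]^2 * exp(p["k"] * x),
    init = function(x, y, sl) {
        C <- max(x)
        k0 <- log(2) / max(C - sl$x0, 1)
        c(a = unname(sl$amp * exp(-k0 * C)), k = unname(k0), m = 0,
          o = min(y))
    },
    lower = c(a = 1e-12, k = 1e-4, m = -Inf, o = -Inf),
    upper = c(a = Inf, k = 2, m = Inf, o = Inf))

.MODELS <- list(b4 = .mod_b4, l4 = .mod_l4, b5 = .mod_b5, l5 = .mod_l5,
                linexp = .mod_linexp)

#' Registered amplification-curve models
#'
#' \code{listModels} returns the identifiers of the registered sigmoidal /
#' linear-exponential model families; \code{modelSpec} returns one model's
#' specification (parameter names, prediction function, analytic second
#' derivative, initialization rule and box constraints).
#'
#' @param modelId one of \code{"b4"}, \code{"l4"}, \code{"b5"}, \code{"l5"},
#'   \code{"linexp"}.
#' @return \code{listModels}: character vector; \code{modelSpec}: a list with
#'   elements \code{id}, \code{paramNames}, \code{predict(p, x)},
#'   \code{d2(p, x)}, \code{init}, \code{lower}, \code{upper}.
#' @examples
#' listModels()
#' m <- modelSpec("l4")
#' m$predict(c(b = -8, c = 0.1, d = 3, e = 30), 1:5)
#' @export
listModels <- function() names(.MODELS)

#' @rdname listModels
#' @export
modelSpec <- function(modelId) {
    modelId <- match.arg(modelId, names(.MODELS))
    .MODELS[[modelId]]
}

#' Evaluate a fitted (or hypothetical) model curve
#'
#' @param modelId a registered model identifier.
#' @param params named numeric parameter vector for that model.
#' @param x cycles at which to evaluate.
#' @return predicted fluorescence.
#' @export
predictCurve <- function(modelId, params, x) {
    m <- modelSpec(modelId)
    stopifnot(all(m$paramNames %in% names(params)))
    unname(m$predict(params[m$paramNames], x))
}

#' Analytic second derivative of a model curve
#'
#' @inheritParams predictCurve
#' @return second derivative of fluorescence with respect to cycle.
#' @export
curveSecondDeriv <- function(modelId, params, x) {
    m <- modelSpec(modelId)
    stopifnot(all(m$paramNames %in% names(params)))
    unname(m$d2(params[m$paramNames], x))
}
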