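## Benchmark assessments over CqSets and a MixtureDesign.
##
## Conventions used throughout:
##  * "good quality" means a present estimate with quality >= threshold
##    (inclusive; higher is always better);
##  * "observed" expression for a feature in a sample type is the mean over
##    its good-quality replicates;
##  * expression is in threshold-cycle units, so abundance doubles when the
##    expression value drops by one cycle.

## per-feature means over good-quality replicates for the given sample types;
## also the proportion of poor-quality (missing or below-threshold) replicates
.typeMeans <- function(cq, types, threshold = qualityThreshold(cq)) {
    good <- .goodMask(cq, threshold)
    e <- cqValues(cq)
    st <- sampleTypes(cq)
    mean_ <- propPoor <- matrix(NA_real_, nrow(e), length(types),
                                dimnames = list(rownames(e), types))
    for (j in seq_along(types)) {
        cols <- which(st == types[j])
        g <- good[, cols, drop = FALSE]
        ee <- e[, cols, drop = FALSE]
        ee[!g] <- NA
        n <- rowSums(g)
        mean_[, j] <- ifelse(n > 0, rowSums(ee, na.rm = TRUE) / n, NA)
        propPoor[, j] <- 1 - n / length(cols)
    }
    list(mean = mean_, propPoor = propPoor)
}

#' Quality-score diagnostics for one method
#'
#' Summarizes the relationship between expression estimates and quality
#' scores: the paired values where an estimate is present, the distribution
#' of quality scores attached to missing estimates, and two-dimensional
#' binned counts suitable for smoothed scatter displays.
#'
#' @param cq a [CqSet-class].
#' @param nbins number of bins per axis for the 2-D count table.
#' @return list with \code{present} (data.frame of expression/quality pairs),
#'   \code{missingQuality} (numeric vector), and \code{binned} (contingency
#'   table of counts over expression x quality bins).
#' @export
qualitySummary <- function(cq, nbins = 25) {
    e <- as.vector(cqValues(cq))
    q <- as.vector(qualityScores(cq))
    present <- data.frame(expression = e[!is.na(e)], quality = q[!is.na(e)])
    binned <- if (nrow(present) > 1)
        table(expression = cut(present$expression, nbins),
              quality = cut(present$quality, nbins))
    else table(numeric(0))
    list(present = present,
         missingQuality = q[is.na(e)],
         binned = binned)
}

#' Pairwise comparison of expression estimates from two methods
#'
#' Pairs the estimates of two methods over their shared feature/sample axes
#' and flags combinations whose estimates differ by more than
#' \code{deltaThreshold} cycles.  By default the comparison is restricted to
#' entries considered good quality by both methods.
#'
#' @param cq1,cq2 [CqSet-class] objects with identical feature and sample
#'   labels.
#' @param deltaThreshold flagging threshold in cycles (2 cycles = 4-fold
#'   abundance).
#' @param filter \code{"both"} restricts to entries good quality under both
#'   methods' thresholds; \code{"none"} uses every entry present in both.
#' @param threshold1,threshold2 quality cuts (default: each set's stored
#'   threshold).
#' @return list with \code{paired} (data.frame featureId, sampleId, e1, e2,
#'   difference) and \code{flagged} (the subset with
#'   \code{|e1 - e2| > deltaThreshold}, largest difference first).
#' @export
expressionComparison <- function(cq1, cq2, deltaThreshold = 2,
                                 filter = c("both", "none"),
                                 threshold1 = qualityThreshold(cq1),
                                 threshold2 = qualityThreshold(cq2)) {
    filter <- match.arg(filter)
    .checkAligned(cq1, cq2)
    e1 <- cqValues(cq1); e2 <- cqValues(cq2)
    keep <- !is.na(e1) & !is.na(e2)
    if (filter == "both")
        keep <- keep & .goodMask(cq1, threshold1) & .goodMask(cq2, threshold2)
    idx <- which(keep, arr.ind = TRUE)
    paired <- data.frame(
        featureId = rownames(e1)[idx[, 1L]],
        sampleId = colnames(e1)[idx[, 2L]],
        e1 = e1[keep], e2 = e2[keep],
        difference = e1[keep] - e2[keep])
    flagged <- paired[abs(paired$difference) > deltaThreshold, , drop = FALSE]
    flagged <- flagged[order(-abs(flagged$difference)), , drop = FALSE]
    list(paired = paired, flagged = flagged)
}

.checkAligned <- function(cq1, cq2) {
    r1 <- rownames(cq1); r2 <- rownames(cq2)
    c1 <- colnames(cq1); c2 <- colnames(cq2)
    if (!identical(r1, r2)) {
        i <- which(r1 != r2)[1L]
        stop("feature labels differ between the two sets; first: '",
             r1[i], "' vs '", r2[i], "'")
    }
    if (!identical(c1, c2)) {
        i <- which(c1 != c2)[1L]
        stop("sample labels differ between the two sets; first: '",
             c1[i], "' vs '", c2[i], "'")
    }
    invisible(TRUE)
}

#' Classify features as complete, partial or absent
#'
#' A feature is \emph{complete} when it is detected (non-missing estimate)
#' with good quality in every sample, \emph{absent} when it is good quality
#' in no sample, and \emph{partial} otherwise.  The three categories
#' partition the feature set.
#'
#' @param cq a [CqSet-class].
#' @param threshold quality cut (inclusive; default the set's stored
#'   threshold).
#' @return named factor, levels \code{complete}, \code{partial},
#'   \code{absent}, one per feature.
#' @export
classifyFeatures <- function(cq, threshold = qualityThreshold(cq)) {
    good <- .goodMask(cq, threshold)
    n <- rowSums(good)
    cls <- ifelse(n == ncol(good), "complete", ifelse(n == 0, "absent",
                  "partial"))
    factor(stats::setNames(cls, rownames(cq)),
           levels = c("complete", "partial", "absent"))
}

#' Cross-tabulated complete-feature assessment for two methods
#'
#' @param cq1,cq2 aligned [CqSet-class] objects.
#' @param threshold1,threshold2 per-method quality cuts.
#' @return list with \code{table} (3x3 counts, method 1 in rows), and the
#'   per-method marginal counts \code{margins1}, \code{margins2}.  Cells sum
#'   to the number of features.
#' @export
completeFeaturesTable <- function(cq1, cq2,
                                  threshold1 = qualityThreshold(cq1),
                                  threshold2 = qualityThreshold(cq2)) {
    .checkAligned(cq1, cq2)
    f1 <- classifyFeatures(cq1, threshold1)
    f2 <- classifyFeatures(cq2, threshold2)
    tab <- table(f1, f2, dnn = c(methodName(cq1), methodName(cq2)))
    list(table = unclass(tab), margins1 = rowSums(tab),
         margins2 = colSums(tab))
}

#' Expected expression of a mixture from the pure pools
#'
#' Mixing is linear on the abundance scale (abundance \eqn{\propto 2^{-E}}
#' for threshold-cycle expression \eqn{E}), so a mixture with pool weights
#' \eqn{(w_A, w_B)} relative to the pure samples has expected expression
#' \deqn{E = -\log_2(w_A 2^{-E_A} + w_B 2^{-E_B}).}
#' A feature lacking a pure value for a pool with positive weight yields a
#' missing result; a pool in which the feature is absent may be encoded as
#' \code{Inf} (zero abundance).
#'
#' @param pureA,pureB numeric vectors of pure-pool expression per feature
#'   (cycles).
#' @param weightA,weightB non-negative scalar pool weights, not both zero.
#' @return numeric vector of expected expression (cycles).
#' @examples
#' expectedExpression(20, 20, 0.1, 0.1)   # 20 - log2(0.2) = 22.3219
#' @export
expectedExpression <- function(pureA, pureB, weightA, weightB) {
    if (weightA < 0 || weightB < 0)
        stop("pool weights must be non-negative")
    if (weightA == 0 && weightB == 0)
        stop("at least one pool weight must be positive")
    contrib <- function(pure, w) {
        if (w == 0) rep(0, length(pure)) else w * 2^(-pure)
    }
    a <- contrib(pureA, weightA)
    b <- contrib(pureB, weightB)
    out <- -log2(a + b)
    if (weightA > 0) out[is.na(pureA)] <- NA
    if (weightB > 0) out[is.na(pureB)] <- NA
    out
}

#' Limit-of-detection assessment
#'
#' Compares average observed expression with dilution-predicted expected
#' expression in the low-input sample types, using three comparisons: each
#' low-input type against the pure-sample prediction, and the lower-input
#' type against the higher-input one (expected there is the observed
#' higher-input expression shifted by the log2 weight ratio).  For each
#' comparison and tolerance the reported limit of detection is the smallest
#' candidate expected-expression value \eqn{t^*} (scanned over the sorted
#' observed expected values, no interpolation) such that the median absolute
#' difference between observed and expected among features with expected
#' \eqn{\ge t^*} is at least the tolerance; missing when never reached.
#' Thresholds are non-decreasing in the tolerance within each comparison.
#'
#' @param cq a [CqSet-class].
#' @param design a [MixtureDesign-class].
#' @param tolerances ascending tolerances in cycles.
#' @param threshold quality cut.
#' @return list with \code{perFeature} (data.frame: comparison, featureId,
#'   expected, observed, difference, propPoorQuality), \code{thresholds}
#'   (matrix comparisons x tolerances) and \code{boxplotData} (average
#'   observed expression per feature/sample-type group with its proportion
#'   of poor-quality replicates, across all sample types).
#' @export
limitOfDetection <- function(cq, design, tolerances = c(0.5, 0.75, 1.0),
                             threshold = qualityThreshold(cq)) {
    stopifnot(all(diff(tolerances) > 0))
    pu <- pureTypes(design)
    low <- lowInputTypes(design)
    stopifnot(length(low) >= 2L)
    w <- poolWeights(design)
    pm <- .typeMeans(cq, pu, threshold)
    lm_ <- .typeMeans(cq, low, threshold)
    cmpName <- c(sprintf("type%d_vs_pure", low[1L]),
                 sprintf("type%d_vs_pure", low[2L]),
                 sprintf("type%d_vs_type%d", low[2L], low[1L]))
    expFromPure <- function(type) {
        wi <- w[match(type, w$sampleType), ]
        expectedExpression(pm$mean[, 1L], pm$mean[, 2L], wi$weightA,
                           wi$weightB)
    }
    ratio <- w$weightA[match(low[1L], w$sampleType)] /
             w$weightA[match(low[2L], w$sampleType)]
    per <- list(
        data.frame(comparison = cmpName[1L], featureId = rownames(cq),
                   expected = expFromPure(low[1L]), observed = lm_$mean[, 1L],
                   propPoorQuality = lm_$propPoor[, 1L]),
        data.frame(comparison = cmpName[2L], featureId = rownames(cq),
                   expected = expFromPure(low[2L]), observed = lm_$mean[, 2L],
                   propPoorQuality = lm_$propPoor[, 2L]),
        data.frame(comparison = cmpName[3L], featureId = rownames(cq),
                   expected = lm_$mean[, 1L] + log2(ratio),
                   observed = lm_$mean[, 2L],
                   propPoorQuality = lm_$propPoor[, 2L]))
    perFeature <- do.call(rbind, per)
    perFeature$difference <- perFeature$observed - perFeature$expected
    keep <- is.finite(perFeature$expected) & is.finite(perFeature$observed)
    perFeature <- perFeature[keep, , drop = FALSE]
    rownames(perFeature) <- NULL
    thr <- matrix(NA_real_, 3L, length(tolerances),
                  dimnames = list(cmpName, as.character(tolerances)))
    for (cmp in cmpName) {
        d <- perFeature[perFeature$comparison == cmp, ]
        if (!nrow(d)) {
            warning("no evaluable features for comparison ", cmp)
            next
        }
        cand <- sort(unique(d$expected))
        for (j in seq_along(tolerances)) {
            for (t in cand) {
                if (stats::median(abs(d$difference[d$expected >= t])) >=
                    tolerances[j]) {
                    thr[cmp, j] <- t
                    break
                }
            }
        }
    }
    allTypes <- sort(unique(w$sampleType))
    am <- .typeMeans(cq, allTypes, threshold)
    e <- cqValues(cq)
    st <- sampleTypes(cq)
    avgObs <- sapply(allTypes, function(ty)
        rowMeans(e[, st == ty, drop = FALSE], na.rm = TRUE))
    box <- data.frame(
        featureId = rep(rownames(cq), length(allTypes)),
        sampleType = rep(allTypes, each = nrow(cq)),
        avgObserved = as.vector(avgObs),
        propPoorQuality = as.vector(am$propPoor))
    box <- box[is.finite(box$avgObserved), , drop = FALSE]
    rownames(box) <- NULL
    list(perFeature = perFeature, thresholds = thr, boxplotData = box)
}

## per-series scaffolding shared by titration and accuracy assessments:
## ordered types, per-type expected expression from the pure means, and the
## stratum d = constant-pure mean - titrated-pure mean (d > 0 <=> the
## titrated component is the more abundant one)
.seriesInfo <- function(cq, design, threshold) {
    pu <- pureTypes(design)
    pm <- .typeMeans(cq, pu, threshold)$mean
    w <- poolWeights(design)
    lapply(titrationSeries(design), function(s) {
        wi <- w[match(s$types, w$sampleType), ]
        expected <- vapply(seq_along(s$types), function(j)
            expectedExpression(pm[, 1L], pm[, 2L], wi$weightA[j],
                               wi$weightB[j]), numeric(nrow(pm)))
        expected <- matrix(expected, nrow = nrow(pm))
        d <- if (s$titrated == "A") pm[, 2L] - pm[, 1L] else pm[, 1L] - pm[, 2L]
        list(types = s$types, titrated = s$titrated, expected = expected,
             d = d)
    })
}

.equalCountBins <- function(d, nbins) {
    edges <- stats::quantile(d, probs = seq(0, 1, length.out = nbins + 1L),
                             na.rm = TRUE, names = FALSE)
    edges <- unique(edges)
    if (length(edges) < 2L) return(NULL)
    bin <- cut(d, edges, include.lowest = TRUE)
    list(edges = edges, bin = bin)
}

#' Titration-response assessment
#'
#' A feature responds to titration when its replicate-mean expression is
#' strictly decreasing in cycle units along the series (abundance strictly
#' increasing as the titrated pool's input doubles); ties count as
#' non-response.  Results are stratified by
#' \eqn{d} = pure expression of the constant component minus pure expression
#' of the titrated component, so \eqn{d > 0} means the titrated component is
#' the more abundant one.
#'
#' @inheritParams limitOfDetection
#' @param nbins number of equal-count bins over \eqn{d}.
#' @return list with \code{perFeature} (series, featureId, responder, d),
#'   \code{counts} (responders / non-responders per series) and \code{bins}
#'   (bin edges, n, proportion responding per series).
#' @export
titrationResponse <- function(cq, design, threshold = qualityThreshold(cq),
                              nbins = 5) {
    info <- .seriesInfo(cq, design, threshold)
    perFeature <- do.call(rbind, lapply(names(info), function(nm) {
        s <- info[[nm]]
        mm <- .typeMeans(cq, s$types, threshold)$mean
        evaluable <- rowSums(is.finite(mm)) == length(s$types)
        resp <- rep(NA, nrow(mm))
        resp[evaluable] <- apply(mm[evaluable, , drop = FALSE], 1L,
                                 function(v) all(diff(v) < 0))
        data.frame(series = nm, featureId = rownames(mm), responder = resp,
                   d = s$d)
    }))
    rownames(perFeature) <- NULL
    ev <- perFeature[!is.na(perFeature$responder), ]
    counts <- do.call(rbind, lapply(split(ev, ev$series), function(d)
        data.frame(series = d$series[1L], responders = sum(d$responder),
                   nonResponders = sum(!d$responder))))
    rownames(counts) <- NULL
    bins <- do.call(rbind, lapply(split(ev[is.finite(ev$d), ],
                                        ev$series[is.finite(ev$d)]),
        function(d) {
            if (!nrow(d)) return(NULL)
            b <- .equalCountBins(d$d, nbins)
            if (is.null(b)) return(NULL)
            agg <- tapply(d$responder, b$bin, mean)
            n <- tapply(d$responder, b$bin, length)
            data.frame(series = d$series[1L], bin = names(agg),
                       n = as.integer(n), propResponding = as.numeric(agg))
        }))
    rownames(bins) <- NULL
    list(perFeature = perFeature, counts = counts, bins = bins)
}

#' Signal-detect slope (accuracy) assessment
#'
#' For each feature and titration series, ordinary least squares of observed
#' expression (replicate-level good-quality estimates, up to 3 types x
#' replicates points) on the expected expression computed from the pure-pool
#' means; the ideal slope is 1.  Slopes with a two-sided p-value at or above
#' 0.05 for the test of slope = 0 are flagged non-significant.  Slopes are
#' summarized by median and MAD within tertile bins of the stratum
#' \eqn{d} (pure-sample expression difference, constant minus titrated).
#'
#' @inheritParams limitOfDetection
#' @return list with \code{perFeature} (series, featureId, slope, pvalue,
#'   significant, d, n) and \code{bins} (tertile edges over d, n, median and
#'   MAD of slopes per bin, pooled over series).
#' @export
signalDetectSlopes <- function(cq, design, threshold = qualityThreshold(cq)) {
    info <- .seriesInfo(cq, design, threshold)
    good <- .goodMask(cq, threshold)
    e <- cqValues(cq)
    st <- sampleTypes(cq)
    perFeature <- do.call(rbind, lapply(names(info), function(nm) {
        s <- info[[nm]]
        slope <- pval <- rep(NA_real_, nrow(e))
        nUsed <- integer(nrow(e))
        xs <- ys <- vector("list", nrow(e))
        for (j in seq_along(s$types)) {
            cols <- which(st == s$types[j])
            for (cc in cols) {
                ok <- good[, cc] & is.finite(s$expected[, j])
                idx <- which(ok)
                for (f in idx) {
                    xs[[f]] <- c(xs[[f]], s$expected[f, j])
                    ys[[f]] <- c(ys[[f]], e[f, cc])
                }
            }
        }
        for (f in seq_len(nrow(e))) {
            xv <- xs[[f]]; yv <- ys[[f]]
            nUsed[f] <- length(xv)
            if (length(xv) < 3L || length(unique(xv)) < 2L) next
            sxx <- sum((xv - mean(xv))^2)
            b1 <- sum((xv - mean(xv)) * (yv - mean(yv))) / sxx
            res <- yv - mean(yv) - b1 * (xv - mean(xv))
            df <- length(xv) - 2L
            se <- sqrt(sum(res^2) / df / sxx)
            slope[f] <- b1
            pval[f] <- if (se == 0) as.numeric(b1 == 0) else
                2 * stats::pt(abs(b1 / se), df, lower.tail = FALSE)
        }
        data.frame(series = nm, featureId = rownames(e), slope = slope,
                   pvalue = pval, significant = !is.na(pval) & pval < 0.05,
                   d = s$d, n = nUsed)
    }))
    rownames(perFeature) <- NULL
    ev <- perFeature[is.finite(perFeature$slope) & is.finite(perFeature$d), ]
    bins <- NULL
    if (nrow(ev) >= 3L) {
        b <- .equalCountBins(ev$d, 3L)
        if (!is.null(b)) {
            med <- tapply(ev$slope, b$bin, stats::median)
            madv <- tapply(ev$slope, b$bin, stats::mad)
            n <- tapply(ev$slope, b$bin, length)
            bins <- data.frame(bin = names(med), n = as.integer(n),
                               median = as.numeric(med),
                               mad = as.numeric(madv))
            rownames(bins) <- NULL
        }
    }
    list(perFeature = perFeature, bins = bins)
}

#' Within-replicate precision assessment
#'
#' For every feature/sample-type group whose present replicates are all good
#' quality and number at least two, computes the within-replicate mean,
#' standard deviation (denominator \eqn{n - 1}) and coefficient of variation
#' CV = SD / mean, stratified into three equal-count bins by the group mean
#' expression.
#'
#' @inheritParams limitOfDetection
#' @return list with \code{perGroup} (featureId, sampleType, n, mean, sd, cv)
#'   and \code{bins} (bin, n, median SD, median CV).
#' @export
precisionSummary <- function(cq, design = NULL,
                             threshold = qualityThreshold(cq)) {
    good <- .goodMask(cq, threshold)
    e <- cqValues(cq)
    st <- sampleTypes(cq)
    types <- sort(unique(st))
    out <- list()
    for (ty in types) {
        cols <- which(st == ty)
        ee <- e[, cols, drop = FALSE]
        gg <- good[, cols, drop = FALSE]
        present <- !is.na(ee)
        nPresent <- rowSums(present)
        allGood <- rowSums(present & gg) == nPresent
        keep <- which(allGood & nPresent >= 2L)
        if (!length(keep)) next
        mu <- rowMeans(ee[keep, , drop = FALSE], na.rm = TRUE)
        sdv <- apply(ee[keep, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
            featureId = rownames(e)[keep], sampleType = ty,
            n = nPresent[keep], mean = mu, sd = sdv, cv = sdv / mu)
    }
    perGroup <- if (length(out)) do.call(rbind, out) else
        data.frame(featureId = character(), sampleType = integer(),
                   n = integer(), mean = numeric(), sd = numeric(),
                   cv = numeric())
    rownames(perGroup) <- NULL
    bins <- NULL
    if (nrow(perGroup) >= 3L) {
        b <- .equalCountBins(perGroup$mean, 3L)
        if (!is.null(b)) {
            bins <- data.frame(
                bin = levels(b$bin),
                n = as.integer(table(b$bin)),
                medianSD = as.numeric(tapply(perGroup$sd, b$bin,
                                             stats::median)),
                medianCV = as.numeric(tapply(perGroup$cv, b$bin,
                                             stats::median)))
        }
    }
    list(perGroup = perGroup, bins = bins)
}
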