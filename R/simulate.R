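#' Noise and failure configuration for the synthetic benchmark
#'
#' @param ctNoiseSd Gaussian replicate noise on the threshold cycle, in
#'   cycles.
#' @param fluorNoiseSd i.i.d. per-cycle fluorescence noise, as a fraction of
#'   each curve's amplitude.
#' @param failureRate probability that a curve fails outright (flat trace),
#'   independently of abundance.
#' @param dropoutMidpoint single-molecule detection ceiling M, in cycles.
#'   Template molecules per reaction are Poisson with mean
#'   \eqn{2^{M - Ct}}: a draw of zero gives a flat (dropped-out) curve, so
#'   the dropout probability \eqn{e^{-2^{M - Ct}}} rises sigmoidally as the
#'   true threshold cycle passes M, and detected curves saturate near
#'   \eqn{M - \log_2 n}.  Use \code{Inf} to disable dropout entirely.
#' @param seed default random seed used by [simulateBenchmark()].
#' @return a list of class \code{"NoiseConfig"}.
#' @export
noiseConfig <- function(ctNoiseSd = 0.25, fluorNoiseSd = 0.02,
                        failureRate = 0.02, dropoutMidpoint = 30,
                        seed = 1L) {
    stopifnot(ctNoiseSd >= 0, fluorNoiseSd >= 0,
              failureRate >= 0, failureRate <= 1)
    structure(list(ctNoiseSd = ctNoiseSd, fluorNoiseSd = fluorNoiseSd,
                   failureRate = failureRate,
                   dropoutMidpoint = dropoutMidpoint, seed = as.integer(seed)),
              class = "NoiseConfig")
}

#' Ground truth for a synthetic two-pool benchmark
#'
#' Draws per-feature pure-pool threshold cycles and curve-shape parameters.
#' A configured fraction of features is specific to pool A, specific to pool
#' B, or absent from both (emulating tissue-specific miRNAs and features
#' unexpressed in all source tissues); absent pools are encoded as
#' \code{Inf} (zero abundance) and contribute nothing to mixtures.
#'
#' @param nFeatures number of features.
#' @param fractions named numeric: fractions of \code{aOnly}, \code{bOnly}
#'   and \code{absent} features (the remainder is present in both pools);
#'   their sum must not exceed 1.
#' @param ctRange range of the uniform distribution of present pure-pool
#'   threshold cycles, in cycles.
#' @param plateauRange,baselineRange,scaleRange uniform ranges of the
#'   per-feature curve plateau (fluorescence), baseline (fluorescence) and
#'   sigmoidal slope scale (cycles).
#' @param seed random seed.
#' @return data.frame with one row per feature: \code{featureId},
#'   \code{ctA}, \code{ctB} (cycles; \code{Inf} = absent from that pool),
#'   \code{plateau}, \code{baseline}, \code{scale}.
#' @export
generateTruth <- function(nFeatures = 754,
                          fractions = c(aOnly = 0.15, bOnly = 0.15,
                                        absent = 0.15),
                          ctRange = c(14, 30),
                          plateauRange = c(1.5, 3.5),
                          baselineRange = c(0, 0.15),
                          scaleRange = c(1.3, 1.9),
                          seed = 1L) {
    stopifnot(nFeatures >= 1)
    fr <- fractions[c("aOnly", "bOnly", "absent")]
    if (anyNA(fr) || any(fr < 0) || sum(fr) > 1)
        stop("fractions must be non-negative and sum to at most 1")
    set.seed(seed)
    u <- stats::runif(nFeatures)
    cls <- ifelse(u < fr[1L], "aOnly",
           ifelse(u < fr[1L] + fr[2L], "bOnly",
           ifelse(u < sum(fr), "absent", "shared")))
    ctA <- stats::runif(nFeatures, ctRange[1L], ctRange[2L])
    ctB <- stats::runif(nFeatures, ctRange[1L], ctRange[2L])
    ctA[cls %in% c("bOnly", "absent")] <- Inf
    ctB[cls %in% c("aOnly", "absent")] <- Inf
    data.frame(
        featureId = sprintf("synth-miR-%04d", seq_len(nFeatures)),
        ctA = ctA, ctB = ctB,
        plateau = stats::runif(nFeatures, plateauRange[1L], plateauRange[2L]),
        baseline = stats::runif(nFeatures, baselineRange[1L],
                                baselineRange[2L]),
        scale = stats::runif(nFeatures, scaleRange[1L], scaleRange[2L]),
        stringsAsFactors = FALSE)
}

#' Simulate a full mixture/dilution benchmark experiment
#'
#' For every feature x sample type the true mixture threshold cycle is the
#' abundance-weighted combination of the pure-pool truths
#' (\eqn{Ct = -\log_2(w_A 2^{-Ct_A} + w_B 2^{-Ct_B})}); each replicate then
#' receives Poisson template sampling against the detection ceiling (see
#' [noiseConfig()]), Gaussian replicate noise on the threshold cycle, and a
#' symmetric-logistic amplification curve
#' \eqn{c + (d - c) / (1 + e^{-(x - x_{mid})/s})} with i.i.d. fluorescence
#' noise.  The logistic midpoint is placed at
#' \eqn{x_{mid} = Ct + s \ln(2 + \sqrt 3)} so that the curve's analytic cpD2
#' equals the (noisy) true threshold cycle, making the truth directly
#' comparable to cpD2-based estimates.  Failed, dropped-out and
#' absent-feature curves are flat (baseline plus fluorescence noise).
#'
#' All randomness is drawn from a single seed in one fixed, vectorized order
#' keyed by (feature, sample type, replicate), so results do not depend on
#' any iteration order.
#'
#' @param truth data.frame from [generateTruth()].
#' @param design a [MixtureDesign-class].
#' @param noise a [noiseConfig()] list.
#' @param nReplicates replicates per sample type.
#' @param nCycles cycles per curve (at least 20).
#' @param seed random seed (defaults to the one in \code{noise}).
#' @return list with \code{dataset} (an [AmplificationSet-class]) and
#'   \code{truth} (data.frame, one row per curve: \code{featureId},
#'   \code{sampleType}, \code{replicate}, \code{sampleId},
#'   \code{mixtureCt} — the deterministic mixture value — \code{trueCt} —
#'   the noisy threshold cycle embedded in the curve, \code{NA} for flat
#'   curves — and the \code{failed}/\code{dropped} flags).
#' @export
simulateBenchmark <- function(truth, design = defaultDesign(),
                              noise = noiseConfig(), nReplicates = 4,
                              nCycles = 46, seed = noise$seed) {
    stopifnot(nCycles >= 20)
    methods::validObject(design)
    w <- poolWeights(design)
    nF <- nrow(truth)
    nT <- nrow(w)
    set.seed(seed)
    ## per feature x type deterministic mixture threshold cycle
    abA <- 2^(-truth$ctA)
    abB <- 2^(-truth$ctB)
    mixCt <- -log2(outer(abA, w$weightA) + outer(abB, w$weightB))
    ## expand to curves: feature fastest, then replicate, then type (fixed
    ## draw order)
    grid <- expand.grid(feature = seq_len(nF), replicate = seq_len(nReplicates),
                        sampleType = w$sampleType, KEEP.OUT.ATTRS = FALSE)
    nC <- nrow(grid)
    ct0 <- mixCt[cbind(grid$feature, match(grid$sampleType, w$sampleType))]
    failed <- stats::runif(nC) < noise$failureRate
    M <- noise$dropoutMidpoint
    if (is.finite(M)) {
        lambda <- ifelse(is.finite(ct0), 2^(M - ct0), 0)
        nMol <- stats::rpois(nC, lambda)
        dropped <- nMol == 0
        ctDet <- ifelse(dropped, NA_real_, M - log2(pmax(nMol, 1L)))
    } else {
        dropped <- !is.finite(ct0)
        ctDet <- ifelse(dropped, NA_real_, ct0)
    }
    ctNoise <- stats::rnorm(nC, 0, noise$ctNoiseSd)
    ct <- ctDet + ctNoise
    flat <- failed | dropped
    ct[flat] <- NA_real_
    ## synthesize fluorescence: symmetric logistic anchored so cpD2 == ct
    s <- truth$scale[grid$feature]
    amp <- truth$plateau[grid$feature] - truth$baseline[grid$feature]
    base <- truth$baseline[grid$feature]
    xmid <- ct + s * log(2 + sqrt(3))
    x <- seq_len(nCycles)
    fl <- matrix(base, nrow = nCycles, ncol = nC, byrow = TRUE)
    live <- which(!flat)
    if (length(live)) {
        z <- outer(x, xmid[live], "-") /
            matrix(s[live], nCycles, length(live), byrow = TRUE)
        fl[, live] <- fl[, live] +
            matrix(amp[live], nCycles, length(live), byrow = TRUE) *
            stats::plogis(z)
    }
    if (noise$fluorNoiseSd > 0)
        fl <- fl + matrix(stats::rnorm(nCycles * nC, 0,
                          rep(noise$fluorNoiseSd * amp, each = nCycles)),
                          nCycles, nC)
    info <- data.frame(
        featureId = truth$featureId[grid$feature],
        sampleId = .sampleId(grid$sampleType, grid$replicate),
        sampleType = as.integer(grid$sampleType),
        replicate = as.integer(grid$replicate),
        stringsAsFactors = FALSE)
    ord <- order(info$featureId, info$sampleType, info$replicate)
    ds <- .newAmplificationSet(fl[, ord, drop = FALSE], info[ord, ])
    methods::validObject(ds)
    truthTab <- data.frame(
        featureId = info$featureId, sampleType = info$sampleType,
        replicate = info$replicate, sampleId = info$sampleId,
        mixtureCt = ct0, trueCt = ct, failed = failed, dropped = dropped,
        stringsAsFactors = FALSE)[ord, ]
    rownames(truthTab) <- NULL
    list(dataset = ds, truth = truthTab)
}

#' Assemble a CqSet of the simulation's true threshold cycles
#'
#' Builds the expression/quality matrices a perfect estimator would recover
#' from a simulated benchmark: expression is the noisy true threshold cycle
#' embedded in each curve (missing for flat curves) and quality is 1 for
#' detected curves and 0 otherwise.  Useful for testing the assessment
#' statistics independently of any curve-fitting step.
#'
#' @param truthTab the \code{truth} table returned by [simulateBenchmark()].
#' @return a [CqSet-class] with \code{methodName = "truth"} and quality
#'   threshold 0.5.
#' @export
truthCqSet <- function(truthTab) {
    feats <- unique(truthTab$featureId)
    samp <- unique(truthTab[order(truthTab$sampleType, truthTab$replicate),
                            c("sampleId", "sampleType", "replicate")])
    expr <- matrix(NA_real_, length(feats), nrow(samp),
                   dimnames = list(feats, samp$sampleId))
    expr[cbind(match(truthTab$featureId, feats),
               match(truthTab$sampleId, samp$sampleId))] <- truthTab$trueCt
    qual <- ifelse(is.na(expr), 0, 1)
    CqSet(expr, qual, methodName = "truth", qualityThreshold = 0.5,
          sampleType = samp$sampleType, replicate = samp$replicate)
}
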