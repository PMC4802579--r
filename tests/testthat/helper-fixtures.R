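## Fixtures built in code; no data files.

## long-format table of synthetic logistic curves for the given features and
## samples (sample ids "<type>:<rep>")
makeAmpTable <- function(features = c("a", "b"), types = 1L, reps = 1L,
                         nCycles = 46, e = 30, s = 2, cLow = 0.1, d = 3) {
    g <- expand.grid(feature = features, sample_type = types,
                     replicate = reps, cycle = seq_len(nCycles),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$deltaRn <- cLow + (d - cLow) * stats::plogis((g$cycle - e) / s)
    g
}

## small CqSet with fully controllable matrices
makeCqSet <- function(expr, qual = NULL, method = "toy", thr = 0.5) {
    if (is.null(qual)) qual <- matrix(1, nrow(expr), ncol(expr),
                                      dimnames = dimnames(expr))
    CqSet(expr, qual, methodName = method, qualityThreshold = thr)
}

## CqSet over the default 10x4 design built from per-feature pure-pool truth;
## expression = expected mixture value + optional noise
designCqSet <- function(ctA, ctB, noiseSd = 0, seed = 1,
                        design = defaultDesign()) {
    set.seed(seed)
    w <- poolWeights(design)
    nF <- length(ctA)
    expected <- -log2(outer(2^(-ctA), w$weightA) + outer(2^(-ctB), w$weightB))
    samp <- expand.grid(replicate = 1:4, sampleType = w$sampleType)
    expr <- expected[, match(samp$sampleType, w$sampleType), drop = FALSE] +
        matrix(stats::rnorm(nF * nrow(samp), 0, noiseSd), nF)
    expr[!is.finite(expr)] <- NA
    dimnames(expr) <- list(sprintf("f%03d", seq_len(nF)),
                           paste(samp$sampleType, samp$replicate, sep = ":"))
    makeCqSet(expr, thr = 0.5)
}

## random admissible parameter draws per model family
randomParams <- function(modelId) {
    switch(modelId,
        b4 = c(b = runif(1, -1.2, -0.3), c = runif(1, 0, 0.3),
               d = runif(1, 1.5, 4), e = runif(1, 15, 35)),
        b5 = c(b = runif(1, -1.2, -0.3), c = runif(1, 0, 0.3),
               d = runif(1, 1.5, 4), e = runif(1, 15, 35),
               f = runif(1, 0.5, 2.5)),
        l4 = c(b = runif(1, -14, -6), c = runif(1, 0, 0.3),
               d = runif(1, 1.5, 4), e = runif(1, 15, 35)),
        l5 = c(b = runif(1, -14, -6), c = runif(1, 0, 0.3),
               d = runif(1, 1.5, 4), e = runif(1, 15, 35),
               f = runif(1, 0.5, 2.5)),
        linexp = c(a = runif(1, 1e-6, 1e-4), k = runif(1, 0.15, 0.35),
                   m = runif(1, 0, 0.01), o = runif(1, 0, 0.2)))
}

## brute-force cpd2 oracle: argmax of the analytic second derivative on a
## 0.001-cycle grid
bruteCpd2 <- function(modelId, params, lo = 1, hi = 46) {
    xs <- seq(lo, hi, by = 0.001)
    xs[which.max(curveSecondDeriv(modelId, params, xs))]
}
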