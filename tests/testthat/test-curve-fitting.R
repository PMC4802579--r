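ampCurve <- function(x, y, f = "f", s = "1:1")
    new("AmplificationCurve", featureId = f, sampleId = s,
        cycles = as.numeric(x), fluor = as.numeric(y))

test_that("l4 parameters are recovered from a noise-free l4 curve", {
    x <- 1:46
    p <- c(b = -8, c = 0.1, d = 3.0, e = 30)
    y <- predictCurve("l4", p, x)
    fit <- fitModel(ampCurve(x, y), "l4")
    expect_true(fit@converged)
    expect_equal(unname(fit@params[names(p)]), unname(p), tolerance = 1e-4)
    expect_gte(fit@rSquared, 1 - 1e-10)
})

test_that("flat and too-short inputs are handled as specified", {
    expect_false(fitModel(ampCurve(1:46, rep(1.3, 46)), "l4")@converged)
    expect_error(fitModel(ampCurve(1:5, runif(5)), "l4"), "too few")
    ## non-converged fit gives a missing estimate, not an error
    expect_true(is.na(cpd2(fitModel(ampCurve(1:46, rep(0, 46)), "b4"))))
})

test_that("cpd2 of a symmetric logistic matches the closed form", {
    ## f(x) = c + (d-c)/(1+exp(-(x-e)/s)) has cpD2 at e - s*log(2+sqrt(3));
    ## in the b4 parameterization s = -1/b
    set.seed(21)
    for (i in 1:25) {
        e <- runif(1, 12, 38)
        s <- runif(1, 1, 3)
        fit <- new("FittedCurve", modelId = "b4",
                   params = c(b = -1 / s, c = 0.1, d = 3, e = e),
                   converged = TRUE, rSquared = 1, residSS = 0,
                   cycleRange = c(1, 46))
        expect_equal(cpd2(fit), e - s * log(2 + sqrt(3)), tolerance = 1e-6)
    }
    ## the worked case e = 30, s = 2
    fit <- new("FittedCurve", modelId = "b4",
               params = c(b = -0.5, c = 0.1, d = 3, e = 30),
               converged = TRUE, rSquared = 1, residSS = 0,
               cycleRange = c(1, 46))
    expect_equal(cpd2(fit), 30 - 2 * log(2 + sqrt(3)), tolerance = 1e-8)
})

test_that("shifting a curve right by delta shifts cpd2 by exactly delta", {
    base <- c(b = -0.6, c = 0.05, d = 2.5, e = 24)
    f0 <- new("FittedCurve", modelId = "b4", params = base, converged = TRUE,
              rSquared = 1, residSS = 0, cycleRange = c(1, 46))
    for (delta in c(1.5, 4, 7.25)) {
        shifted <- base
        shifted["e"] <- base["e"] + delta
        f1 <- new("FittedCurve", modelId = "b4", params = shifted,
                  converged = TRUE, rSquared = 1, residSS = 0,
                  cycleRange = c(1, 46))
        expect_equal(cpd2(f1) - cpd2(f0), delta, tolerance = 1e-6)
    }
})

test_that("cpd2 equals the brute-force grid argmax for every family", {
    set.seed(22)
    for (m in listModels()) {
        for (i in 1:8) {
            p <- randomParams(m)
            fit <- new("FittedCurve", modelId = m, params = p,
                       converged = TRUE, rSquared = 1, residSS = 0,
                       cycleRange = c(1, 46))
            expect_equal(cpd2(fit), bruteCpd2(m, p), tolerance = 0.01,
                         label = paste(m, i))
        }
    }
})

test_that("l4 fit of a noise-free l4 curve reproduces the generating cpd2", {
    set.seed(23)
    for (i in 1:5) {
        p <- randomParams("l4")
        y <- predictCurve("l4", p, 1:46)
        fit <- fitModel(ampCurve(1:46, y), "l4")
        expect_true(fit@converged)
        expect_equal(cpd2(fit), bruteCpd2("l4", p), tolerance = 0.01)
    }
})

test_that("R-squared is exact for perfect fits and decays with noise", {
    x <- 1:46
    y <- predictCurve("b4", c(b = -0.7, c = 0.1, d = 3, e = 28), x)
    fit0 <- fitModel(ampCurve(x, y), "b4")
    expect_equal(fit0@rSquared, 1, tolerance = 1e-12)
    set.seed(24)
    r2 <- sapply(c(0.01, 0.05, 0.2, 0.5), function(sd) {
        mean(replicate(8, fitModel(ampCurve(x, y + rnorm(46, 0, sd)),
                                   "b4")@rSquared))
    })
    expect_true(all(diff(r2) < 0))
    expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("batch estimation fills matrices, records failures, is deterministic", {
    tr <- generateTruth(8, seed = 31)
    nz <- noiseConfig(ctNoiseSd = 0, fluorNoiseSd = 0, failureRate = 0.15,
                      dropoutMidpoint = Inf)
    sim <- simulateBenchmark(tr, noise = nz, nReplicates = 2, nCycles = 46,
                             seed = 31)
    cq <- estimateExpression(sim$dataset, "b4")
    expect_equal(dim(cqValues(cq)), c(8L, 20L))
    expect_equal(methodName(cq), "b4")
    ## with zero fluorescence noise, flat curves are exactly the injected
    ## failures plus absent features: those and only those are missing
    flat <- is.na(sim$truth$trueCt)
    est <- cqValues(cq)[cbind(match(sim$truth$featureId, rownames(cq)),
                              match(sim$truth$sampleId, colnames(cq)))]
    expect_identical(is.na(est), flat)
    ## estimates lie in [1, C] and noise-free fits are near-perfect
    expect_true(all(est[!flat] >= 1 & est[!flat] <= 46))
    expect_true(all(qualityScores(cq)[!is.na(cqValues(cq))] >= 0.999))
    cq2 <- estimateExpression(sim$dataset, "b4")
    expect_identical(cqValues(cq2), cqValues(cq))
})
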