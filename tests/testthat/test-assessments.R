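test_that("expected expression follows abundance-scale mixing", {
    ## pure identity
    expect_equal(expectedExpression(c(18, 25), c(30, 12), 1, 0), c(18, 25))
    ## equal pools at a tenth each: E - log2(0.2)
    expect_equal(expectedExpression(20, 20, 0.1, 0.1), 22.3219281,
                 tolerance = 1e-6)
    ## tenfold dilution shifts by exactly log2(10)
    e1 <- expectedExpression(c(15, 22, 28), c(17, 20, 31), 0.4, 0.7)
    e2 <- expectedExpression(c(15, 22, 28), c(17, 20, 31), 0.04, 0.07)
    expect_equal(e2 - e1, rep(log2(10), 3), tolerance = 1e-12)
    ## missing required pure value propagates; absent pool (Inf) does not
    expect_true(is.na(expectedExpression(NA, 20, 0.5, 0.5)))
    expect_equal(expectedExpression(Inf, 20, 0.5, 0.5), 21)
    expect_error(expectedExpression(20, 20, 0, 0), "positive")
    expect_error(expectedExpression(20, 20, -1, 1), "non-negative")
})

test_that("feature categories partition the features and tables add up", {
    set.seed(41)
    for (i in 1:15) {
        nF <- sample(5:40, 1)
        expr <- matrix(runif(nF * 8, 15, 35), nF,
                       dimnames = list(sprintf("f%02d", 1:nF),
                                       paste(rep(1:2, each = 4), 1:4,
                                             sep = ":")))
        expr[runif(length(expr)) < 0.2] <- NA
        qual <- matrix(runif(nF * 8), nF, dimnames = dimnames(expr))
        cq1 <- makeCqSet(expr, qual, thr = runif(1, 0.2, 0.8))
        cls <- classifyFeatures(cq1)
        expect_equal(sum(table(cls)), nF)        # partition
        expect_false(anyNA(cls))
        cq2 <- makeCqSet(expr + rnorm(length(expr)),
                         matrix(runif(nF * 8), nF, dimnames = dimnames(expr)),
                         thr = 0.5)
        cft <- completeFeaturesTable(cq1, cq2)
        expect_equal(sum(cft$table), nF)          # grand total
        expect_equal(unname(rowSums(cft$table)), unname(cft$margins1))
        expect_equal(unname(colSums(cft$table)), unname(cft$margins2))
    }
})

test_that("all-good and identical inputs give diagonal complete tables", {
    cq <- designCqSet(c(20, 22, 24), c(21, 23, 25))
    expect_equal(unname(table(classifyFeatures(cq))["complete"]), 3L)
    cft <- completeFeaturesTable(cq, cq)
    expect_equal(sum(diag(cft$table)), 3L)
    expect_equal(sum(cft$table) - sum(diag(cft$table)), 0L)
})

test_that("expression comparison flags exactly the perturbed entries", {
    cq <- designCqSet(c(20, 24, 28), c(22, 26, 30), seed = 5)
    none <- expressionComparison(cq, cq, deltaThreshold = 2)
    expect_equal(nrow(none$flagged), 0L)
    e2 <- cqValues(cq)
    e2["f002", "7:3"] <- e2["f002", "7:3"] + 4   # 2x the threshold
    cq2 <- makeCqSet(e2, qualityScores(cq))
    one <- expressionComparison(cq, cq2, deltaThreshold = 2)
    expect_equal(nrow(one$flagged), 1L)
    expect_equal(one$flagged$featureId, "f002")
    expect_equal(one$flagged$sampleId, "7:3")
    ## alignment errors name the first disagreeing label
    cq3 <- cq2
    rownames(cq3)[1] <- "other"
    expect_error(expressionComparison(cq, cq3, 2), "other")
})

test_that("LOD recovers a constructed step-function breakpoint exactly", {
    ## |observed - expected| is 0 below expected expression 28 and 2 from 28
    ## on; the well-measured features dominate every scan suffix below the
    ## step, so the threshold scan must return exactly 28 for every
    ## tolerance <= 2 and miss for tolerances beyond the maximum difference
    expct <- c(rep(c(20, 22, 24, 26), each = 6), 28, 29, 30)
    pure <- expct - log2(5)     # type 9 expected = pure + log2(5)
    cq <- designCqSet(pure, pure)
    e <- cqValues(cq)
    shift <- ifelse(expct >= 28, 2, 0)
    e[, grepl("^9:", colnames(e))] <-
        e[, grepl("^9:", colnames(e))] + shift
    cqS <- makeCqSet(e, qualityScores(cq))
    lod <- limitOfDetection(cqS, defaultDesign(),
                            tolerances = c(0.5, 0.75, 2))
    expect_equal(unname(lod$thresholds["type9_vs_pure", ]), rep(28, 3))
    ## tolerance above the maximum difference: threshold missing
    lod2 <- limitOfDetection(cqS, defaultDesign(), tolerances = c(0.5, 2, 3))
    expect_true(is.na(lod2$thresholds["type9_vs_pure", "3"]))
    ## thresholds are non-decreasing in tolerance for every comparison
    th <- lod2$thresholds
    for (r in seq_len(nrow(th))) {
        v <- th[r, ][!is.na(th[r, ])]
        if (length(v) > 1) expect_true(all(diff(v) >= 0))
    }
})

test_that("LOD per-feature records carry poor-quality proportions", {
    cq <- designCqSet(c(20, 24), c(21, 25))
    q <- qualityScores(cq)
    q["f001", "9:1"] <- 0   # one poor replicate out of four
    cq2 <- makeCqSet(cqValues(cq), q)
    lod <- limitOfDetection(cq2, defaultDesign())
    pf <- lod$perFeature
    expect_equal(pf$propPoorQuality[pf$comparison == "type9_vs_pure" &
                                    pf$featureId == "f001"], 0.25)
    expect_true(all(pf$propPoorQuality %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("titration response is strict monotone decrease of the Cq means", {
    ## noise-free mixture data: every feature present in the titrated pool
    ## responds; a feature absent from it cannot
    ctA <- c(18, 22, 26, Inf)
    ctB <- c(20, 24, Inf, 22)
    cq <- designCqSet(ctA, ctB)
    tit <- titrationResponse(cq, defaultDesign())
    pf <- tit$perFeature
    ## series B titrates pool B (types 2-4): f003 (absent in B) gets a
    ## constant series, so either unevaluable or a non-response
    inB <- pf[pf$series == "B", ]
    expect_true(all(inB$responder[inB$featureId %in%
                                  c("f001", "f002", "f004")]))
    expect_false(isTRUE(inB$responder[inB$featureId == "f003"]))
    inA <- pf[pf$series == "A", ]
    expect_true(all(inA$responder[inA$featureId %in%
                                  c("f001", "f002", "f003")]))
    ## d stratum: constant-pure minus titrated-pure, in cycles
    expect_equal(inB$d[inB$featureId == "f001"], 18 - 20)
    expect_equal(inA$d[inA$featureId == "f001"], 20 - 18)
    ## ties count as non-response
    e <- cqValues(cq)
    e[1, grepl("^(2|3|4):", colnames(e))] <- 25
    tie <- titrationResponse(makeCqSet(e, qualityScores(cq)),
                             defaultDesign())
    expect_false(tie$perFeature$responder[tie$perFeature$series == "B" &
        tie$perFeature$featureId == "f001"])
})

test_that("signal-detect slopes are 1 on perfect data and 0 on flat data", {
    set.seed(47)
    cq <- designCqSet(runif(30, 16, 28), runif(30, 16, 28))
    acc <- signalDetectSlopes(cq, defaultDesign())
    sl <- acc$perFeature$slope
    expect_true(all(abs(sl[!is.na(sl)] - 1) < 1e-6))
    ## constant observed values: slope 0, not significant
    e <- cqValues(cq)
    e[1, grepl("^(2|3|4):", colnames(e))] <- 24
    acc2 <- signalDetectSlopes(makeCqSet(e, qualityScores(cq)),
                               defaultDesign())
    row <- acc2$perFeature[acc2$perFeature$series == "B" &
                           acc2$perFeature$featureId == "f001", ]
    expect_equal(row$slope, 0, tolerance = 1e-12)
    expect_false(row$significant)
    ## tertile bins cover all evaluable features
    expect_equal(sum(acc$bins$n),
                 sum(is.finite(acc$perFeature$slope) &
                     is.finite(acc$perFeature$d)))
})

test_that("slope recovery under replicate noise is unbiased", {
    ## Gaussian replicate noise, sd 0.25 cycles, 500 features: the median
    ## signal-detect slope stays within [0.9, 1.1]
    set.seed(48)
    cq <- designCqSet(runif(500, 15, 29), runif(500, 15, 29),
                      noiseSd = 0.25, seed = 48)
    acc <- signalDetectSlopes(cq, defaultDesign())
    med <- median(acc$perFeature$slope, na.rm = TRUE)
    expect_gte(med, 0.9)
    expect_lte(med, 1.1)
})

test_that("precision matches hand computation and a brute-force oracle", {
    e <- matrix(c(19, 20, 21, 20,
                  20, 20, 20, 20), 2, 4, byrow = TRUE,
                dimnames = list(c("v", "w"), paste("1", 1:4, sep = ":")))
    cq <- makeCqSet(e)
    pre <- precisionSummary(cq)
    g <- pre$perGroup
    expect_equal(g$sd[g$featureId == "v"], 0.8164966, tolerance = 1e-6)
    expect_equal(g$cv[g$featureId == "v"], 0.04082483, tolerance = 1e-6)
    expect_equal(g$sd[g$featureId == "w"], 0)
    expect_equal(g$cv[g$featureId == "w"], 0)

    ## oracle equivalence on random replicate groups + permutation invariance
    set.seed(49)
    cqR <- designCqSet(runif(25, 16, 28), runif(25, 16, 28), noiseSd = 0.4,
                       seed = 49)
    preR <- precisionSummary(cqR)
    eR <- cqValues(cqR)
    st <- sampleTypes(cqR)
    for (k in sample(nrow(preR$perGroup), 20)) {
        row <- preR$perGroup[k, ]
        vals <- eR[row$featureId, st == row$sampleType]
        vals <- vals[!is.na(vals)]
        mu <- sum(vals) / length(vals)
        sd2 <- sqrt(sum((vals - mu)^2) / (length(vals) - 1))
        expect_equal(row$mean, mu, tolerance = 1e-12)
        expect_equal(row$sd, sd2, tolerance = 1e-12)
        expect_equal(row$cv, sd2 / mu, tolerance = 1e-12)
    }
    ## shuffling replicate columns leaves every SD/CV unchanged
    perm <- order(replicates(cqR), decreasing = TRUE)
    eP <- eR[, perm]
    qP <- qualityScores(cqR)[, perm]
    cqP <- CqSet(eP, qP, methodName = "perm", qualityThreshold = 0.5,
                 sampleType = st[perm], replicate = replicates(cqR)[perm])
    preP <- precisionSummary(cqP)
    a <- preR$perGroup[order(preR$perGroup$featureId,
                             preR$perGroup$sampleType), ]
    b <- preP$perGroup[order(preP$perGroup$featureId,
                             preP$perGroup$sampleType), ]
    expect_equal(a$sd, b$sd, tolerance = 1e-12)
    expect_equal(a$cv, b$cv, tolerance = 1e-12)
})

test_that("quality summary separates present and missing estimates", {
    e <- matrix(c(20, NA, 24, NA), 2, 2,
                dimnames = list(c("a", "b"), c("1:1", "1:2")))
    q <- matrix(c(0.999, 0, 0.95, 0), 2, 2, dimnames = dimnames(e))
    qs <- qualitySummary(makeCqSet(e, q))
    expect_equal(nrow(qs$present), 2L)
    expect_equal(qs$missingQuality, c(0, 0))
    expect_equal(sum(qs$binned), 2L)
})
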