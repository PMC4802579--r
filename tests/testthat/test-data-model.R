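test_that("long-table construction counts records and enforces contiguity", {
    d <- makeAmpTable(c("a", "b"), types = 1L, reps = 1L, nCycles = 46)
    expect_equal(nrow(d), 92L)
    x <- AmplificationSet(d)
    expect_equal(nCycles(x), 46L)
    expect_equal(nrow(ampData(x)), 92L)

    ## deleting one cycle row must name the offending curve
    bad <- d[!(d$feature == "b" & d$cycle == 17L), ]
    expect_error(AmplificationSet(bad), "(b, 1:1)", fixed = TRUE)

    ## missing column named in the schema error
    expect_error(AmplificationSet(d[, setdiff(colnames(d), "deltaRn")]),
                 "deltaRn")
})

test_that("amplification table round-trips through CSV losslessly", {
    set.seed(42)
    d <- makeAmpTable(c("x", "y", "z"), types = 1:2, reps = 1:2, nCycles = 12)
    d$deltaRn <- d$deltaRn + rnorm(nrow(d), 0, 0.05)
    x <- AmplificationSet(d)
    p <- withr::local_tempfile(fileext = ".csv")
    writeAmplificationTable(x, p)
    y <- readAmplificationTable(p)
    expect_identical(ampData(y)[, 1:4], ampData(x)[, 1:4])
    expect_equal(ampData(y)$deltaRn, ampData(x)$deltaRn, tolerance = 1e-12)
})

test_that("column mapping ingests foreign headers", {
    d <- makeAmpTable("a", nCycles = 10)
    colnames(d) <- c("Assay", "SampleGroup", "Rep", "Cycle", "Rn")
    p <- withr::local_tempfile(fileext = ".csv")
    data.table::fwrite(d, p)
    x <- readAmplificationTable(p, columnMap = c(
        feature = "Assay", sample_type = "SampleGroup", replicate = "Rep",
        cycle = "Cycle", deltaRn = "Rn"))
    expect_equal(nCycles(x), 10L)
    expect_equal(featureIds(x), "a")
})

test_that("extractCurve returns the full ordered trace and rebuilds the set", {
    d <- makeAmpTable(c("a", "b"), types = c(1L, 2L), reps = 1:2,
                      nCycles = 20)
    x <- AmplificationSet(d)
    cv <- extractCurve(x, "a", "2:1")
    expect_s4_class(cv, "AmplificationCurve")
    expect_equal(cv@cycles, as.numeric(1:20))
    expect_error(extractCurve(x, "nope", "1:1"), "no curve")

    ## round-trip: long data -> set -> long data is the identity
    rebuilt <- AmplificationSet(ampData(x))
    expect_identical(ampData(rebuilt), ampData(x))
})

test_that("sample identity maps (type, replicate) one-to-one", {
    d <- makeAmpTable("a", types = 1L, reps = 1:2, nCycles = 5)
    x <- AmplificationSet(d)
    expect_setequal(sampleIds(x), c("1:1", "1:2"))
})

test_that("CqSet import handles blanks, sentinels and permuted labels", {
    e <- matrix(c(20, 21, NA, 23, 24, 25, 26, 27, 28, 29, 30, 31), 3, 4,
                dimnames = list(c("m1", "m2", "m3"),
                                c("1:1", "1:2", "2:1", "2:2")))
    q <- matrix(runif(12, 0.9, 1), 3, 4, dimnames = dimnames(e))
    ed <- data.frame(feature = rownames(e), e, check.names = FALSE)
    ed[1, 3] <- ""          # blank cell -> missing expression
    pe <- withr::local_tempfile(fileext = ".csv")
    pq <- withr::local_tempfile(fileext = ".csv")
    data.table::fwrite(ed, pe)
    ## permute quality rows and columns: label alignment must restore them
    qd <- data.frame(feature = rownames(q)[c(2, 3, 1)],
                     q[c(2, 3, 1), c(3, 1, 4, 2)], check.names = FALSE)
    data.table::fwrite(qd, pq)
    x <- readCqSet(pe, pq, methodName = "vendor", qualityThreshold = 1.25)
    expect_equal(sum(is.na(cqValues(x))), 2L)  # the NA and the blank
    expect_equal(qualityScores(x), q)
    expect_equal(methodName(x), "vendor")
    expect_equal(sampleTypes(x), c(1L, 1L, 2L, 2L))

    ## axis mismatch is an alignment error naming the first bad label
    qd2 <- qd
    qd2$feature[1] <- "mX"
    data.table::fwrite(qd2, pq)
    expect_error(readCqSet(pe, pq), "mX")
})

test_that("CqSet round-trips through paired CSVs", {
    cq <- designCqSet(c(20, 25), c(22, 28), noiseSd = 0.3, seed = 9)
    pe <- withr::local_tempfile(fileext = ".csv")
    pq <- withr::local_tempfile(fileext = ".csv")
    writeCqSet(cq, pe, pq)
    y <- readCqSet(pe, pq, methodName = methodName(cq),
                   qualityThreshold = qualityThreshold(cq))
    expect_equal(cqValues(y), cqValues(cq), tolerance = 1e-12)
    expect_equal(qualityScores(y), qualityScores(cq), tolerance = 1e-12)
})

test_that("quality must accompany every present estimate", {
    e <- matrix(20, 1, 2, dimnames = list("f", c("1:1", "1:2")))
    q <- matrix(c(NA, 1), 1, 2, dimnames = dimnames(e))
    expect_error(CqSet(e, q), "quality")
})

test_that("default design encodes the titration and dilution weights", {
    d <- defaultDesign()
    w <- poolWeights(d)
    expect_equal(w$weightB[w$sampleType %in% 2:4], c(0.2, 0.4, 0.8))
    expect_equal(w$weightA[w$sampleType %in% 6:8], c(0.2, 0.4, 0.8))
    expect_equal(unlist(w[w$sampleType == 9, c("weightA", "weightB")]),
                 c(weightA = 0.1, weightB = 0.1))
    expect_equal(unlist(w[w$sampleType == 10, c("weightA", "weightB")]),
                 c(weightA = 0.01, weightB = 0.01))
    ## titrated weights in exact ratio 1:2:4
    expect_equal(w$weightB[w$sampleType %in% 2:4] /
                 w$weightB[w$sampleType == 2], c(1, 2, 4))
    expect_true(validObject(d))

    ## violations of the design invariants are rejected
    w2 <- w; w2$weightB[w2$sampleType == 3] <- 0.5
    expect_error(MixtureDesign(w2, 1L, 5L, 2:4, 6:8, c(9L, 10L)), "double")
    w3 <- w; w3$weightA[w3$sampleType == 9] <- 0.2
    expect_error(MixtureDesign(w3, 1L, 5L, 2:4, 6:8, c(9L, 10L)), "equal")
})

test_that("design round-trips through JSON", {
    d <- defaultDesign()
    p <- withr::local_tempfile(fileext = ".json")
    writeDesign(d, p)
    y <- readDesign(p)
    expect_equal(poolWeights(y), poolWeights(d))
    expect_equal(titrationSeries(y), titrationSeries(d))
})
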