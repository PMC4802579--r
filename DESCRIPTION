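Package: ampliBench
Title: Benchmarking of qPCR Amplification-Curve Expression Estimators
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to estimate expression (threshold cycles) from raw qPCR
    amplification curves by sigmoidal model fitting with the
    second-derivative-maximum (cpD2) rule, and to assess and compare
    expression-estimation algorithms on a mixture/dilution benchmark design.
    Provides quality-score diagnostics, expression comparison, complete-feature
    counts, limit-of-detection estimation, titration-response, signal-detect
    slope accuracy and replicate precision assessments, together with a
    ground-truthed synthetic benchmark generator emulating a two-pool
    titration/dilution experiment with realistic dropout and fit failure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, qPCR, QualityControl, Preprocessing
RoxygenNote: 7.3.3
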