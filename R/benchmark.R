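#' Configuration for a one-shot benchmark run
#'
#' @param nFeatures number of synthetic features (ignored when
#'   \code{rawPath} points at an existing amplification table).
#' @param models one or two registered model identifiers; with two models
#'   the two-method comparisons (expression comparison, complete-feature
#'   cross-table) are included.
#' @param qcThresholds named numeric, good-quality \eqn{R^2} cut per model.
#' @param deltaThreshold expression-comparison flagging threshold (cycles).
#' @param tolerances ascending limit-of-detection tolerances (cycles).
#' @param seed integer seed governing simulation.
#' @param outputDir directory for the report bundle (created if needed).
#' @param rawPath optional CSV of raw amplification data to load instead of
#'   simulating.
#' @param noise a [noiseConfig()] list (simulation only).
#' @param nReplicates,nCycles simulated experiment size.
#' @return a list of class \code{"BenchmarkConfig"}.
#' @export
benchmarkConfig <- function(nFeatures = 754, models = "l4",
                            qcThresholds = NULL, deltaThreshold = 2,
                            tolerances = c(0.5, 0.75, 1.0), seed = 1L,
                            outputDir = "benchmark-out", rawPath = NULL,
                            noise = noiseConfig(), nReplicates = 4,
                            nCycles = 46) {
    stopifnot(length(models) %in% 1:2, all(models %in% listModels()),
              all(diff(tolerances) > 0))
    if (is.null(qcThresholds))
        qcThresholds <- stats::setNames(rep(0.99, length(models)), models)
    if (!is.null(rawPath) && !file.exists(rawPath))
        stop("rawPath does not exist: ", rawPath)
    structure(list(nFeatures = nFeatures, models = models,
                   qcThresholds = qcThresholds,
                   deltaThreshold = deltaThreshold, tolerances = tolerances,
                   seed = as.integer(seed), outputDir = outputDir,
                   rawPath = rawPath, noise = noise,
                   nReplicates = nReplicates, nCycles = nCycles),
              class = "BenchmarkConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("benchmark stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full benchmark pipeline
#'
#' Simulates (or loads) raw amplification data, fits one or two models, runs
#' all seven assessments and writes a CSV/JSON report bundle plus a run log
#' recording the package version, seed and a checksum of the configuration.
#' Given identical configuration and seed the bundle is byte-identical
#' across runs; any stage failure aborts with the stage name.
#'
#' @param config a [benchmarkConfig()] list.
#' @param verbose emit progress messages on standard error.
#' @return invisibly, a list with the in-memory results: \code{cqSets},
#'   \code{quality}, \code{comparison}, \code{completeFeatures}, \code{lod},
#'   \code{titration}, \code{accuracy}, \code{precision}, \code{truth}, and
#'   \code{files} (paths written).
#' @export
runBenchmark <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "BenchmarkConfig"))
    say <- function(...) if (verbose) message(...)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    design <- defaultDesign()
    truthTab <- NULL
    if (is.null(config$rawPath)) {
        say("stage simulate: ", config$nFeatures, " features")
        sim <- .stage("simulate", {
            tr <- generateTruth(config$nFeatures, seed = config$seed)
            simulateBenchmark(tr, design, config$noise,
                              nReplicates = config$nReplicates,
                              nCycles = config$nCycles, seed = config$seed)
        })
        ds <- sim$dataset
        truthTab <- sim$truth
    } else {
        say("stage load: ", config$rawPath)
        ds <- .stage("load", readAmplificationTable(config$rawPath))
    }
    cqSets <- lapply(config$models, function(m) {
        say("stage fit: model ", m)
        .stage(paste0("fit:", m),
               estimateExpression(ds, m,
                   qualityThreshold = config$qcThresholds[[m]]))
    })
    names(cqSets) <- config$models
    cq1 <- cqSets[[1L]]
    say("stage assess")
    qs <- .stage("quality", qualitySummary(cq1))
    cmp <- cft <- NULL
    if (length(cqSets) == 2L) {
        cmp <- .stage("compare",
            expressionComparison(cqSets[[1L]], cqSets[[2L]],
                                 config$deltaThreshold))
        cft <- .stage("complete",
            completeFeaturesTable(cqSets[[1L]], cqSets[[2L]]))
    } else {
        cft <- .stage("complete", {
            cls <- classifyFeatures(cq1)
            list(table = NULL, margins1 = table(cls), margins2 = NULL)
        })
    }
    lod <- .stage("lod", limitOfDetection(cq1, design, config$tolerances))
    tit <- .stage("titration", titrationResponse(cq1, design))
    acc <- .stage("accuracy", signalDetectSlopes(cq1, design))
    pre <- .stage("precision", precisionSummary(cq1))
    say("stage report")
    files <- character()
    wcsv <- function(d, f) {
        data.table::fwrite(d, out(f)); files <<- c(files, out(f)); NULL
    }
    for (m in names(cqSets))
        writeCqSet(cqSets[[m]], out(paste0("expression_", m, ".csv")),
                   out(paste0("quality_", m, ".csv")))
    files <- c(files, out(paste0("expression_", names(cqSets), ".csv")),
               out(paste0("quality_", names(cqSets), ".csv")))
    if (!is.null(truthTab)) wcsv(truthTab, "truth.csv")
    if (!is.null(cmp)) wcsv(cmp$flagged, "expression_comparison_flags.csv")
    wcsv(lod$perFeature, "lod_per_feature.csv")
    wcsv(as.data.frame(lod$thresholds), "lod_thresholds.csv")
    wcsv(tit$perFeature, "titration_per_feature.csv")
    wcsv(acc$perFeature, "accuracy_per_feature.csv")
    wcsv(pre$perGroup, "precision_per_group.csv")
    summary <- list(
        models = config$models,
        seed = config$seed,
        nFeatures = if (is.null(truthTab)) length(featureIds(ds))
                    else config$nFeatures,
        completeFeatures = as.list(cft$margins1),
        completeTable = if (!is.null(cft$table)) cft$table else NULL,
        lodThresholds = lod$thresholds,
        titrationCounts = tit$counts,
        accuracyBins = acc$bins,
        precisionBins = pre$bins,
        nFlagged = if (!is.null(cmp)) nrow(cmp$flagged) else NULL)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", matrix = "rowmajor",
                         force = TRUE, pretty = TRUE, na = "null")
    files <- c(files, out("summary.json"))
    cfgJson <- jsonlite::toJSON(config[setdiff(names(config), "outputDir")],
                                auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(as.character(cfgJson), out("config.json"))
    log <- c(paste0("ampliBench version: ",
                    as.character(utils::packageVersion("ampliBench"))),
             paste0("seed: ", config$seed),
             paste0("models: ", paste(config$models, collapse = ", ")),
             paste0("config sha: ",
                    unname(tools::md5sum(out("config.json")))))
    writeLines(log, out("run_log.txt"))
    files <- c(files, out("config.json"), out("run_log.txt"))
    invisible(list(cqSets = cqSets, quality = qs, comparison = cmp,
                   completeFeatures = cft, lod = lod, titration = tit,
                   accuracy = acc, precision = pre, truth = truthTab,
                   files = files))
}
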