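#!/usr/bin/env Rscript
## Thin command-line wrapper over the ampliBench package.
##
##   Rscript scripts/ampliBench.R simulate --n-features 754 --replicates 4 \
##       --cycles 46 --seed 1 --out raw.csv --out-truth truth.csv
##   Rscript scripts/ampliBench.R fit --input raw.csv --model l4 \
##       --out-expr expr.csv --out-quality quality.csv
##   Rscript scripts/ampliBench.R fit --list-models
##   Rscript scripts/ampliBench.R assess {quality|compare|complete|lod|
##       titration|accuracy|precision} --expr expr.csv --quality quality.csv \
##       [--expr2 ... --quality2 ...] [--design design.json]
##       [--qc-threshold 0.99] --out report.csv
##   Rscript scripts/ampliBench.R benchmark --config config.json
##
## Exit status is 0 on success, nonzero with a stage-named diagnostic.

suppressMessages({
    library(ampliBench)
    library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1L] else ""
args <- args[-1L]
opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
}
has <- function(flag) flag %in% args
die <- function(...) { message("error: ", ...); quit(status = 1L) }

loadDesign <- function() {
    p <- opt("--design")
    if (is.null(p)) defaultDesign() else readDesign(p)
}
loadCq <- function(exprFlag = "--expr", qualFlag = "--quality",
                   name = "imported") {
    e <- opt(exprFlag); q <- opt(qualFlag)
    if (is.null(e) || is.null(q))
        die("assess needs ", exprFlag, " and ", qualFlag)
    readCqSet(e, q, methodName = name,
              qualityThreshold = as.numeric(opt("--qc-threshold", "0.99")))
}

res <- try(switch(cmd,
    simulate = {
        tr <- generateTruth(as.integer(opt("--n-features", "754")),
                            seed = as.integer(opt("--seed", "1")))
        sim <- simulateBenchmark(tr,
            nReplicates = as.integer(opt("--replicates", "4")),
            nCycles = as.integer(opt("--cycles", "46")),
            seed = as.integer(opt("--seed", "1")))
        writeAmplificationTable(sim$dataset, opt("--out", "raw.csv"))
        data.table::fwrite(sim$truth, opt("--out-truth", "truth.csv"))
        message("wrote ", opt("--out", "raw.csv"), " and ",
                opt("--out-truth", "truth.csv"))
    },
    fit = {
        if (has("--list-models")) {
            cat(listModels(), sep = "\n")
        } else {
            ds <- readAmplificationTable(opt("--input"))
            cq <- estimateExpression(ds, opt("--model", "l4"))
            writeCqSet(cq, opt("--out-expr", "expr.csv"),
                       opt("--out-quality", "quality.csv"))
            message("wrote ", opt("--out-expr", "expr.csv"), " and ",
                    opt("--out-quality", "quality.csv"))
        }
    },
    assess = {
        what <- if (length(args)) args[1L] else ""
        cq <- loadCq()
        design <- loadDesign()
        outCsv <- opt("--out", "report.csv")
        out <- switch(what,
            quality = qualitySummary(cq)$present,
            compare = expressionComparison(cq,
                loadCq("--expr2", "--quality2", "imported2"),
                as.numeric(opt("--delta-threshold", "2")))$flagged,
            complete = {
                cls <- classifyFeatures(cq)
                data.frame(featureId = names(cls), category = as.character(cls))
            },
            lod = limitOfDetection(cq, design)$perFeature,
            titration = titrationResponse(cq, design)$perFeature,
            accuracy = signalDetectSlopes(cq, design)$perFeature,
            precision = precisionSummary(cq)$perGroup,
            die("unknown assessment '", what, "'"))
        data.table::fwrite(out, outCsv)
        summ <- switch(what,
            complete = as.list(table(out$category)),
            lod = list(thresholds = limitOfDetection(cq, design)$thresholds),
            titration = titrationResponse(cq, design)$counts,
            accuracy = signalDetectSlopes(cq, design)$bins,
            precision = precisionSummary(cq)$bins,
            NULL)
        if (!is.null(summ))
            write_json(summ, sub("\\.csv$", ".json", outCsv),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
        message("wrote ", outCsv)
    },
    benchmark = {
        cfgPath <- opt("--config")
        cfg <- if (is.null(cfgPath)) benchmarkConfig() else {
            j <- read_json(cfgPath, simplifyVector = TRUE)
            do.call(benchmarkConfig, j[intersect(names(j),
                names(formals(benchmarkConfig)))])
        }
        if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
        if (!is.null(opt("--out-dir"))) cfg$outputDir <- opt("--out-dir")
        runBenchmark(cfg)
    },
    die("usage: ampliBench.R {simulate|fit|assess|benchmark} [options]")
), silent = TRUE)

if (inherits(res, "try-error"))
    die(attr(res, "condition")$message)
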