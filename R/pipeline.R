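# serialize a params object to a plain named list (for the config echo)
.paramsList <- function(x) {
    sl <- methods::slotNames(class(x))
    stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
}

.writeConfig <- function(config, path) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    } else {
        writeLines(utils::capture.output(utils::str(config)), path)
    }
    invisible(path)
}

.logger <- function(path, verbose = TRUE) {
    function(fmt, ...) {
        line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                        sprintf(fmt, ...))
        cat(line, "\n", file = path, append = TRUE)
        if (verbose) message(line)
    }
}

#' Run the detection pipeline and write its outputs
#'
#' Normalizes the cohort, detects outlier splicing events, and writes to
#' `outDir`: `results.tsv` (per junction and direction, with per-sample
#' outlier flags), `burden.tsv` (per-sample splice burden), and
#' `config.json` (the effective parameters) plus `run.log`. Outputs are
#' deterministic for fixed inputs and parameters; inputs are never mutated.
#'
#' @param je a condition-labelled [JunctionExperiment-class] of raw counts.
#' @param geneExpr genes x samples expression matrix (raw expected counts).
#' @param model optional [GeneModel-class] for gene mapping and event
#'   classification.
#' @param outDir output directory (created if needed).
#' @param params an [OutlierParams-class].
#' @param norm a [NormParams-class].
#' @param verbose echo log lines to the console.
#' @return invisibly, the list from [detectEvents()] plus `burden`.
#' @export
runDetection <- function(je, geneExpr, model = NULL, outDir,
                         params = outlierParams(), norm = normParams(),
                         verbose = FALSE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- .logger(file.path(outDir, "run.log"), verbose)
    cond <- sampleCondition(je)
    if (sum(cond == "normal", na.rm = TRUE) < 2L)
        stop("at least 2 normal samples are required")
    log("cohort: %d junctions x %d samples", nrow(je), ncol(je))
    je <- normalizeJunctions(je, geneExpr, model = model, norm = norm)
    res <- detectEvents(je, params, norm)
    log("tested %d (junction, direction) pairs; %d significant at FDR <= %g",
        nrow(res$events), sum(res$events$significant), params@fdrThreshold)
    burden <- computeSpliceBurden(res$events, res$calls, params@fdrThreshold)
    writeEventResults(res$events, file.path(outDir, "results.tsv"), res$calls)
    writeSpliceBurden(burden, file.path(outDir, "burden.tsv"))
    .writeConfig(list(outlier = .paramsList(params), norm = .paramsList(norm)),
                 file.path(outDir, "config.json"))
    log("wrote results.tsv, burden.tsv, config.json")
    res$burden <- burden
    res$je <- je
    invisible(res)
}

#' Simulate, detect, and score against ground truth
#'
#' Runs the full benchmark loop: for each seed, simulate a cohort, run
#' detection with the benchmark fold-change cutoff (default 2, chosen for
#' the simulated data's modest expression variation; the detection default
#' of 10 targets real tumor cohorts), and score gene-level calls at the
#' identified and significant levels.
#'
#' @param params a [SimParams-class]; its seed is replaced by each value of
#'   `seeds` in turn.
#' @param seeds integer vector of replicate seeds (default: `params@seed`).
#' @param foldChangeCutoff detection fold-change cutoff (default 2).
#' @param outlier baseline [OutlierParams-class] for the remaining settings.
#' @param outDir optional directory for `benchmark.tsv`, `config.json` and a
#'   log.
#' @param verbose echo log lines.
#' @return data.frame: one row per seed and level with the confusion
#'   metrics, plus mean rows (`seed = NA`) per level.
#' @export
runSimulationBenchmark <- function(params = simParams(), seeds = NULL,
                                   foldChangeCutoff = 2,
                                   outlier = outlierParams(),
                                   outDir = NULL, verbose = FALSE) {
    if (is.null(seeds)) seeds <- params@seed
    op <- outlier
    op@foldChangeCutoff <- foldChangeCutoff
    log <- if (is.null(outDir)) function(...) invisible(NULL)
           else {
               dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
               .logger(file.path(outDir, "run.log"), verbose)
           }
    rows <- lapply(seeds, function(s) {
        p <- params
        p@seed <- as.integer(s)
        sim <- simulateCohort(p)
        je <- annotateJunctions(sim$je, sim$model)
        je <- normalizeJunctions(je, sim$geneExpr)
        res <- detectEvents(je, op)
        ev <- evaluateDetection(res$events, sim$truth, op@fdrThreshold)
        log("seed %d: identified sens %.3f fdr %.3f; significant sens %.3f spec %.3f",
            s, ev$sensitivity[1], ev$fdr[1], ev$sensitivity[2],
            ev$specificity[2])
        cbind(seed = s, ev)
    })
    out <- do.call(rbind, rows)
    means <- do.call(rbind, lapply(split(out, out$level), function(d) {
        data.frame(seed = NA_integer_, level = d$level[1],
                   true_positive = mean(d$true_positive),
                   total_identified = mean(d$total_identified),
                   sensitivity = mean(d$sensitivity),
                   specificity = mean(d$specificity),
                   fdr = mean(d$fdr))
    }))
    out <- rbind(out, means)
    rownames(out) <- NULL
    if (!is.null(outDir)) {
        utils::write.table(out, file.path(outDir, "benchmark.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        .writeConfig(list(sim = .paramsList(params),
                          outlier = .paramsList(op),
                          seeds = seeds),
                     file.path(outDir, "config.json"))
    }
    out
}
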