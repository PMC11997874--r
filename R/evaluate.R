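#' Gene-level calls from detected events
#'
#' Two call levels mirror the benchmark definitions:
#' * `"identified"` - genes with at least one junction having at least one
#'   tumor outlier call that survived the expression-floor and fold-change
#'   filters, regardless of significance;
#' * `"significant"` - genes with at least one junction at
#'   `fdr <= fdrThreshold`.
#' The significant set is always nested in the identified set.
#'
#' @param events the `events` data.frame from [detectEvents()].
#' @param level `"identified"` or `"significant"`.
#' @param fdrThreshold threshold for the significant level (default 0.05).
#' @return character vector of unique gene ids (unmapped junctions are
#'   ignored).
#' @export
geneLevelCalls <- function(events, level = c("identified", "significant"),
                           fdrThreshold = 0.05) {
    level <- match.arg(level)
    keep <- if (level == "identified") events$tumor_outlier_count >= 1L
            else !is.na(events$fdr) & events$fdr <= fdrThreshold
    sort(unique(events$gene[keep & !is.na(events$gene)]))
}

#' Score gene-level calls against simulation ground truth
#'
#' @param calls character vector of called gene ids.
#' @param truth a [SimTruth-class].
#' @return one-row data.frame with `true_positive`, `total_identified`,
#'   `sensitivity` (TP / truth positives; `NA` when there are none),
#'   `specificity` (TN / truth negatives) and `fdr`
#'   ((total - TP) / total; 0 when nothing is called).
#' @examples
#' # positives {A,B}, negatives {C,D,E}, calls {A,C}:
#' # sensitivity 0.5, specificity 2/3, FDR 0.5
#' @export
scoreGeneCalls <- function(calls, truth) {
    stopifnot(methods::is(truth, "SimTruth"))
    calls <- unique(calls)
    pos <- truePositiveGenes(truth)
    neg <- setdiff(simulatedGenes(truth), pos)
    tp <- length(intersect(calls, pos))
    total <- length(calls)
    tn <- length(setdiff(neg, calls))
    data.frame(true_positive = tp,
               total_identified = total,
               sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
               specificity = if (length(neg)) tn / length(neg) else NA_real_,
               fdr = if (total) (total - tp) / total else 0)
}

#' Evaluate a detection run at both call levels
#'
#' @param events the `events` data.frame from [detectEvents()].
#' @param truth a [SimTruth-class].
#' @param fdrThreshold significance threshold (default 0.05).
#' @return data.frame with one row per level (`identified`,
#'   `identified_and_significant`) and the confusion metrics.
#' @export
evaluateDetection <- function(events, truth, fdrThreshold = 0.05) {
    ident <- scoreGeneCalls(geneLevelCalls(events, "identified"), truth)
    sig <- scoreGeneCalls(
        geneLevelCalls(events, "significant", fdrThreshold), truth)
    out <- rbind(ident, sig)
    out <- cbind(level = c("identified", "identified_and_significant"), out)
    rownames(out) <- NULL
    out
}
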