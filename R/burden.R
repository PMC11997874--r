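#' Per-sample splice burden
#'
#' Counts, for every sample (normals included), the significant events in
#' which that sample is itself an outlier, split by direction and by event
#' type. Only events with `fdr <= fdrThreshold` contribute.
#'
#' @param events the `events` data.frame from [detectEvents()].
#' @param calls the matching [OutlierCalls-class] from the same run.
#' @param fdrThreshold significance threshold (default 0.05).
#' @return data.frame with columns `sample`, `condition`, `over_count`,
#'   `under_count`, `total`, and one column per event type.
#' @export
computeSpliceBurden <- function(events, calls, fdrThreshold = 0.05) {
    m <- outlierCallMatrix(calls)
    if (!all(events$junction_id %in% rownames(m)))
        stop("events and calls come from different runs")
    sig <- events[!is.na(events$fdr) & events$fdr <= fdrThreshold, ,
                  drop = FALSE]
    samples <- colnames(m)
    over <- under <- stats::setNames(integer(length(samples)), samples)
    etypes <- sort(unique(events$event_type))
    etypes <- etypes[!is.na(etypes)]
    byType <- matrix(0L, length(samples), length(etypes),
                     dimnames = list(samples, etypes))
    for (i in seq_len(nrow(sig))) {
        row <- m[sig$junction_id[i], ]
        code <- if (sig$direction[i] == "over") 1L else -1L
        hit <- !is.na(row) & row == code
        if (sig$direction[i] == "over") over[hit] <- over[hit] + 1L
        else under[hit] <- under[hit] + 1L
        et <- sig$event_type[i]
        if (!is.na(et)) byType[hit, et] <- byType[hit, et] + 1L
    }
    out <- data.frame(sample = samples, condition = calls@condition,
                      over_count = unname(over), under_count = unname(under),
                      total = unname(over + under),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(byType))
}

#' Waterfall-plot data for one junction
#'
#' Per-sample normalized junction expression sorted by descending value
#' (stable for ties), with the tumor/normal condition for coloring.
#' Undefined cells are omitted; the omission count is kept as attribute
#' `omitted`.
#'
#' @param je a normalized [JunctionExperiment-class].
#' @param junction a junction id string (see [junctionIds()]) or row index.
#' @return data.frame with columns `sample`, `condition`, `value`.
#' @export
waterfallData <- function(je, junction) {
    vals <- normalizedExpression(je)
    if (is.character(junction)) {
        if (!junction %in% rownames(vals))
            stop(sprintf("junction '%s' not present", junction))
        junction <- match(junction, rownames(vals))
    }
    v <- vals[junction, ]
    cond <- sampleCondition(je)
    keep <- !is.na(v)
    df <- data.frame(sample = colnames(vals)[keep],
                     condition = unname(cond[keep]),
                     value = unname(v[keep]), stringsAsFactors = FALSE)
    df <- df[order(-df$value), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "omitted") <- sum(!keep)
    df
}

#' Waterfall plot of normalized junction expression
#'
#' One bar per sample, sorted by descending normalized expression, colored
#' by tumor/normal condition: tumors towering over the normal distribution
#' are the outliers the pipeline calls. Requires ggplot2.
#'
#' @inheritParams waterfallData
#' @return a ggplot object.
#' @export
plotJunctionWaterfall <- function(je, junction) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotJunctionWaterfall requires ggplot2")
    df <- waterfallData(je, junction)
    df$sample <- factor(df$sample, levels = df$sample)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                     fill = .data$condition)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "normalized junction expression",
                      fill = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write the splice-burden table
#'
#' @param burden data.frame from [computeSpliceBurden()].
#' @param path output path (TSV).
#' @export
writeSpliceBurden <- function(burden, path) {
    utils::write.table(burden, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(burden)
}
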