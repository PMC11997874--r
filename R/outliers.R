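#' Remove junctions on sex chromosomes
#'
#' Tumor-normal splicing comparisons are not sex-matched by design, so X/Y
#' junctions are filtered before testing (on by default).
#'
#' @param je a [JunctionExperiment-class].
#' @param params an [OutlierParams-class].
#' @return the filtered experiment (unchanged when the filter is off).
#' @export
filterSexChromosomes <- function(je, params = outlierParams()) {
    if (!params@excludeSexChromosomes) return(je)
    chrom <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(je)))
    je[!(chrom %in% params@sexChromosomes), ]
}

# type-7 quantile from an already sorted vector (no names, no checks)
.sortedQuantile <- function(xs, p) {
    xs <- unname(xs)
    n <- length(xs)
    if (n == 1L) return(xs[1])
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# median / lower fence / upper fence of a sorted reference vector
.fences <- function(xs, tailQuantile, iqrMultiplier) {
    q1 <- .sortedQuantile(xs, tailQuantile)
    q3 <- .sortedQuantile(xs, 1 - tailQuantile)
    iqr <- q3 - q1
    c(median = .sortedQuantile(xs, 0.5),
      lower = q1 - iqrMultiplier * iqr,
      upper = q3 + iqrMultiplier * iqr)
}

# apply the over/under rules to a vector of values against one reference
.judge <- function(v, fen, floor, fc, eps) {
    def <- !is.na(v)
    over <- def & v > fen["upper"] & v >= floor &
        v >= fc * max(fen["median"], eps)
    under <- def & v < fen["lower"] & v >= floor & fen["median"] >= floor &
        fen["median"] >= fc * pmax(v, eps)
    over[is.na(over)] <- FALSE
    under[is.na(under)] <- FALSE
    out <- integer(length(v))
    out[over] <- 1L
    out[under] <- -1L
    out[is.na(v)] <- NA_integer_
    out
}

#' Call per-sample junction expression outliers
#'
#' For every junction, robust fences are computed from the normal samples'
#' defined normalized values: `Q(1-tailQuantile) + iqrMultiplier * IQR`
#' (upper) and `Q(tailQuantile) - iqrMultiplier * IQR` (lower). A tumor cell
#' is an over-expression outlier when its value strictly exceeds the upper
#' fence, reaches the absolute floor, and is at least `foldChangeCutoff`
#' times the normal median; an under-expression outlier when it is strictly
#' below the lower fence, both it and the normal median reach the floor
#' (a cell below the floor is never an outlier in either direction), and the
#' normal median is at least `foldChangeCutoff` times the value. Normal
#' samples are judged the same way against leave-one-out fences (a normal
#' compared to a panel containing itself could never be extreme). Junctions
#' with fewer than two defined normal values are left entirely undefined.
#'
#' @param je a normalized [JunctionExperiment-class] with a tumor/normal
#'   condition (see [normalizeJunctions()], [sampleCondition()]).
#' @param params an [OutlierParams-class].
#' @param norm the [NormParams-class] used for normalization (fixes the
#'   scale of the expression floor); defaults to the one recorded by
#'   [normalizeJunctions()].
#' @return an [OutlierCalls-class].
#' @export
callOutliers <- function(je, params = outlierParams(), norm = NULL) {
    vals <- normalizedExpression(je)
    if (is.null(norm))
        norm <- S4Vectors::metadata(je)$normParams
    if (is.null(norm)) norm <- normParams()
    cond <- sampleCondition(je)
    if (sum(cond == "normal", na.rm = TRUE) < 2L)
        stop("at least 2 normal samples are required")
    nIdx <- which(cond == "normal")
    tIdx <- which(cond == "tumor")
    floor <- effectiveFloor(params, norm)
    fc <- params@foldChangeCutoff
    eps <- params@epsilon
    calls <- matrix(NA_integer_, nrow(vals), ncol(vals),
                    dimnames = dimnames(vals))
    summ <- matrix(NA_real_, nrow(vals), 3,
                   dimnames = list(rownames(vals),
                                   c("median", "lower", "upper")))
    for (j in seq_len(nrow(vals))) {
        nv <- vals[j, nIdx]
        def <- which(!is.na(nv))
        if (length(def) < 2L) next
        xs <- sort(nv[def])
        fen <- .fences(xs, params@tailQuantile, params@iqrMultiplier)
        summ[j, ] <- fen
        calls[j, tIdx] <- .judge(vals[j, tIdx], fen, floor, fc, eps)
        # leave-one-out judging of each defined normal
        for (k in def) {
            v <- nv[k]
            loo <- xs[-match(v, xs)]
            fenK <- .fences(loo, params@tailQuantile, params@iqrMultiplier)
            calls[j, nIdx[k]] <- .judge(v, fenK, floor, fc, eps)
        }
    }
    methods::new("OutlierCalls", calls = calls,
                 normalSummary = S4Vectors::DataFrame(summ),
                 condition = unname(cond), params = params)
}

#' One-sided Fisher's exact test for tumor outlier enrichment
#'
#' Exact tail probability of the 2x2 table
#' `[[tumorOutliers, tumorN - tumorOutliers],
#'   [normalOutliers, normalN - normalOutliers]]`
#' toward an excess of outliers among tumors (hypergeometric upper tail).
#' Vectorized over all arguments.
#'
#' @param tumorOutliers,tumorN,normalOutliers,normalN table counts; outlier
#'   counts must not exceed the group sizes.
#' @return p-values in `[0, 1]`; `NA` when a group is empty.
#' @examples
#' fisherTestJunction(20, 40, 0, 25)
#' @export
fisherTestJunction <- function(tumorOutliers, tumorN, normalOutliers,
                               normalN) {
    if (any(tumorOutliers > tumorN, na.rm = TRUE) ||
        any(normalOutliers > normalN, na.rm = TRUE))
        stop("outlier counts cannot exceed group sizes")
    if (any(c(tumorOutliers, normalOutliers) < 0, na.rm = TRUE))
        stop("counts must be non-negative")
    k <- tumorOutliers + normalOutliers
    p <- stats::phyper(tumorOutliers - 1, k, tumorN + normalN - k, tumorN,
                       lower.tail = FALSE)
    p[tumorN == 0 | normalN == 0] <- NA_real_
    p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   preserved; the effective number of tests is the number of non-missing
#'   values).
#' @return adjusted values, order-preserving with the input.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Detect junctions with a significant excess of tumor outliers
#'
#' The full statistical pipeline: sex-chromosome filter, per-sample outlier
#' calls against the normal panel, a one-sided Fisher's exact test per
#' junction and direction (over / under) on the outlier counts, and a
#' Benjamini-Hochberg correction pooled across every tested
#' (junction, direction) pair.
#'
#' @param je a normalized, condition-labelled [JunctionExperiment-class].
#' @param params an [OutlierParams-class].
#' @param norm optional [NormParams-class] (defaults to the one recorded at
#'   normalization time).
#' @return a list with elements
#'   `events` (data.frame: one row per junction and direction with
#'   coordinates, gene, event type, outlier counts, effective group sizes,
#'   `p_value`, `fdr` and `significant`),
#'   `calls` (the [OutlierCalls-class] on the filtered junction set), and
#'   `params`.
#' @export
detectEvents <- function(je, params = outlierParams(), norm = NULL) {
    je <- filterSexChromosomes(je, params)
    calls <- callOutliers(je, params, norm)
    m <- outlierCallMatrix(calls)
    cond <- sampleCondition(je)
    tIdx <- which(cond == "tumor")
    nIdx <- which(cond == "normal")
    tumorN <- rowSums(!is.na(m[, tIdx, drop = FALSE]))
    normalN <- rowSums(!is.na(m[, nIdx, drop = FALSE]))
    cnt <- function(code, idx)
        rowSums(m[, idx, drop = FALSE] == code, na.rm = TRUE)
    gr <- SummarizedExperiment::rowRanges(je)
    rd <- SummarizedExperiment::rowData(je)
    gene <- if ("gene_id" %in% colnames(rd)) rd$gene_id
            else rep(NA_character_, nrow(je))
    etype <- if ("event_type" %in% colnames(rd)) rd$event_type
             else rep(NA_character_, nrow(je))
    base <- data.frame(junction_id = rownames(m),
                       chromosome = as.character(GenomicRanges::seqnames(gr)),
                       intron_start = GenomicRanges::start(gr),
                       intron_end = GenomicRanges::end(gr),
                       strand = as.character(GenomicRanges::strand(gr)),
                       gene = gene, event_type = etype,
                       tumor_n = tumorN, normal_n = normalN,
                       stringsAsFactors = FALSE)
    mk <- function(direction, code) {
        df <- base
        df$direction <- direction
        df$tumor_outlier_count <- cnt(code, tIdx)
        df$normal_outlier_count <- cnt(code, nIdx)
        df
    }
    events <- rbind(mk("over", 1L), mk("under", -1L))
    events <- events[events$tumor_n > 0 & events$normal_n > 0, , drop = FALSE]
    events$p_value <- fisherTestJunction(events$tumor_outlier_count,
                                         events$tumor_n,
                                         events$normal_outlier_count,
                                         events$normal_n)
    events$fdr <- bhAdjust(events$p_value)
    events$significant <- !is.na(events$fdr) & events$fdr <= params@fdrThreshold
    ord <- order(events$chromosome, events$intron_start, events$intron_end,
                 events$direction)
    events <- events[ord, c("junction_id", "chromosome", "intron_start",
                            "intron_end", "strand", "gene", "event_type",
                            "direction", "tumor_outlier_count",
                            "normal_outlier_count", "tumor_n", "normal_n",
                            "p_value", "fdr", "significant")]
    rownames(events) <- NULL
    list(events = events, calls = calls, params = params)
}
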