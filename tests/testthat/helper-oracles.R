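# Independent oracles and toy-fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check: the Fisher oracle
# enumerates 2x2 tables with choose(), the BH oracle applies the step-up
# definition directly, and the outlier oracle applies the call rules
# literally per cell with stats::quantile.

# one-sided (greater) Fisher p by enumeration of all tables with the
# observed margins
oracleFisherGreater <- function(a, tn, b, nn) {
    K <- a + b
    N <- tn + nn
    aVals <- max(0, K - nn):min(K, tn)
    probs <- choose(tn, aVals) * choose(nn, K - aVals) / choose(N, K)
    sum(probs[aVals >= a])
}

# Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * n / j, capped at 1
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(ranked)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

# literal per-cell application of the outlier call rules
oracleCalls <- function(vals, cond, minExpr = 1e-5, fc = 10,
                        tailq = 0.25, mult = 1.5, eps = 1e-12) {
    out <- matrix(NA_integer_, nrow(vals), ncol(vals),
                  dimnames = dimnames(vals))
    nIdx <- which(cond == "normal")
    q <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)
    for (j in seq_len(nrow(vals))) {
        panel <- vals[j, nIdx]
        if (sum(!is.na(panel)) < 2) next
        for (s in seq_len(ncol(vals))) {
            v <- vals[j, s]
            if (is.na(v)) next
            refIdx <- setdiff(nIdx, if (s %in% nIdx) s else integer(0))
            ref <- vals[j, refIdx]
            ref <- ref[!is.na(ref)]
            if (length(ref) < 1) next
            q1 <- q(ref, tailq); q3 <- q(ref, 1 - tailq)
            lo <- q1 - mult * (q3 - q1); up <- q3 + mult * (q3 - q1)
            med <- q(ref, 0.5)
            call <- 0L
            if (v > up && v >= minExpr && v >= fc * max(med, eps)) call <- 1L
            else if (v < lo && v >= minExpr && med >= minExpr &&
                     med >= fc * max(v, eps))
                call <- -1L
            out[j, s] <- call
        }
    }
    out
}

# wrap a normalized value matrix into a labelled JunctionExperiment
toyExperiment <- function(vals, cond, chrom = "chr1") {
    n <- nrow(vals)
    if (is.null(colnames(vals)))
        colnames(vals) <- paste0("s", seq_len(ncol(vals)))
    gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
                                 IRanges::IRanges(seq_len(n) * 1000L,
                                                  seq_len(n) * 1000L + 500L),
                                 strand = "+")
    cts <- matrix(1L, n, ncol(vals), dimnames = dimnames(vals))
    je <- JunctionExperiment(cts, gr, rep(1e6, ncol(vals)), cond)
    storage.mode(vals) <- "double"
    SummarizedExperiment::assay(je, "normexpr", withDimnames = FALSE) <- vals
    je
}

# two overlapping genes plus a distant third, for mapping tie-breaks:
#  A chr1:100-2000 (+), exons 100-200, 900-1000, 1900-2000
#  B chr1:150-5000 (+), exons 150-250, 4900-5000  (wide span)
#  C chr2:100-700 (-),  exons 100-200, 600-700
toyModel <- function() {
    ex <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
        IRanges::IRanges(start = c(100, 900, 1900, 150, 4900, 100, 600),
                         end = c(200, 1000, 2000, 250, 5000, 200, 700)),
        strand = c("+", "+", "+", "+", "+", "-", "-"))
    ex$gene_id <- c("A", "A", "A", "B", "B", "C", "C")
    ex$transcript_id <- c("A.1", "A.1", "A.1", "B.1", "B.1", "C.1", "C.1")
    ex$gene_name <- ex$gene_id
    geneModelFromExons(ex)
}

# tiny simulated cohort for fast end-to-end tests
smallSimParams <- function(seed = 42, ...) {
    simParams(nGenes = 30, nAltGenes = 8, nNormals = 15, nTumors = 20,
              nTumorsHigh = 10, seed = seed, ...)
}
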