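#' Library-size normalization of junction counts
#'
#' Divides each sample's junction counts by its total uniquely mapped reads.
#' On the default `"per_million"` scale the result is reads per million
#' (RPM); on the `"proportion"` scale it is the plain fraction (RPM / 1e6).
#'
#' @param je a [JunctionExperiment-class].
#' @param norm a [NormParams-class].
#' @return numeric matrix, junctions x samples.
#' @export
librarySizeNormalize <- function(je, norm = normParams()) {
    cts <- SummarizedExperiment::assay(je, "counts")
    scale <- if (norm@scale == "per_million") 1e6 else 1
    sweep(cts, 2, libSizes(je), "/") * scale
}

#' Upper-quartile normalization of gene expression
#'
#' Rescales every sample so that the 75th percentile of its expressed genes
#' equals `uqTarget`. The percentile is computed over genes with value > 0
#' (configurable) using the (n+1)p linear-interpolation rule between order
#' statistics (`stats::quantile` type 6).
#'
#' @param expr numeric matrix of gene expression, genes x samples
#'   (e.g. RSEM expected counts).
#' @param uqTarget post-normalization upper-quartile value (default 1000).
#' @param nonzeroOnly compute the percentile over nonzero genes only
#'   (default `TRUE`).
#' @return the rescaled matrix.
#' @examples
#' m <- cbind(s1 = c(0, 10, 20, 30, 40))
#' upperQuartileNormalize(m)  # q75 of {10,20,30,40} = 37.5; 30 -> 800
#' @export
upperQuartileNormalize <- function(expr, uqTarget = 1000, nonzeroOnly = TRUE) {
    stopifnot(uqTarget > 0)
    q75 <- apply(expr, 2, function(v) {
        use <- if (nonzeroOnly) v[v > 0] else v
        if (length(use) == 0L) NA_real_
        else stats::quantile(use, 0.75, type = 6, names = FALSE)
    })
    if (anyNA(q75) || any(q75 <= 0)) {
        bad <- colnames(expr)[which(is.na(q75) | q75 <= 0)]
        stop(sprintf("sample(s) with no expressed genes: %s",
                     paste(bad, collapse = ", ")))
    }
    sweep(expr, 2, q75 / uqTarget, "/")
}

#' Normalize junction expression by host-gene expression
#'
#' Divides the library-size-normalized junction value by the (upper-quartile
#' normalized) expression of the gene the junction lies on. Cells whose gene
#' expression is zero become `NA` ("undefined") and are excluded from
#' outlier calling. Junctions with no gene mapping are carried through with
#' divisor 1 and flagged, preserving novel unannotated junctions.
#'
#' @param libNorm matrix from [librarySizeNormalize()].
#' @param exprNorm matrix from [upperQuartileNormalize()] with gene ids as
#'   row names and the same samples as columns.
#' @param junctionGene character vector parallel to the rows of `libNorm`:
#'   the host gene id of each junction, `NA` when unmapped.
#' @return numeric matrix of normalized junction expression (with `NA` for
#'   undefined cells) and attribute `noGene` (logical per junction).
#' @export
normalizeByGene <- function(libNorm, exprNorm, junctionGene) {
    stopifnot(length(junctionGene) == nrow(libNorm))
    if (!identical(colnames(libNorm), colnames(exprNorm)))
        exprNorm <- exprNorm[, colnames(libNorm), drop = FALSE]
    noGene <- is.na(junctionGene) | !(junctionGene %in% rownames(exprNorm))
    div <- matrix(1, nrow(libNorm), ncol(libNorm))
    if (any(!noGene))
        div[!noGene, ] <- exprNorm[junctionGene[!noGene], , drop = FALSE]
    vals <- libNorm / div
    vals[div == 0] <- NA_real_
    dimnames(vals) <- dimnames(libNorm)
    attr(vals, "noGene") <- noGene
    vals
}

#' Full junction normalization
#'
#' Adds a `"normexpr"` assay to the experiment: junction counts per million
#' (or proportion) divided by the upper-quartile-normalized expression of the
#' host gene. When a [GeneModel-class] is supplied, junctions are first
#' mapped to genes and classified (filling `rowData` columns `gene_id` and
#' `event_type`).
#'
#' @param je a [JunctionExperiment-class].
#' @param geneExpr genes x samples expression matrix (raw expected counts
#'   unless `uqNormalized = TRUE`).
#' @param model optional [GeneModel-class] used to map junctions to genes.
#' @param junctionGene optional precomputed gene assignment (overrides
#'   `model` mapping).
#' @param norm a [NormParams-class].
#' @param uqNormalized set `TRUE` if `geneExpr` is already upper-quartile
#'   normalized.
#' @return the experiment with assay `"normexpr"` and rowData `gene_id`,
#'   `event_type` (when a model is given) and `no_gene`.
#' @export
normalizeJunctions <- function(je, geneExpr, model = NULL,
                               junctionGene = NULL, norm = normParams(),
                               uqNormalized = FALSE) {
    if (!all(colnames(je) %in% colnames(geneExpr)))
        stop("gene expression is missing some cohort samples")
    geneExpr <- geneExpr[, colnames(je), drop = FALSE]
    if (is.null(junctionGene)) {
        if (!is.null(model)) {
            gr <- SummarizedExperiment::rowRanges(je)
            junctionGene <- mapJunctionsToGenes(gr, model)
            SummarizedExperiment::rowData(je)$gene_id <- junctionGene
            SummarizedExperiment::rowData(je)$event_type <-
                classifyEvents(gr, junctionGene, model)
        } else if ("gene_id" %in%
                   colnames(SummarizedExperiment::rowData(je))) {
            junctionGene <- SummarizedExperiment::rowData(je)$gene_id
        } else {
            junctionGene <- rep(NA_character_, nrow(je))
        }
    } else {
        SummarizedExperiment::rowData(je)$gene_id <- junctionGene
    }
    exprNorm <- if (uqNormalized) geneExpr
                else upperQuartileNormalize(geneExpr, norm@uqTarget)
    vals <- normalizeByGene(librarySizeNormalize(je, norm), exprNorm,
                            junctionGene)
    SummarizedExperiment::rowData(je)$no_gene <- attr(vals, "noGene")
    attr(vals, "noGene") <- NULL
    SummarizedExperiment::assay(je, "normexpr") <- vals
    S4Vectors::metadata(je)$normParams <- norm
    je
}
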