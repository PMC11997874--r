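#' Construct a JunctionExperiment
#'
#' @param counts integer matrix of unique junction read counts,
#'   junctions x samples.
#' @param junctions a [GenomicRanges::GRanges] of intron coordinates
#'   (1-based, inclusive; strand `+`, `-` or `*` for undetermined), parallel
#'   to the rows of `counts`.
#' @param libSizes positive numeric vector of per-sample total uniquely
#'   mapped reads, parallel to the columns of `counts`.
#' @param condition optional character vector (`"tumor"`/`"normal"`) per
#'   sample.
#'
#' @return a [JunctionExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200), "+")
#' je <- JunctionExperiment(matrix(5L, 1, 2,
#'                                 dimnames = list(NULL, c("s1", "s2"))),
#'                          gr, libSizes = c(1e6, 2e6),
#'                          condition = c("tumor", "normal"))
#' libSizes(je)
#' @export
JunctionExperiment <- function(counts, junctions, libSizes, condition = NULL) {
    counts <- as.matrix(counts)
    if (length(junctions) != nrow(counts))
        stop("'junctions' must be parallel to the rows of 'counts'")
    if (length(libSizes) != ncol(counts))
        stop("'libSizes' must have one entry per sample")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    cd <- S4Vectors::DataFrame(libSize = as.numeric(libSizes),
                               row.names = colnames(counts))
    if (!is.null(condition)) {
        if (length(condition) != ncol(counts))
            stop("'condition' must have one entry per sample")
        cd$condition <- as.character(condition)
    }
    names(junctions) <- junctionIds(junctions)
    rownames(counts) <- names(junctions)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = junctions, colData = cd)
    methods::new("JunctionExperiment", se)
}

#' Canonical string ids for junctions
#'
#' `"chrom:intronStart-intronEnd:strand"`, unique within a cohort.
#'
#' @param x a `GRanges` of junctions or a `JunctionExperiment`.
#' @return character vector of ids.
#' @export
junctionIds <- function(x) {
    if (methods::is(x, "JunctionExperiment"))
        x <- SummarizedExperiment::rowRanges(x)
    sprintf("%s:%d-%d:%s", as.character(GenomicRanges::seqnames(x)),
            GenomicRanges::start(x), GenomicRanges::end(x),
            as.character(GenomicRanges::strand(x)))
}

#' @describeIn JunctionExperiment-class per-sample library sizes.
#' @param x a `JunctionExperiment`.
#' @export
libSizes <- function(x) {
    stopifnot(methods::is(x, "JunctionExperiment"))
    stats::setNames(SummarizedExperiment::colData(x)$libSize, colnames(x))
}

#' @describeIn JunctionExperiment-class per-sample tumor/normal condition
#'   (`NA` when unset).
#' @export
sampleCondition <- function(x) {
    stopifnot(methods::is(x, "JunctionExperiment"))
    cd <- SummarizedExperiment::colData(x)
    if (!"condition" %in% colnames(cd))
        return(stats::setNames(rep(NA_character_, ncol(x)), colnames(x)))
    stats::setNames(as.character(cd$condition), colnames(x))
}

#' @describeIn JunctionExperiment-class replace the tumor/normal condition.
#' @param value character vector of conditions.
#' @export
`sampleCondition<-` <- function(x, value) {
    SummarizedExperiment::colData(x)$condition <- as.character(value)
    methods::validObject(x)
    x
}

#' @describeIn JunctionExperiment-class the `"normexpr"` assay of normalized
#'   junction expression (after [normalizeJunctions()]); undefined cells are
#'   `NA`.
#' @export
normalizedExpression <- function(x) {
    stopifnot(methods::is(x, "JunctionExperiment"))
    if (!"normexpr" %in% SummarizedExperiment::assayNames(x))
        stop("no 'normexpr' assay; run normalizeJunctions() first")
    SummarizedExperiment::assay(x, "normexpr")
}

setMethod("show", "JunctionExperiment", function(object) {
    cond <- sampleCondition(object)
    cat(sprintf("JunctionExperiment: %d junctions x %d samples (%d tumor, %d normal)\n",
                nrow(object), ncol(object),
                sum(cond == "tumor", na.rm = TRUE),
                sum(cond == "normal", na.rm = TRUE)))
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    if ("gene_id" %in% colnames(SummarizedExperiment::rowData(object))) {
        gid <- SummarizedExperiment::rowData(object)$gene_id
        cat(sprintf("gene-mapped junctions: %d/%d\n",
                    sum(!is.na(gid)), nrow(object)))
    }
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel: %d genes, %d transcripts, %d annotated introns\n",
                length(object@genes), length(object@exonsByTx),
                sum(lengths(object@intronsByTx))))
})

setMethod("show", "OutlierCalls", function(object) {
    cat(sprintf("OutlierCalls: %d junctions x %d samples\n",
                nrow(object@calls), ncol(object@calls)))
    cat(sprintf("  over: %d  under: %d  undefined cells: %d\n",
                sum(object@calls == 1L, na.rm = TRUE),
                sum(object@calls == -1L, na.rm = TRUE),
                sum(is.na(object@calls))))
})

#' @describeIn OutlierCalls-class the coded call matrix (1 over, -1 under,
#'   0 none, NA undefined).
#' @param x an `OutlierCalls` object.
#' @export
outlierCallMatrix <- function(x) {
    stopifnot(methods::is(x, "OutlierCalls"))
    x@calls
}

#' @describeIn OutlierCalls-class per-junction median and robust fences of
#'   the normal panel.
#' @export
normalSummary <- function(x) {
    stopifnot(methods::is(x, "OutlierCalls"))
    x@normalSummary
}
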