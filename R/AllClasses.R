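#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData assay<- rowData<- colData<-
NULL

#' Container for a junction-count cohort
#'
#' A `JunctionExperiment` holds splice-junction read counts for a cohort:
#' one row per junction (the intron removed by the splice, 1-based inclusive
#' coordinates, as reported in STAR's `SJ.out.tab`), one column per sample.
#' It extends [SummarizedExperiment::RangedSummarizedExperiment-class]; the
#' `"counts"` assay carries raw unique-read counts, and after
#' [normalizeJunctions()] a `"normexpr"` assay carries normalized junction
#' expression. `colData` carries the per-sample library size (total uniquely
#' mapped reads) and the tumor/normal condition.
#'
#' @seealso [JunctionExperiment()] for construction,
#'   [normalizeJunctions()], [detectEvents()]
#' @name JunctionExperiment-class
#' @aliases JunctionExperiment-class
#' @exportClass JunctionExperiment
setClass("JunctionExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("JunctionExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"libSize" %in% colnames(cd))
        msg <- c(msg, "colData column 'libSize' is required")
    else if (any(!is.finite(cd$libSize)) || any(cd$libSize <= 0))
        msg <- c(msg, "all library sizes must be positive")
    if ("condition" %in% colnames(cd)) {
        bad <- !(cd$condition %in% c("tumor", "normal") | is.na(cd$condition))
        if (any(bad))
            msg <- c(msg, "condition must be 'tumor', 'normal' or NA")
    }
    if (is.null(msg)) TRUE else msg
})

#' Gene model derived from a GTF annotation
#'
#' Holds, per gene, the span and strand, and per transcript the sorted exon
#' intervals together with the annotated introns (the gaps between
#' consecutive exons). Junction-to-gene mapping and splicing event
#' classification ([mapJunctionsToGenes()], [classifyEvents()]) work against
#' this model.
#'
#' @slot genes a [GenomicRanges::GRanges] of gene spans, named by gene id,
#'   with a `gene_name` metadata column.
#' @slot exonsByTx a [GenomicRanges::GRangesList] of exons per transcript,
#'   sorted by coordinate, named by transcript id.
#' @slot intronsByTx a [GenomicRanges::GRangesList] of annotated introns per
#'   transcript (1-based inclusive intron coordinates).
#' @slot txToGene named character vector mapping transcript id to gene id.
#'
#' @seealso [readGeneModel()]
#' @exportClass GeneModel
setClass("GeneModel",
         slots = c(genes = "GRanges",
                   exonsByTx = "GRangesList",
                   intronsByTx = "GRangesList",
                   txToGene = "character"))

setValidity("GeneModel", function(object) {
    msg <- NULL
    if (is.null(names(object@genes)) && length(object@genes) > 0)
        msg <- c(msg, "genes must be named by gene id")
    if (length(object@exonsByTx) != length(object@intronsByTx))
        msg <- c(msg, "exonsByTx and intronsByTx must be parallel")
    if (!all(names(object@exonsByTx) %in% names(object@txToGene)))
        msg <- c(msg, "every transcript must map to a gene")
    if (is.null(msg)) TRUE else msg
})

#' Per-sample outlier calls for every junction
#'
#' The result of [callOutliers()]: an integer matrix with one row per
#' junction and one column per sample, coded `1` (over-expression outlier),
#' `-1` (under-expression outlier), `0` (no call) and `NA` (undefined cell:
#' zero gene expression, or a junction without enough informative normals).
#' The per-junction summary of the normal reference distribution (median and
#' robust fences) is kept alongside.
#'
#' @slot calls integer matrix, junctions x samples.
#' @slot normalSummary a [S4Vectors::DataFrame] with columns `median`,
#'   `lowerFence`, `upperFence` computed from the full normal panel.
#' @slot condition character vector, one of `"tumor"`/`"normal"` per sample.
#' @slot params the [OutlierParams] used.
#' @exportClass OutlierCalls
setClass("OutlierCalls",
         slots = c(calls = "matrix",
                   normalSummary = "DataFrame",
                   condition = "character",
                   params = "ANY"))

setValidity("OutlierCalls", function(object) {
    msg <- NULL
    if (nrow(object@calls) != nrow(object@normalSummary))
        msg <- c(msg, "calls and normalSummary must have one row per junction")
    if (ncol(object@calls) != length(object@condition))
        msg <- c(msg, "condition must have one entry per sample")
    vals <- object@calls
    if (!all(vals %in% c(-1L, 0L, 1L, NA)))
        msg <- c(msg, "calls must be coded -1, 0, 1 or NA")
    if (is.null(msg)) TRUE else msg
})

#' Parameters of the outlier test
#'
#' @slot minNormExpr absolute expression floor on the normalized junction
#'   value (default `0.00001` on the reads-per-million scale). A tumor cell
#'   can only be an over-expression outlier if its own value reaches the
#'   floor; an under-expression outlier additionally requires the normal
#'   median to reach it.
#' @slot foldChangeCutoff minimum fold change versus the normal median
#'   (default `10`; the simulation benchmark uses `2`).
#' @slot fdrThreshold Benjamini-Hochberg threshold for significance
#'   (default `0.05`).
#' @slot tailQuantile quantile defining the fences (default `0.25`: fences at
#'   the quartiles +/- `iqrMultiplier` times the IQR of the normal panel).
#' @slot iqrMultiplier fence width multiplier (default `1.5`).
#' @slot excludeSexChromosomes drop chrX/chrY junctions before testing
#'   (default `TRUE`).
#' @slot sexChromosomes chromosome names treated as sex chromosomes.
#' @slot epsilon guard for fold-change ratios against zero medians.
#' @seealso [outlierParams()]
#' @exportClass OutlierParams
setClass("OutlierParams",
         slots = c(minNormExpr = "numeric",
                   foldChangeCutoff = "numeric",
                   fdrThreshold = "numeric",
                   tailQuantile = "numeric",
                   iqrMultiplier = "numeric",
                   excludeSexChromosomes = "logical",
                   sexChromosomes = "character",
                   epsilon = "numeric"))

setValidity("OutlierParams", function(object) {
    msg <- NULL
    if (object@minNormExpr < 0) msg <- c(msg, "minNormExpr must be >= 0")
    if (object@foldChangeCutoff < 1) msg <- c(msg, "foldChangeCutoff must be >= 1")
    if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
        msg <- c(msg, "fdrThreshold must be in (0, 1)")
    if (object@tailQuantile <= 0 || object@tailQuantile >= 0.5)
        msg <- c(msg, "tailQuantile must be in (0, 0.5)")
    if (object@iqrMultiplier < 0) msg <- c(msg, "iqrMultiplier must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Parameters of junction and gene-expression normalization
#'
#' @slot uqTarget value the upper quartile of expressed genes is rescaled to
#'   in every sample (default `1000`).
#' @slot scale scale of the library-size normalization of junction counts:
#'   `"per_million"` (reads per million, the default; the `0.00001` outlier
#'   floor is stated on this scale) or `"proportion"` (plain count / total;
#'   the floor is rescaled by `1e-6` so both scales behave identically).
#' @seealso [normParams()]
#' @exportClass NormParams
setClass("NormParams",
         slots = c(uqTarget = "numeric", scale = "character"))

setValidity("NormParams", function(object) {
    msg <- NULL
    if (object@uqTarget <= 0) msg <- c(msg, "uqTarget must be > 0")
    if (!object@scale %in% c("per_million", "proportion"))
        msg <- c(msg, "scale must be 'per_million' or 'proportion'")
    if (is.null(msg)) TRUE else msg
})

#' Parameters of the synthetic cohort simulator
#'
#' Defaults reproduce the benchmark design: 1000 genes each with one
#' canonical transcript, 200 of them additionally carrying an alternative
#' transcript that skips one internal exon; 20 normal and 40 tumor samples;
#' a baseline of 600 reads per transcript; canonical transcripts expressed
#' at 1-2x baseline in every sample; the alternative transcript at 1x in
#' normals, 1-2x in half the tumors and 4-5x in the other half.
#'
#' @slot nGenes,nAltGenes,nNormals,nTumors,nTumorsHigh cohort dimensions.
#' @slot baselineReads expected reads per transcript at multiplier 1.
#' @slot canonicalMultRange,altTumorLowRange,altTumorHighRange uniform ranges
#'   the per-sample expression multipliers are drawn from.
#' @slot altNormalMult fixed multiplier of the alternative transcript in
#'   normal samples.
#' @slot exonsPerTranscriptRange exon-count range of the canonical model.
#' @slot noise count noise family: `"poisson"`, `"negative_binomial"`, or
#'   `"none"` (expected counts, rounded).
#' @slot nbDispersion dispersion of the negative binomial (variance
#'   mu + dispersion * mu^2).
#' @slot seed integer seed; all randomness flows through it.
#' @seealso [simParams()], [simulateCohort()]
#' @exportClass SimParams
setClass("SimParams",
         slots = c(nGenes = "integer", nAltGenes = "integer",
                   nNormals = "integer", nTumors = "integer",
                   nTumorsHigh = "integer", baselineReads = "numeric",
                   canonicalMultRange = "numeric", altNormalMult = "numeric",
                   altTumorLowRange = "numeric", altTumorHighRange = "numeric",
                   exonsPerTranscriptRange = "integer", noise = "character",
                   nbDispersion = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- NULL
    if (object@nAltGenes > object@nGenes)
        msg <- c(msg, "nAltGenes must be <= nGenes")
    if (object@nTumorsHigh > object@nTumors)
        msg <- c(msg, "nTumorsHigh must be <= nTumors")
    if (object@nNormals < 2) msg <- c(msg, "need at least 2 normals")
    if (!object@noise %in% c("poisson", "negative_binomial", "none"))
        msg <- c(msg, "noise must be poisson, negative_binomial or none")
    for (s in c("canonicalMultRange", "altTumorLowRange", "altTumorHighRange"))
        if (length(slot(object, s)) != 2L || diff(slot(object, s)) < 0)
            msg <- c(msg, sprintf("%s must be an increasing length-2 range", s))
    if (length(object@exonsPerTranscriptRange) != 2L ||
        object@exonsPerTranscriptRange[1] < 3L)
        msg <- c(msg, "exonsPerTranscriptRange must start at >= 3 exons")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a simulated cohort
#'
#' @slot geneIds all simulated gene ids.
#' @slot hasAlt named logical: does the gene carry a true alternative event?
#' @slot altJunctions [GenomicRanges::GRanges] of the exon-skipping
#'   junctions introduced by the alternative transcripts (metadata column
#'   `gene_id`).
#' @slot multipliers numeric matrix, transcripts x samples, of the expression
#'   multipliers actually drawn.
#' @slot txToGene named character, transcript id to gene id.
#' @slot condition named character, `"tumor"`/`"normal"` per sample.
#' @slot tumorHigh sample ids of the high-expression tumor group.
#' @exportClass SimTruth
setClass("SimTruth",
         slots = c(geneIds = "character", hasAlt = "logical",
                   altJunctions = "GRanges", multipliers = "matrix",
                   txToGene = "character", condition = "character",
                   tumorHigh = "character"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    if (!identical(names(object@hasAlt), object@geneIds))
        msg <- c(msg, "hasAlt must be named by geneIds")
    if (!all(object@tumorHigh %in% names(object@condition)))
        msg <- c(msg, "tumorHigh must be a subset of the samples")
    if (is.null(msg)) TRUE else msg
})
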