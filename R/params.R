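#' Outlier-test parameters
#'
#' Defaults match the published pipeline defaults: expression floor 0.00001
#' (reads-per-million scale), fold-change cutoff 10, FDR threshold 0.05,
#' quartile fences with a 1.5 x IQR width, sex-chromosome filter on. The
#' simulation benchmark lowers the fold-change cutoff to 2.
#'
#' @param minNormExpr,foldChangeCutoff,fdrThreshold,tailQuantile,iqrMultiplier
#'   see [OutlierParams-class].
#' @param excludeSexChromosomes,sexChromosomes,epsilon see
#'   [OutlierParams-class].
#' @return an [OutlierParams-class] object.
#' @examples
#' outlierParams(foldChangeCutoff = 2)
#' @export
outlierParams <- function(minNormExpr = 0.00001,
                          foldChangeCutoff = 10,
                          fdrThreshold = 0.05,
                          tailQuantile = 0.25,
                          iqrMultiplier = 1.5,
                          excludeSexChromosomes = TRUE,
                          sexChromosomes = c("chrX", "chrY", "X", "Y"),
                          epsilon = 1e-12) {
    methods::new("OutlierParams",
                 minNormExpr = minNormExpr,
                 foldChangeCutoff = foldChangeCutoff,
                 fdrThreshold = fdrThreshold,
                 tailQuantile = tailQuantile,
                 iqrMultiplier = iqrMultiplier,
                 excludeSexChromosomes = excludeSexChromosomes,
                 sexChromosomes = sexChromosomes,
                 epsilon = epsilon)
}

#' Normalization parameters
#'
#' @param uqTarget,scale see [NormParams-class].
#' @return a [NormParams-class] object.
#' @export
normParams <- function(uqTarget = 1000, scale = c("per_million", "proportion")) {
    methods::new("NormParams", uqTarget = uqTarget, scale = match.arg(scale))
}

#' The expression floor on the scale of the normalized values
#'
#' The published floor (0.00001) is stated on the reads-per-million scale;
#' on the proportion scale the same cut is 1e-6 smaller, so the two scales
#' call identical outliers.
#'
#' @param params an [OutlierParams-class] object.
#' @param norm a [NormParams-class] object.
#' @return numeric floor to compare normalized values against.
#' @keywords internal
effectiveFloor <- function(params, norm) {
    if (norm@scale == "per_million") params@minNormExpr
    else params@minNormExpr * 1e-6
}

setMethod("show", "OutlierParams", function(object) {
    cat("OutlierParams:\n")
    cat(sprintf("  minNormExpr=%g foldChangeCutoff=%g fdrThreshold=%g\n",
                object@minNormExpr, object@foldChangeCutoff,
                object@fdrThreshold))
    cat(sprintf("  fences: Q(%g/%g) +/- %g x IQR; sex-chrom filter %s\n",
                object@tailQuantile, 1 - object@tailQuantile,
                object@iqrMultiplier,
                if (object@excludeSexChromosomes) "on" else "off"))
})

setMethod("show", "NormParams", function(object) {
    cat(sprintf("NormParams: uqTarget=%g scale=%s\n",
                object@uqTarget, object@scale))
})

#' Simulation parameters
#'
#' @param nGenes,nAltGenes,nNormals,nTumors,nTumorsHigh cohort design
#'   (defaults 1000 genes, 200 with a true alternative transcript, 20
#'   normals, 40 tumors of which 20 express the alternative transcript at
#'   4-5x).
#' @param baselineReads expected reads per transcript at multiplier 1
#'   (default 600).
#' @param canonicalMultRange,altNormalMult,altTumorLowRange,altTumorHighRange
#'   expression-multiplier design, see [SimParams-class].
#' @param exonsPerTranscriptRange range of exon counts (default 3 to 8).
#' @param noise `"poisson"` (default), `"negative_binomial"` or `"none"`.
#' @param nbDispersion negative-binomial dispersion (default 0.05).
#' @param seed integer seed.
#' @return a [SimParams-class] object.
#' @examples
#' simParams(nGenes = 20, nAltGenes = 5, seed = 1)
#' @export
simParams <- function(nGenes = 1000, nAltGenes = 200,
                      nNormals = 20, nTumors = 40, nTumorsHigh = 20,
                      baselineReads = 600,
                      canonicalMultRange = c(1, 2),
                      altNormalMult = 1,
                      altTumorLowRange = c(1, 2),
                      altTumorHighRange = c(4, 5),
                      exonsPerTranscriptRange = c(3, 8),
                      noise = c("poisson", "negative_binomial", "none"),
                      nbDispersion = 0.05,
                      seed = 1L) {
    methods::new("SimParams",
                 nGenes = as.integer(nGenes), nAltGenes = as.integer(nAltGenes),
                 nNormals = as.integer(nNormals), nTumors = as.integer(nTumors),
                 nTumorsHigh = as.integer(nTumorsHigh),
                 baselineReads = baselineReads,
                 canonicalMultRange = as.numeric(canonicalMultRange),
                 altNormalMult = altNormalMult,
                 altTumorLowRange = as.numeric(altTumorLowRange),
                 altTumorHighRange = as.numeric(altTumorHighRange),
                 exonsPerTranscriptRange = as.integer(exonsPerTranscriptRange),
                 noise = match.arg(noise),
                 nbDispersion = nbDispersion,
                 seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat(sprintf("SimParams: %d genes (%d alt), %d normals, %d tumors (%d high)\n",
                object@nGenes, object@nAltGenes, object@nNormals,
                object@nTumors, object@nTumorsHigh))
    cat(sprintf("  baseline %g reads/transcript, noise=%s, seed=%d\n",
                object@baselineReads, object@noise, object@seed))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d genes, %d with a true alternative event; %d samples\n",
                length(object@geneIds), sum(object@hasAlt),
                length(object@condition)))
})

#' @describeIn SimTruth-class gene ids carrying a true alternative event.
#' @param x a `SimTruth` object.
#' @export
truePositiveGenes <- function(x) {
    stopifnot(methods::is(x, "SimTruth"))
    x@geneIds[x@hasAlt]
}

#' @describeIn SimTruth-class all simulated gene ids.
#' @export
simulatedGenes <- function(x) {
    stopifnot(methods::is(x, "SimTruth"))
    x@geneIds
}
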