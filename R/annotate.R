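#' Map junctions to host genes
#'
#' A junction is assigned to the gene whose span (minimum exon start to
#' maximum exon end on the same chromosome) contains its whole intron
#' interval; the gene strand must match when the junction strand is
#' determined (`*` junctions may match either strand). When several genes
#' contain the junction, genes sharing at least one annotated splice site
#' with it are preferred, then the gene with the smaller span, then the
#' lexicographically first id (deterministic).
#'
#' @param junctions a `GRanges` of junctions.
#' @param model a [GeneModel-class].
#' @param tieBreak apply the tie-break rules (default `TRUE`); when `FALSE`,
#'   ambiguous junctions are left unassigned (`NA`).
#' @return character vector of gene ids (`NA` for unmapped junctions).
#' @export
mapJunctionsToGenes <- function(junctions, model, tieBreak = TRUE) {
    genes <- model@genes
    hits <- GenomicRanges::findOverlaps(junctions, genes, type = "within",
                                        ignore.strand = TRUE)
    jStrand <- as.character(GenomicRanges::strand(junctions))
    gStrand <- as.character(GenomicRanges::strand(genes))
    ok <- jStrand[S4Vectors::queryHits(hits)] == "*" |
        gStrand[S4Vectors::subjectHits(hits)] == "*" |
        jStrand[S4Vectors::queryHits(hits)] ==
            gStrand[S4Vectors::subjectHits(hits)]
    hits <- hits[ok]
    sites <- spliceSitesByGene(model)
    out <- rep(NA_character_, length(junctions))
    byJ <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (jChr in names(byJ)) {
        j <- as.integer(jChr)
        cand <- byJ[[jChr]]
        if (length(cand) > 1L) {
            if (!tieBreak) next
            ids <- names(genes)[cand]
            shared <- vapply(ids, function(g) {
                ss <- sites[[g]]
                !is.null(ss) && (GenomicRanges::start(junctions)[j] %in% ss ||
                                 GenomicRanges::end(junctions)[j] %in% ss)
            }, logical(1))
            if (any(shared)) cand <- cand[shared]
            if (length(cand) > 1L) {
                w <- GenomicRanges::width(genes)[cand]
                cand <- cand[w == min(w)]
            }
            if (length(cand) > 1L)
                cand <- cand[order(names(genes)[cand])[1]]
        }
        out[j] <- names(genes)[cand[1]]
    }
    out
}

# annotated donor/acceptor positions per gene (intron starts and ends of
# every transcript of the gene)
spliceSitesByGene <- function(model) {
    tx <- names(model@intronsByTx)
    gene <- unname(model@txToGene[tx])
    starts <- GenomicRanges::start(model@intronsByTx)
    ends <- GenomicRanges::end(model@intronsByTx)
    pos <- mapply(function(s, e) c(s, e), as.list(starts), as.list(ends),
                  SIMPLIFY = FALSE)
    lapply(split(pos, gene), function(l) unique(unlist(l)))
}

#' Classify the splicing event type of each junction
#'
#' Against the exon model of its host gene a junction is labelled, in this
#' priority order:
#' * `annotated` - it equals an annotated intron of some transcript;
#' * `skipping` - both boundaries coincide with annotated splice sites of
#'   one transcript and the intron fully contains at least one exon of that
#'   transcript (whole-exon skipping);
#' * `deletion` - at least one boundary falls strictly inside an annotated
#'   exon (part of the exon is spliced out);
#' * `insertion` - boundaries lie in annotated intronic sequence without
#'   matching annotated splice sites (novel exonic sequence implied);
#' * `unmapped` - no host gene.
#'
#' @param junctions a `GRanges` of junctions.
#' @param junctionGene gene assignment from [mapJunctionsToGenes()].
#' @param model a [GeneModel-class].
#' @return character vector of labels.
#' @export
classifyEvents <- function(junctions, junctionGene, model) {
    txOfGene <- split(names(model@txToGene), unname(model@txToGene))
    # plain integer views of the model, far cheaper than repeated GRanges ops
    exS <- as.list(GenomicRanges::start(model@exonsByTx))
    exE <- as.list(GenomicRanges::end(model@exonsByTx))
    inS <- as.list(GenomicRanges::start(model@intronsByTx))
    inE <- as.list(GenomicRanges::end(model@intronsByTx))
    out <- rep("unmapped", length(junctions))
    js <- GenomicRanges::start(junctions)
    je <- GenomicRanges::end(junctions)
    for (i in seq_along(junctions)) {
        g <- junctionGene[i]
        if (is.na(g) || is.null(txOfGene[[g]])) next
        out[i] <- classifyOne(js[i], je[i], txOfGene[[g]], exS, exE, inS, inE)
    }
    out
}

classifyOne <- function(jStart, jEnd, txIds, exS, exE, inS, inE) {
    for (t in txIds) {
        if (any(inS[[t]] == jStart & inE[[t]] == jEnd))
            return("annotated")
    }
    for (t in txIds) {
        if (!(jStart %in% inS[[t]]) || !(jEnd %in% inE[[t]])) next
        if (any(exS[[t]] >= jStart & exE[[t]] <= jEnd))
            return("skipping")
    }
    for (t in txIds) {
        if (any(exS[[t]] < jStart & jStart < exE[[t]]) ||
            any(exS[[t]] < jEnd & jEnd < exE[[t]]))
            return("deletion")
    }
    "insertion"
}

#' Annotate a junction cohort against a gene model
#'
#' Fills `rowData` columns `gene_id` and `event_type`.
#'
#' @param je a [JunctionExperiment-class].
#' @param model a [GeneModel-class].
#' @return the annotated experiment.
#' @export
annotateJunctions <- function(je, model) {
    gr <- SummarizedExperiment::rowRanges(je)
    gid <- mapJunctionsToGenes(gr, model)
    SummarizedExperiment::rowData(je)$gene_id <- gid
    SummarizedExperiment::rowData(je)$event_type <- classifyEvents(gr, gid, model)
    je
}
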