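# run expr with a local, fully restored RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# lay out nGenes non-overlapping multi-exon genes on chr1 and pick the
# alternative (one-exon-skipping) transcripts
.simGeneLayout <- function(params) {
    nG <- params@nGenes
    ids <- sprintf("SIMG%04d", seq_len(nG))
    altGenes <- sort(sample.int(nG, params@nAltGenes))
    hasAlt <- seq_len(nG) %in% altGenes
    kRange <- params@exonsPerTranscriptRange
    k <- sample(seq(kRange[1], kRange[2]), nG, replace = TRUE)
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    cursor <- 10000L
    genes <- vector("list", nG)
    for (g in seq_len(nG)) {
        exLen <- sample(100:300, k[g], replace = TRUE)
        inLen <- sample(500:2000, k[g] - 1L, replace = TRUE)
        starts <- integer(k[g]); ends <- integer(k[g])
        pos <- cursor
        for (i in seq_len(k[g])) {
            starts[i] <- pos
            ends[i] <- pos + exLen[i] - 1L
            pos <- ends[i] + if (i < k[g]) inLen[i] + 1L else 0L
        }
        skip <- if (hasAlt[g]) {
            internal <- seq(2L, k[g] - 1L)
            internal[sample.int(length(internal), 1L)]
        } else NA_integer_
        genes[[g]] <- list(starts = starts, ends = ends, skip = skip)
        cursor <- ends[k[g]] + 10000L
    }
    list(ids = ids, hasAlt = hasAlt, k = k, strand = strand, genes = genes)
}

#' Simulate a tumor/normal cohort at the junction-count level
#'
#' Generates a synthetic annotation (non-overlapping multi-exon genes on an
#' autosome, one canonical transcript each; a chosen subset additionally
#' carries an alternative transcript that skips one internal exon), draws
#' per-sample expression multipliers (canonical uniform 1-2x of the baseline
#' in every sample; alternative 1x in normals, 1-2x in the low tumor group,
#' 4-5x in the high group), and emits junction read counts, gene expected
#' counts and library sizes with the chosen count noise. Each junction's
#' expected count is the summed expected reads of the transcripts containing
#' it; gene expression is the summed expected reads of the gene's
#' transcripts; the library size is the total simulated reads of the sample.
#'
#' All randomness flows through `params@seed`; equal parameters give
#' identical cohorts. The caller's RNG state is untouched.
#'
#' @param params a [SimParams-class].
#' @return a list with elements `je` (a condition-labelled
#'   [JunctionExperiment-class]), `geneExpr` (genes x samples expected-count
#'   matrix), `model` (the [GeneModel-class]) and `truth`
#'   (a [SimTruth-class]).
#' @examples
#' sim <- simulateCohort(simParams(nGenes = 10, nAltGenes = 3,
#'                                 nNormals = 4, nTumors = 6,
#'                                 nTumorsHigh = 3, seed = 7))
#' sim$je
#' @export
simulateCohort <- function(params = simParams()) {
    .withSeed(params@seed, .simulateCohortImpl(params))
}

.simulateCohortImpl <- function(params) {
    lay <- .simGeneLayout(params)
    nG <- params@nGenes
    samples <- c(sprintf("N%02d", seq_len(params@nNormals)),
                 sprintf("T%02d", seq_len(params@nTumors)))
    condition <- c(rep("normal", params@nNormals),
                   rep("tumor", params@nTumors))
    nS <- length(samples)
    nLow <- params@nTumors - params@nTumorsHigh
    lowIdx <- params@nNormals + seq_len(nLow)
    highIdx <- params@nNormals + nLow + seq_len(params@nTumorsHigh)

    # expression multipliers, one draw per transcript and sample
    cmr <- params@canonicalMultRange
    cMult <- matrix(stats::runif(nG * nS, cmr[1], cmr[2]), nG, nS,
                    dimnames = list(paste0(lay$ids, ".c"), samples))
    altIds <- lay$ids[lay$hasAlt]
    aMult <- matrix(params@altNormalMult, length(altIds), nS,
                    dimnames = list(sprintf("%s.a", altIds), samples))
    lr <- params@altTumorLowRange; hr <- params@altTumorHighRange
    aMult[, lowIdx] <- stats::runif(length(altIds) * nLow, lr[1], lr[2])
    aMult[, highIdx] <- stats::runif(length(altIds) * params@nTumorsHigh,
                                     hr[1], hr[2])

    # junction table: coordinates plus which transcripts carry each junction
    jChrom <- "chr1"
    rows <- vector("list", nG)
    altRank <- cumsum(lay$hasAlt)
    for (g in seq_len(nG)) {
        gi <- lay$genes[[g]]
        k <- length(gi$starts)
        js <- gi$ends[-k] + 1L
        jeod <- gi$starts[-1] - 1L
        wCan <- rep(1L, k - 1L)
        wAlt <- if (lay$hasAlt[g])
            as.integer(!(seq_len(k - 1L) %in% (gi$skip + c(-1L, 0L))))
        else rep(0L, k - 1L)
        df <- data.frame(start = js, end = jeod, gene = g,
                         wCan = wCan, wAlt = wAlt)
        if (lay$hasAlt[g])
            df <- rbind(df, data.frame(start = gi$ends[gi$skip - 1L] + 1L,
                                       end = gi$starts[gi$skip + 1L] - 1L,
                                       gene = g, wCan = 0L, wAlt = 1L))
        rows[[g]] <- df
    }
    jtab <- do.call(rbind, rows)

    b <- params@baselineReads
    eCan <- b * cMult
    eAlt <- b * aMult
    eJunc <- jtab$wCan * eCan[jtab$gene, , drop = FALSE]
    isAltRow <- jtab$wAlt == 1L
    eJunc[isAltRow, ] <- eJunc[isAltRow, , drop = FALSE] +
        eAlt[altRank[jtab$gene[isAltRow]], , drop = FALSE]
    eGene <- eCan
    rownames(eGene) <- lay$ids
    eGene[lay$hasAlt, ] <- eGene[lay$hasAlt, , drop = FALSE] + eAlt

    draw <- function(mu) {
        m <- switch(params@noise,
                    poisson = stats::rpois(length(mu), mu),
                    negative_binomial = stats::rnbinom(
                        length(mu), mu = mu, size = 1 / params@nbDispersion),
                    none = round(mu))
        matrix(as.numeric(m), nrow(mu), ncol(mu), dimnames = dimnames(mu))
    }
    juncCounts <- draw(eJunc)
    geneExpr <- draw(eGene)
    libSizes <- colSums(geneExpr)

    gr <- GenomicRanges::GRanges(jChrom,
                                 IRanges::IRanges(jtab$start, jtab$end),
                                 strand = lay$strand[jtab$gene])
    je <- JunctionExperiment(juncCounts, gr, libSizes, condition)

    ex <- .layoutExons(lay)
    model <- geneModelFromExons(ex)
    altSel <- jtab$wCan == 0L
    altJ <- GenomicRanges::GRanges(
        rep(jChrom, sum(altSel)),
        IRanges::IRanges(jtab$start[altSel], jtab$end[altSel]),
        strand = lay$strand[jtab$gene[altSel]])
    altJ$gene_id <- lay$ids[jtab$gene[altSel]]
    truth <- methods::new("SimTruth",
                          geneIds = lay$ids,
                          hasAlt = stats::setNames(lay$hasAlt, lay$ids),
                          altJunctions = altJ,
                          multipliers = rbind(cMult, aMult),
                          txToGene = stats::setNames(
                              c(lay$ids, altIds),
                              c(rownames(cMult), rownames(aMult))),
                          condition = stats::setNames(condition, samples),
                          tumorHigh = samples[highIdx])
    list(je = je, geneExpr = geneExpr, model = model, truth = truth)
}

# exon GRanges (canonical + alternative transcripts) for the simulated layout
.layoutExons <- function(lay) {
    chrom <- "chr1"
    recs <- vector("list", length(lay$ids))
    for (g in seq_along(lay$ids)) {
        gi <- lay$genes[[g]]
        k <- length(gi$starts)
        gid <- lay$ids[g]
        start <- gi$starts
        end <- gi$ends
        tx <- rep(paste0(gid, ".c"), k)
        if (lay$hasAlt[g]) {
            keep <- setdiff(seq_len(k), gi$skip)
            start <- c(start, gi$starts[keep])
            end <- c(end, gi$ends[keep])
            tx <- c(tx, rep(paste0(gid, ".a"), length(keep)))
        }
        recs[[g]] <- data.frame(start = start, end = end, tx = tx,
                                gene = gid, strand = lay$strand[g])
    }
    df <- do.call(rbind, recs)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gr$gene_id <- df$gene
    gr$transcript_id <- df$tx
    gr$gene_name <- df$gene
    gr
}

#' Export a simulated cohort as an on-disk fixture
#'
#' Writes the external file formats the readers consume: a GTF of the
#' synthetic annotation, one STAR-style `SJ.out.tab` per sample (zero-count
#' junctions omitted, as STAR does), one `Log.final.out` per sample with the
#' library size, a gene expression TSV, a phenotype TSV and a ground-truth
#' TSV. Reading the fixture back reproduces the in-memory cohort.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportCohortFixture <- function(sim, dir) {
    dir.create(file.path(dir, "sj"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "logs"), showWarnings = FALSE)
    ex <- .modelExons(sim$model)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     ex$gene_id, ex$transcript_id, ex$gene_name)
    gtf <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(ex)),
                   GenomicRanges::start(ex), GenomicRanges::end(ex),
                   as.character(GenomicRanges::strand(ex)), attrs)
    writeLines(gtf, file.path(dir, "model.gtf"))

    cts <- SummarizedExperiment::assay(sim$je, "counts")
    gr <- SummarizedExperiment::rowRanges(sim$je)
    code <- c("*" = 0L, "+" = 1L, "-" = 2L)[
        as.character(GenomicRanges::strand(gr))]
    ls <- libSizes(sim$je)
    for (s in colnames(cts)) {
        keep <- cts[, s] > 0
        lines <- sprintf("%s\t%d\t%d\t%d\t0\t1\t%d\t0\t50",
                         as.character(GenomicRanges::seqnames(gr))[keep],
                         GenomicRanges::start(gr)[keep],
                         GenomicRanges::end(gr)[keep],
                         code[keep], as.integer(cts[keep, s]))
        writeLines(lines, file.path(dir, "sj", paste0(s, ".SJ.out.tab")))
        writeLines(sprintf("Uniquely mapped reads number |\t%d",
                           as.integer(ls[s])),
                   file.path(dir, "logs", paste0(s, ".Log.final.out")))
    }
    ge <- data.frame(gene_id = rownames(sim$geneExpr), sim$geneExpr,
                     check.names = FALSE)
    utils::write.table(ge, file.path(dir, "gene_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cond <- sampleCondition(sim$je)
    utils::write.table(data.frame(sample = names(cond), condition = cond),
                       file.path(dir, "phenotype.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    truth <- data.frame(gene_id = simulatedGenes(sim$truth),
                        has_alt = unname(sim$truth@hasAlt))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

# flat exon GRanges of a GeneModel, with gene/transcript metadata
.modelExons <- function(model) {
    tx <- names(model@exonsByTx)
    ex <- unlist(model@exonsByTx, use.names = FALSE)
    n <- lengths(model@exonsByTx)
    ex$transcript_id <- rep(tx, n)
    ex$gene_id <- rep(unname(model@txToGene[tx]), n)
    gn <- stats::setNames(model@genes$gene_name, names(model@genes))
    ex$gene_name <- unname(gn[ex$gene_id])
    ex
}

#' Load a cohort fixture written by [exportCohortFixture()]
#'
#' @param dir fixture directory.
#' @return list with `je` (condition-labelled [JunctionExperiment-class]),
#'   `geneExpr` and `model`.
#' @export
loadCohortFixture <- function(dir) {
    sjFiles <- list.files(file.path(dir, "sj"), full.names = TRUE)
    names(sjFiles) <- sub("\\.SJ\\.out\\.tab$", "", basename(sjFiles))
    sjList <- lapply(sjFiles, readStarJunctions)
    logFiles <- list.files(file.path(dir, "logs"), full.names = TRUE)
    names(logFiles) <- sub("\\.Log\\.final\\.out$", "", basename(logFiles))
    ls <- readLibrarySizes(logFiles)
    cond <- readPhenotype(file.path(dir, "phenotype.tsv"))
    je <- assembleJunctionExperiment(sjList, ls, cond)
    ge <- utils::read.table(file.path(dir, "gene_expression.tsv"),
                            header = TRUE, sep = "\t", check.names = FALSE)
    geneExpr <- as.matrix(ge[, -1, drop = FALSE])
    rownames(geneExpr) <- ge$gene_id
    model <- readGeneModel(file.path(dir, "model.gtf"))
    list(je = je, geneExpr = geneExpr, model = model)
}
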