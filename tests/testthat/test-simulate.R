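test_that("the simulated annotation matches the requested design", {
    sim <- simulateCohort(simParams(nGenes = 3, nAltGenes = 1, nNormals = 3,
                                    nTumors = 4, nTumorsHigh = 2, seed = 2))
    expect_length(sim$model@genes, 3L)
    expect_length(sim$model@exonsByTx, 4L)  # 3 canonical + 1 alternative
    expect_equal(sum(sim$truth@hasAlt), 1L)
    altGene <- truePositiveGenes(sim$truth)
    canIntr <- sim$model@intronsByTx[[paste0(altGene, ".c")]]
    altIntr <- sim$model@intronsByTx[[paste0(altGene, ".a")]]
    # the alternative transcript's junction set differs from the canonical
    expect_gt(length(setdiff(junctionIds(altIntr), junctionIds(canIntr))), 0L)
    # and shares its gene's chromosome and strand
    gene <- sim$model@genes[altGene]
    expect_true(all(as.character(GenomicRanges::seqnames(altIntr)) ==
                    as.character(GenomicRanges::seqnames(gene))))
    expect_true(all(as.character(GenomicRanges::strand(altIntr)) ==
                    as.character(GenomicRanges::strand(gene))))
    # the skip junction spans exactly one skipped canonical exon
    skip <- sim$truth@altJunctions
    ex <- sim$model@exonsByTx[[paste0(altGene, ".c")]]
    contained <- GenomicRanges::start(ex) >= GenomicRanges::start(skip) &
        GenomicRanges::end(ex) <= GenomicRanges::end(skip)
    expect_equal(sum(contained), 1L)
})

test_that("equal seeds give identical cohorts, different seeds differ", {
    a <- simulateCohort(smallSimParams(seed = 99))
    b <- simulateCohort(smallSimParams(seed = 99))
    expect_identical(SummarizedExperiment::assay(a$je, "counts"),
                     SummarizedExperiment::assay(b$je, "counts"))
    expect_identical(a$geneExpr, b$geneExpr)
    expect_identical(junctionIds(a$je), junctionIds(b$je))
    c <- simulateCohort(smallSimParams(seed = 100))
    expect_false(identical(SummarizedExperiment::assay(a$je, "counts"),
                           SummarizedExperiment::assay(c$je, "counts")))
    # the caller's RNG state is untouched
    set.seed(1); before <- .Random.seed
    simulateCohort(smallSimParams(seed = 5))
    expect_identical(.Random.seed, before)
})

test_that("multipliers respect the group design", {
    sim <- simulateCohort(smallSimParams(seed = 12))
    mult <- sim$truth@multipliers
    cond <- sim$truth@condition
    canRows <- grepl("\\.c$", rownames(mult))
    expect_true(all(mult[canRows, ] >= 1 & mult[canRows, ] <= 2))
    altRows <- grepl("\\.a$", rownames(mult))
    normals <- names(cond)[cond == "normal"]
    expect_true(all(mult[altRows, normals] == 1))
    high <- sim$truth@tumorHigh
    low <- setdiff(names(cond)[cond == "tumor"], high)
    expect_true(all(mult[altRows, high] >= 4 & mult[altRows, high] <= 5))
    expect_true(all(mult[altRows, low] >= 1 & mult[altRows, low] <= 2))
})

test_that("junction counts follow the expected-reads contract", {
    # noiseless: counts equal rounded expected reads of covering transcripts
    p <- smallSimParams(seed = 8, noise = "none")
    sim <- simulateCohort(p)
    cts <- SummarizedExperiment::assay(sim$je, "counts")
    mult <- sim$truth@multipliers
    truth <- sim$truth
    # an alternative junction in a normal sample has expected count
    # baseline x 1
    aj <- junctionIds(truth@altJunctions)
    normals <- names(truth@condition)[truth@condition == "normal"]
    expect_true(all(cts[aj, normals] == p@baselineReads))
    # a canonical-only junction carries the canonical multiplier alone;
    # the flanking junctions are the canonical introns absent from the
    # alternative transcript
    gid <- truth@altJunctions$gene_id[1]
    can <- junctionIds(sim$model@intronsByTx[[paste0(gid, ".c")]])
    alt <- junctionIds(sim$model@intronsByTx[[paste0(gid, ".a")]])
    flank <- setdiff(can, alt)
    expect_length(flank, 2L)
    s <- normals[1]
    expected <- round(p@baselineReads * mult[paste0(gid, ".c"), s])
    expect_true(all(cts[flank, s] == expected))
    # shared junctions carry canonical + alternative expression
    shared <- intersect(can, alt)
    if (length(shared))
        expect_true(all(cts[shared, s] ==
                        round(p@baselineReads *
                              (mult[paste0(gid, ".c"), s] + 1))))
})

test_that("Poisson noise is centered on the expected counts", {
    # Monte-Carlo: across replicate seeds the mean count of a fixed
    # junction stays within 3 standard errors of its expected value
    z <- vapply(1:60, function(s) {
        p <- simParams(nGenes = 2, nAltGenes = 0, nNormals = 2, nTumors = 1,
                       nTumorsHigh = 1, seed = 1000 + s)
        sim <- simulateCohort(p)
        mu <- 600 * sim$truth@multipliers[1, "N01"]
        cts <- SummarizedExperiment::assay(sim$je, "counts")
        (cts[1, "N01"] - mu) / sqrt(mu)  # ~N(0,1) if counts are Poisson(mu)
    }, numeric(1))
    expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
})

test_that("fixtures round-trip through the readers", {
    sim <- simulateCohort(smallSimParams(seed = 77))
    dir <- withr::local_tempdir()
    exportCohortFixture(sim, dir)
    back <- loadCohortFixture(dir)
    orig <- SummarizedExperiment::assay(sim$je, "counts")
    got <- SummarizedExperiment::assay(back$je, "counts")
    expect_setequal(rownames(got), rownames(orig))
    expect_equal(got[rownames(orig), colnames(orig)], orig)
    expect_equal(unname(libSizes(back$je)[colnames(orig)]),
                 unname(libSizes(sim$je)))
    expect_equal(sampleCondition(back$je)[colnames(orig)],
                 sampleCondition(sim$je))
    # the GTF reproduces the intron structure
    expect_setequal(names(back$model@intronsByTx), names(sim$model@intronsByTx))
    for (tx in names(sim$model@intronsByTx))
        expect_equal(junctionIds(back$model@intronsByTx[[tx]]),
                     junctionIds(sim$model@intronsByTx[[tx]]))
    expect_equal(back$geneExpr[rownames(sim$geneExpr), colnames(sim$geneExpr)],
                 sim$geneExpr)
})

test_that("a 5-gene fixture stays small on disk", {
    sim <- simulateCohort(simParams(nGenes = 5, nAltGenes = 2, nNormals = 3,
                                    nTumors = 4, nTumorsHigh = 2, seed = 4))
    dir <- withr::local_tempdir()
    exportCohortFixture(sim, dir)
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    expect_lt(sum(file.size(files)), 100 * 1024)
})
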