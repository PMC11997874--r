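test_that("junctions map to the gene whose span contains them, strand-aware", {
    model <- toyModel()
    j <- GenomicRanges::GRanges(
        c("chr1", "chr3", "chr2", "chr2"),
        IRanges::IRanges(start = c(1001, 100, 201, 201),
                         end = c(1899, 200, 599, 599)),
        strand = c("+", "+", "-", "+"))
    got <- mapJunctionsToGenes(j, model)
    expect_equal(got[1], "A")        # only gene A contains 1001-1899
    expect_true(is.na(got[2]))       # nothing on chr3
    expect_equal(got[3], "C")        # strand matches
    expect_true(is.na(got[4]))       # wrong strand
    # undetermined strand may match either strand
    jstar <- GenomicRanges::GRanges("chr2", IRanges::IRanges(201, 599), "*")
    expect_equal(mapJunctionsToGenes(jstar, model), "C")
})

test_that("overlap ties prefer shared splice sites, then the smaller span", {
    model <- toyModel()
    # 201-899 sits inside both A (100-2000) and B (150-5000); its donor 201
    # is an annotated splice site of A only
    jA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 899), "+")
    expect_equal(mapJunctionsToGenes(jA, model), "A")
    # 300-800 shares no splice site with either gene; A has the smaller span
    jSpan <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 800), "+")
    expect_equal(mapJunctionsToGenes(jSpan, model), "A")
    # with tie-breaking off, ambiguous junctions stay unassigned
    expect_true(is.na(mapJunctionsToGenes(jSpan, model, tieBreak = FALSE)))
})

test_that("event classification follows annotated > skipping > deletion > insertion", {
    ex <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(100, 300, 500),
                                                  c(200, 400, 600)), "+")
    ex$gene_id <- "G"; ex$transcript_id <- "G.t"; ex$gene_name <- "G"
    model <- geneModelFromExons(ex)
    j <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(201, 201, 201, 220),
                                                 c(499, 299, 550, 280)), "+")
    gene <- rep("G", 4)
    expect_equal(classifyEvents(j, gene, model),
                 c("skipping",    # contains exon 300-400, sites annotated
                   "annotated",   # equals intron 201-299
                   "deletion",    # acceptor 550 inside exon 500-600
                   "insertion"))  # both ends inside intron 201-299
    expect_equal(classifyEvents(j[1], NA_character_, model), "unmapped")
})

test_that("classification is invariant to transcript order in the model", {
    mk <- function(rev) {
        ex1 <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(c(100, 300, 500),
                                                       c(200, 400, 600)), "+")
        ex2 <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(c(100, 500),
                                                       c(200, 600)), "+")
        ex <- c(ex1, ex2)
        ex$gene_id <- "G"
        ex$transcript_id <- rep(c("G.a", "G.b"), c(3, 2))
        ex$gene_name <- "G"
        if (rev) ex <- rev(ex)
        geneModelFromExons(ex)
    }
    j <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(201, 201), c(499, 299)),
                                "+")
    g <- c("G", "G")
    expect_equal(classifyEvents(j, g, mk(FALSE)),
                 classifyEvents(j, g, mk(TRUE)))
    # the skip junction of G.b is annotated there, so never "skipping"
    expect_equal(classifyEvents(j, g, mk(FALSE))[1], "annotated")
})

test_that("a 2-exon transcript can only yield annotated, deletion or insertion", {
    ex <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(10, 30), c(19, 39)), "+")
    ex$gene_id <- "G"; ex$transcript_id <- "G.t"; ex$gene_name <- "G"
    model <- geneModelFromExons(ex)
    # exhaustive placements of (start, end) within the gene span
    combos <- expand.grid(start = 11:38, end = 11:38)
    combos <- combos[combos$start <= combos$end, ]
    j <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(combos$start, combos$end),
                                "+")
    labels <- classifyEvents(j, rep("G", length(j)), model)
    expect_true(all(labels %in% c("annotated", "deletion", "insertion")))
    expect_true("deletion" %in% labels && "insertion" %in% labels)
    expect_equal(sum(labels == "annotated"), 1L)  # only the real intron 20-29
})

test_that("annotateJunctions fills rowData for a simulated cohort", {
    sim <- simulateCohort(smallSimParams(seed = 3))
    je <- annotateJunctions(sim$je, sim$model)
    rd <- SummarizedExperiment::rowData(je)
    expect_true(all(!is.na(rd$gene_id)))
    # every junction of the simulated annotation is an annotated intron
    expect_true(all(rd$event_type == "annotated"))
    # the true skip junctions belong to their generating genes
    truth <- sim$truth
    ids <- junctionIds(truth@altJunctions)
    expect_equal(unname(rd[ids, "gene_id"]), truth@altJunctions$gene_id)
})
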