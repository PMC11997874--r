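Package: spliceOutliers
Title: Tumor-Specific Splice-Junction Outlier Detection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects tumor-specific aberrant splicing as outlier expression
    of individual splice junctions relative to a panel of normal samples.
    Junction read counts (STAR SJ.out.tab, or TCGA/Firebrowse junction
    matrices) are converted to reads per million, normalized by
    upper-quartile-normalized gene expression, and screened per tumor sample
    against robust fences of the normal distribution with an absolute
    expression floor and a fold-change requirement; a one-sided Fisher's
    exact test with Benjamini-Hochberg correction identifies junctions with
    a significant excess of tumor outliers. Junctions are mapped to genes
    and classified as annotated, exon-skipping, insertion, or deletion
    events against a GTF exon model, and per-sample splice burden and
    waterfall-plot data are reported. A seeded count-level cohort simulator
    with ground truth and a sensitivity/specificity/FDR evaluator support
    benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, Software, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
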