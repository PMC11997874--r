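#' Read one STAR SJ.out.tab file
#'
#' Parses STAR's per-sample splice-junction table (9 tab-separated columns:
#' chromosome, intron start, intron end, strand code 0/1/2, motif, annotated
#' flag, unique reads, multi-mapping reads, max overhang). Only the
#' unique-read count (column 7) is used; multi-mapping reads are ignored.
#' Intron coordinates are 1-based and inclusive, STAR's native convention.
#'
#' @param path path to an `SJ.out.tab` file.
#' @param minUniqueReads junctions with fewer unique reads are dropped
#'   (default 1, i.e. keep every observed junction; filtering happens
#'   statistically downstream).
#' @return a [GenomicRanges::GRanges] of junctions with a `count` metadata
#'   column. An empty file yields an empty `GRanges`.
#' @export
readStarJunctions <- function(path, minUniqueReads = 1L) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(GenomicRanges::GRanges(count = integer(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L))
        stop(sprintf("malformed SJ.out.tab line %d in '%s': expected >= 9 columns, got %d",
                     which(nf < 9L)[1], path, nf[which(nf < 9L)[1]]))
    m <- do.call(rbind, lapply(fields, `[`, 1:9))
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    cnt <- suppressWarnings(as.integer(m[, 7]))
    bad <- which(is.na(start) | is.na(end) | is.na(cnt))
    if (length(bad))
        stop(sprintf("malformed SJ.out.tab line %d in '%s': non-integer field",
                     bad[1], path))
    strand <- c("0" = "*", "1" = "+", "2" = "-")[m[, 4]]
    if (anyNA(strand))
        stop(sprintf("malformed SJ.out.tab line %d in '%s': bad strand code",
                     which(is.na(strand))[1], path))
    keep <- cnt >= minUniqueReads
    gr <- GenomicRanges::GRanges(m[keep, 1],
                                 IRanges::IRanges(start[keep], end[keep]),
                                 strand = strand[keep])
    gr$count <- cnt[keep]
    gr
}

#' Read total uniquely mapped reads from STAR Log.final.out files
#'
#' @param paths character vector of `Log.final.out` paths; names (or file
#'   basenames) become sample ids.
#' @return named numeric vector of library sizes.
#' @export
readLibrarySizes <- function(paths) {
    ids <- names(paths)
    if (is.null(ids)) ids <- sub("\\.?Log\\.final\\.out$", "", basename(paths))
    out <- vapply(seq_along(paths), function(i) {
        lines <- readLines(paths[i])
        hit <- grep("Uniquely mapped reads number", lines, fixed = TRUE)
        if (length(hit) == 0L)
            stop(sprintf("'%s' has no 'Uniquely mapped reads number' line",
                         paths[i]))
        if (length(hit) > 1L)
            warning(sprintf("'%s': duplicate library-size lines, using the first",
                            paths[i]))
        val <- sub(".*\\|\\s*", "", lines[hit[1]])
        as.numeric(trimws(val))
    }, numeric(1))
    stats::setNames(out, ids)
}

#' Read RSEM genes.results files into a gene expression matrix
#'
#' Extracts the `expected_count` column per sample. Samples with
#' inconsistent gene sets are combined by outer union with zero fill (a
#' warning is raised).
#'
#' @param paths character vector of `*.genes.results` paths; names (or file
#'   basenames) become sample ids.
#' @param stripVersions drop trailing `.NN` version suffixes from gene ids
#'   (default `TRUE`).
#' @return numeric matrix of expected counts, genes x samples.
#' @export
readRsemGenes <- function(paths, stripVersions = TRUE) {
    ids <- names(paths)
    if (is.null(ids)) ids <- sub("\\.genes\\.results$", "", basename(paths))
    tabs <- lapply(seq_along(paths), function(i) {
        df <- utils::read.table(paths[i], header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, check.names = FALSE)
        if (!all(c("gene_id", "expected_count") %in% colnames(df)))
            stop(sprintf("'%s' lacks gene_id/expected_count columns", paths[i]))
        g <- df$gene_id
        if (stripVersions) g <- sub("\\.[0-9]+$", "", g)
        stats::setNames(df$expected_count, g)
    })
    genes <- unique(unlist(lapply(tabs, names)))
    if (!all(vapply(tabs, function(t) identical(names(t), genes), logical(1))))
        warning("inconsistent gene sets across samples; taking the union with 0 fill")
    mat <- vapply(tabs, function(t) {
        v <- t[genes]
        v[is.na(v)] <- 0
        unname(v)
    }, numeric(length(genes)))
    dimnames(mat) <- list(genes, ids)
    mat
}

#' Parse a Firebrowse-style donor/acceptor junction token
#'
#' Tokens look like `"chr1:12227:+,chr1:12595:+"`: the two positions are the
#' last base of the upstream exon and the first base of the downstream exon,
#' so the intron is `min(pos)+1 .. max(pos)-1` (1-based inclusive).
#'
#' @param tokens character vector of junction strings.
#' @return a [GenomicRanges::GRanges] of intron coordinates.
#' @export
parseFirebrowseJunctions <- function(tokens) {
    parts <- strsplit(tokens, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
        stop(sprintf("unparsable junction token '%s'", tokens[bad[1]]))
    one <- function(side) do.call(rbind, strsplit(side, ":", fixed = TRUE))
    a <- one(vapply(parts, `[`, character(1), 1))
    b <- one(vapply(parts, `[`, character(1), 2))
    if (ncol(a) != 3L || ncol(b) != 3L || any(a[, 1] != b[, 1]))
        stop(sprintf("unparsable junction token '%s'", tokens[1]))
    pa <- suppressWarnings(as.integer(a[, 2]))
    pb <- suppressWarnings(as.integer(b[, 2]))
    if (anyNA(pa) || anyNA(pb)) {
        i <- which(is.na(pa) | is.na(pb))[1]
        stop(sprintf("unparsable junction token '%s'", tokens[i]))
    }
    GenomicRanges::GRanges(a[, 1],
                           IRanges::IRanges(pmin(pa, pb) + 1L,
                                            pmax(pa, pb) - 1L),
                           strand = a[, 3])
}

#' Read a TCGA/Firebrowse junction quantification table
#'
#' First column: junction tokens (see [parseFirebrowseJunctions()]);
#' remaining columns: per-sample raw counts.
#'
#' @param path path to the tab-separated table.
#' @param librarySizes optional named vector of per-sample totals; when
#'   absent, per-sample column sums are used (an all-zero sample falls back
#'   to library size 1 with a warning).
#' @return a [JunctionExperiment-class].
#' @export
readFirebrowseJunctions <- function(path, librarySizes = NULL) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    gr <- parseFirebrowseJunctions(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    if (is.null(librarySizes)) {
        librarySizes <- colSums(counts)
        if (any(librarySizes == 0)) {
            warning("sample(s) with all-zero counts; library size fallback = 1")
            librarySizes[librarySizes == 0] <- 1
        }
    } else {
        librarySizes <- librarySizes[colnames(counts)]
    }
    JunctionExperiment(counts, gr, librarySizes)
}

#' Assemble per-sample junction maps into a cohort
#'
#' Junctions with identical coordinates collapse to one row; a junction
#' absent from a sample's file gets count 0 there. Row order is genomic
#' (chromosome, start, end).
#'
#' @param sjList named list of per-sample `GRanges` from
#'   [readStarJunctions()].
#' @param libSizes named numeric vector of library sizes (one per sample).
#' @param condition optional named character vector of tumor/normal labels.
#' @return a [JunctionExperiment-class].
#' @export
assembleJunctionExperiment <- function(sjList, libSizes, condition = NULL) {
    if (is.null(names(sjList)))
        stop("'sjList' must be a named list (sample ids)")
    samples <- names(sjList)
    keys <- unique(unlist(lapply(sjList, function(gr) junctionIds(gr))))
    all <- unlist(GenomicRanges::GRangesList(lapply(sjList, function(gr) {
        S4Vectors::mcols(gr) <- NULL
        gr
    })), use.names = FALSE)
    uniq <- all[match(keys, junctionIds(all))]
    ord <- order(as.character(GenomicRanges::seqnames(uniq)),
                 GenomicRanges::start(uniq), GenomicRanges::end(uniq),
                 as.character(GenomicRanges::strand(uniq)))
    uniq <- uniq[ord]
    keys <- keys[ord]
    counts <- matrix(0L, length(keys), length(samples),
                     dimnames = list(keys, samples))
    for (s in samples) {
        gr <- sjList[[s]]
        counts[match(junctionIds(gr), keys), s] <- gr$count
    }
    ls <- libSizes[samples]
    if (anyNA(ls)) stop("libSizes missing for some samples")
    cond <- if (is.null(condition)) NULL else unname(condition[samples])
    JunctionExperiment(counts, uniq, ls, cond)
}

#' Read a two-column phenotype file (sample, tumor|normal)
#'
#' @param path tab-separated file with columns `sample` and `condition`
#'   (header optional).
#' @return named character vector of conditions.
#' @export
readPhenotype <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (identical(tolower(as.character(df[1, ])), c("sample", "condition")))
        df <- df[-1, , drop = FALSE]
    cond <- tolower(df[[2]])
    if (!all(cond %in% c("tumor", "normal")))
        stop("phenotype conditions must be 'tumor' or 'normal'")
    if (anyDuplicated(df[[1]]))
        stop("duplicate sample ids in phenotype file")
    stats::setNames(cond, df[[1]])
}

#' Build a GeneModel from a GTF annotation
#'
#' Exon features are grouped by transcript; annotated introns are the gaps
#' between consecutive exons of each transcript. Exons lacking a
#' transcript_id are skipped with a warning.
#'
#' @param path path to a GTF file (GENCODE dialect).
#' @return a [GeneModel-class].
#' @export
readGeneModel <- function(path) {
    gtf <- rtracklayer::import(path, format = "gtf")
    ex <- gtf[gtf$type == "exon"]
    if (length(ex) == 0L) stop("no exon features in GTF")
    noTx <- is.na(ex$transcript_id) | ex$transcript_id == ""
    if (any(noTx)) {
        warning(sprintf("%d exon(s) without transcript_id skipped", sum(noTx)))
        ex <- ex[!noTx]
    }
    geneModelFromExons(ex)
}

#' Build a GeneModel from exon ranges
#'
#' @param ex a `GRanges` of exons with `gene_id`, `transcript_id` and
#'   optionally `gene_name` metadata columns.
#' @return a [GeneModel-class].
#' @export
geneModelFromExons <- function(ex) {
    ex <- GenomicRanges::sort(ex, ignore.strand = TRUE)
    txv <- as.character(ex$transcript_id)
    gv <- as.character(ex$gene_id)
    gnv <- if ("gene_name" %in% colnames(S4Vectors::mcols(ex)))
        as.character(ex$gene_name) else gv
    bare <- ex
    S4Vectors::mcols(bare) <- NULL
    exonsByTx <- GenomicRanges::split(bare, txv)
    first <- !duplicated(txv)
    txToGene <- stats::setNames(gv[first], txv[first])
    spans <- unlist(range(exonsByTx))
    intronsByTx <- GenomicRanges::psetdiff(spans, exonsByTx)
    geneOfTx <- unname(txToGene[names(exonsByTx)])
    geneSpans <- unlist(range(GenomicRanges::split(spans, geneOfTx)))
    firstG <- !duplicated(gv)
    gname <- stats::setNames(gnv[firstG], gv[firstG])
    geneSpans$gene_name <- unname(gname[names(geneSpans)])
    methods::new("GeneModel", genes = geneSpans, exonsByTx = exonsByTx,
                 intronsByTx = intronsByTx, txToGene = txToGene)
}

#' Write detected events to a tab-separated results file
#'
#' One row per (junction, direction) record with coordinates, gene, event
#' type, outlier counts, p-value, FDR and per-sample outlier flags; rows
#' are ordered by chromosome, intron start, intron end, direction.
#'
#' @param events the `events` data.frame from [detectEvents()].
#' @param path output path.
#' @param calls optional [OutlierCalls-class]; when given, one flag column
#'   per sample (`over`/`under`/`none`/`undefined`) is appended.
#' @return the written data.frame, invisibly.
#' @export
writeEventResults <- function(events, path, calls = NULL) {
    out <- events
    if (!is.null(calls)) {
        m <- outlierCallMatrix(calls)
        idx <- match(out$junction_id, rownames(m))
        if (anyNA(idx))
            stop("events and calls come from different runs")
        lab <- matrix(c("under", "none", "over")[m[idx, , drop = FALSE] + 2L],
                      nrow = length(idx))
        lab[is.na(lab)] <- "undefined"
        colnames(lab) <- colnames(m)
        out <- cbind(out, as.data.frame(lab, stringsAsFactors = FALSE))
    }
    ord <- order(out$chromosome, out$intron_start, out$intron_end,
                 out$direction)
    out <- out[ord, , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}

#' Read back a results file written by [writeEventResults()]
#'
#' @param path path to the results TSV.
#' @return a data.frame.
#' @export
readEventResults <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export a normalized junction matrix as TSV
#'
#' @param je a normalized [JunctionExperiment-class].
#' @param path output path. Undefined cells are written as `NA`.
#' @export
writeNormalizedMatrix <- function(je, path) {
    vals <- normalizedExpression(je)
    gr <- SummarizedExperiment::rowRanges(je)
    df <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                     intron_start = GenomicRanges::start(gr),
                     intron_end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     vals, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
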