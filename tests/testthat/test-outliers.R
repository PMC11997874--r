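test_that("sex-chromosome junctions are removed by default, kept on request", {
    vals <- matrix(1e-4, 4, 4)
    je <- toyExperiment(vals, c("normal", "normal", "tumor", "tumor"),
                        chrom = c("chr1", "chrX", "chrY", "chr2"))
    kept <- filterSexChromosomes(je, outlierParams())
    expect_equal(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(kept))), c("chr1", "chr2"))
    off <- filterSexChromosomes(je, outlierParams(excludeSexChromosomes = FALSE))
    expect_equal(nrow(off), 4L)
    expect_equal(nrow(filterSexChromosomes(je[0, ], outlierParams())), 0L)
})

test_that("outlier calls obey floor, fold change and fences", {
    cond <- c(rep("normal", 4), rep("tumor", 3))
    # constant normals at 1e-4; tumors at 20x, 5x, and below the floor
    vals <- matrix(c(rep(1e-4, 4), 2e-3, 5e-4, 5e-6), 1)
    je <- toyExperiment(vals, cond)
    m10 <- outlierCallMatrix(callOutliers(je, outlierParams()))
    # 20x the median, above the floor: over at the default cutoff
    expect_equal(unname(m10[1, 5]), 1L)
    # 5x the median: not over at cutoff 10 ...
    expect_equal(unname(m10[1, 6]), 0L)
    # below the 0.00001 floor: never an outlier regardless of fold change,
    # in either direction
    expect_equal(unname(m10[1, 7]), 0L)
    # ... but over at cutoff 2
    m2 <- outlierCallMatrix(callOutliers(je, outlierParams(foldChangeCutoff = 2)))
    expect_equal(unname(m2[1, 6]), 1L)
    expect_equal(unname(m2[1, 7]), 0L)
    # constant junctions yield no outlier among the normals (strict fences)
    expect_equal(unname(m10[1, 1:4]), rep(0L, 4))
})

test_that("undefined cells and thin normal panels propagate as NA", {
    cond <- c("normal", "normal", "normal", "tumor")
    vals <- rbind(c(1e-4, NA, NA, 2e-3),    # only 1 defined normal
                  c(1e-4, 1e-4, NA, 2e-3),  # 2 defined normals: testable
                  c(1e-4, 1e-4, 1e-4, NA))  # undefined tumor cell
    je <- toyExperiment(vals, cond)
    m <- outlierCallMatrix(callOutliers(je, outlierParams()))
    expect_true(all(is.na(m[1, ])))
    expect_equal(unname(m[2, 4]), 1L)
    expect_true(is.na(m[2, 3]))
    expect_true(is.na(m[3, 4]))
})

test_that("Fisher enrichment p-values match brute-force enumeration", {
    expect_equal(fisherTestJunction(0, 40, 0, 25), 1.0)
    p <- fisherTestJunction(40, 40, 0, 25)
    expect_lt(p, 1e-10)
    expect_equal(p, oracleFisherGreater(40, 40, 0, 25), tolerance = 1e-12)
    expect_equal(fisherTestJunction(20, 40, 0, 25),
                 oracleFisherGreater(20, 40, 0, 25), tolerance = 1e-12)
    # also matches base R's one-sided exact test
    ft <- stats::fisher.test(matrix(c(20, 20, 0, 25), 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(fisherTestJunction(20, 40, 0, 25), unname(ft$p.value),
                 tolerance = 1e-12)
    expect_true(is.na(fisherTestJunction(0, 0, 1, 5)))
    expect_error(fisherTestJunction(5, 4, 0, 5), "exceed")
})

test_that("p-values are invariant to sample ordering", {
    set.seed(21)
    cond <- c(rep("normal", 3), rep("tumor", 3))
    vals <- matrix(rexp(18, rate = 1e4), 3)
    je1 <- toyExperiment(vals, cond)
    perm <- c(4, 2, 6, 1, 3, 5)
    je2 <- toyExperiment(vals[, perm], cond[perm])
    p1 <- detectEvents(je1, outlierParams(foldChangeCutoff = 2))$events
    p2 <- detectEvents(je2, outlierParams(foldChangeCutoff = 2))$events
    expect_equal(p1$p_value, p2$p_value)
})

test_that("BH adjustment matches hand-computed step-up values", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(c(0.001, 0.5, 1)), c(0.003, 0.75, 1))
    expect_equal(bhAdjust(c(0.2, 0.2, 0.2)), rep(0.2, 3))
    expect_equal(bhAdjust(c(0.03, 0.01)), c(0.03, 0.02))
    expect_equal(bhAdjust(c(0.05, 0.1, 0.5, 0.5, 1)),
                 c(0.25, 0.25, 0.625, 0.625, 1))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    # order preservation: permute-then-adjust equals adjust-then-permute
    set.seed(7)
    p <- runif(50)
    perm <- sample.int(50)
    expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
    expect_equal(bhAdjust(p), oracleBH(p))
})

test_that("detectEvents matches the literal brute-force pipeline on small cohorts", {
    set.seed(123)
    for (rep in 1:8) {
        nN <- sample(2:4, 1)
        nT <- sample(1:3, 1)
        cond <- c(rep("normal", nN), rep("tumor", nT))
        nJ <- sample(1:5, 1)
        vals <- matrix(10^runif(nJ * length(cond), -6, -2), nJ)
        vals[runif(length(vals)) < 0.1] <- NA  # sprinkle undefined cells
        fc <- sample(c(2, 10), 1)
        je <- toyExperiment(vals, cond)
        params <- outlierParams(foldChangeCutoff = fc)
        got <- detectEvents(je, params)
        # literal per-cell rules
        expCalls <- oracleCalls(vals, cond, fc = fc)
        dimnames(expCalls) <- dimnames(outlierCallMatrix(got$calls))
        expect_equal(outlierCallMatrix(got$calls), expCalls)
        # literal Fisher + BH on the outlier counts
        tI <- which(cond == "tumor"); nI <- which(cond == "normal")
        for (d in c("over", "under")) {
            code <- if (d == "over") 1L else -1L
            ev <- got$events[got$events$direction == d, ]
            for (r in seq_len(nrow(ev))) {
                j <- match(ev$junction_id[r],
                           rownames(outlierCallMatrix(got$calls)))
                a <- sum(expCalls[j, tI] == code, na.rm = TRUE)
                b <- sum(expCalls[j, nI] == code, na.rm = TRUE)
                tn <- sum(!is.na(expCalls[j, tI]))
                nn <- sum(!is.na(expCalls[j, nI]))
                expect_equal(ev$p_value[r],
                             oracleFisherGreater(a, tn, b, nn),
                             tolerance = 1e-12)
            }
        }
        expect_equal(got$events$fdr, oracleBH(got$events$p_value))
    }
})

test_that("raising thresholds never increases the number of outlier calls", {
    set.seed(31)
    cond <- c(rep("normal", 5), rep("tumor", 5))
    vals <- matrix(10^runif(100, -6, -2), 10)
    je <- toyExperiment(vals, cond)
    nCalls <- function(p) {
        m <- outlierCallMatrix(callOutliers(je, p))
        sum(m != 0L, na.rm = TRUE)
    }
    fcs <- c(1, 2, 5, 10, 50)
    byFc <- vapply(fcs, function(fc)
        nCalls(outlierParams(foldChangeCutoff = fc)), numeric(1))
    expect_true(all(diff(byFc) <= 0))
    floors <- c(0, 1e-5, 1e-4, 1e-3)
    byFloor <- vapply(floors, function(fl)
        nCalls(outlierParams(minNormExpr = fl, foldChangeCutoff = 2)),
        numeric(1))
    expect_true(all(diff(byFloor) <= 0))
})

test_that("a tumor pinned at the normal median is never an outlier", {
    set.seed(17)
    cond <- c(rep("normal", 5), rep("tumor", 4))
    vals <- matrix(10^runif(45, -5, -3), 5)
    med <- apply(vals[, 1:5], 1, median)
    vals <- cbind(vals, med)  # extra tumor sitting exactly at the median
    je <- toyExperiment(vals, c(cond, "tumor"))
    base <- callOutliers(toyExperiment(vals[, 1:9], cond),
                         outlierParams(foldChangeCutoff = 2))
    more <- callOutliers(je, outlierParams(foldChangeCutoff = 2))
    expect_true(all(outlierCallMatrix(more)[, 10] == 0L))
    expect_equal(rowSums(outlierCallMatrix(more)[, 6:9, drop = FALSE] == 1L),
                 rowSums(outlierCallMatrix(base)[, 6:9, drop = FALSE] == 1L))
})

test_that("a junction enriched for tumor outliers is significant end to end", {
    # 20/40 tumors over-expressed, 0/25 normals: single-junction cohort
    cond <- c(rep("normal", 25), rep("tumor", 40))
    vals <- matrix(c(rep(1e-4, 25), rep(5e-3, 20), rep(1.05e-4, 20)), 1)
    je <- toyExperiment(vals, cond)
    res <- detectEvents(je, outlierParams())
    over <- res$events[res$events$direction == "over", ]
    expect_equal(over$tumor_outlier_count, 20L)
    expect_equal(over$normal_outlier_count, 0L)
    expect_true(over$significant)
    expect_equal(over$p_value, oracleFisherGreater(20, 40, 0, 25),
                 tolerance = 1e-12)
})

test_that("swapping tumor and normal labels kills one-sided significance", {
    cond <- c(rep("normal", 10), rep("tumor", 10))
    vals <- rbind(c(rep(1e-4, 10), rep(5e-3, 10)),
                  c(rep(2e-4, 10), rep(2.1e-4, 10)),
                  c(rep(5e-4, 10), rep(4.9e-4, 10)))
    je <- toyExperiment(vals, cond)
    res <- detectEvents(je, outlierParams(foldChangeCutoff = 2))
    overSig <- with(res$events, significant[direction == "over"])
    expect_true(any(overSig))
    flipped <- ifelse(cond == "tumor", "normal", "tumor")
    jeF <- toyExperiment(vals, flipped)
    resF <- detectEvents(jeF, outlierParams(foldChangeCutoff = 2))
    # over-expression moved into the "normal" group: the one-sided test
    # for tumor over-enrichment finds nothing there
    expect_false(any(with(resF$events, significant[direction == "over"])))
})

test_that("an all-zero cohort produces no significant events", {
    cond <- c(rep("normal", 3), rep("tumor", 3))
    vals <- matrix(0, 4, 6)
    je <- toyExperiment(vals, cond)
    res <- detectEvents(je, outlierParams())
    expect_equal(sum(res$events$significant), 0L)
    expect_true(all(res$events$p_value == 1))
})
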