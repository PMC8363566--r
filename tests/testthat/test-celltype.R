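# Cell-type attribution: QC boundaries, log-normalisation, per-type
# averaging, percent-of-total and the enrichment test.

# A tiny hand-built experiment: 6 genes x 6 cells over 3 types.
make_tiny_sce <- function() {
    counts <- matrix(c(
        10, 12,  0,  0, 0, 0,    # fibroblast-only gene
         5,  5,  5,  5, 5, 5,    # uniform gene
         0,  0,  8,  9, 0, 0,
         2,  1,  3,  2, 4, 1,
         1,  0,  0,  1, 2, 3,
         3,  3,  2,  2, 1, 1), nrow = 6, byrow = TRUE,
        dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:6)))
    CellCountsExperiment(counts,
        cellType = rep(c("fibroblast", "ductal", "acinar"), each = 2),
        mitoGenes = character(0))
}

test_that("QC boundaries follow the strict retention rules", {
    # 300 genes; cells engineered to sit on each boundary
    nGenes <- 300
    geneIds <- c(sprintf("MT-%d", 1:5), sprintf("g%d", 1:(nGenes - 5)))
    counts <- matrix(0L, nGenes, 4,
        dimnames = list(geneIds, sprintf("c%d", 1:4)))
    counts[6:205, 1] <- 1L   # exactly 200 features: removed (> 200 rule)
    counts[6:206, 2] <- 1L   # 201 features: kept
    counts[6:205, 3] <- 1L   # 201 features, mito 40/240 = 1/6 > 0.15:
    counts[1, 3] <- 40L      #   removed
    counts[6:226, 4] <- 1L   # 222 features, mito 39/260 = 0.15 exactly:
    counts[1, 4] <- 39L      #   retained
    sce <- CellCountsExperiment(counts,
        cellType = rep("fibroblast", 4), mitoGenes = geneIds[1:5])
    kept <- colnames(qcFilterCells(sce))
    expect_false("c1" %in% kept)   # exactly 200 features
    expect_true("c2" %in% kept)    # 201 features
    expect_false("c3" %in% kept)   # mito 1/6 > 0.15
    expect_true("c4" %in% kept)    # mito exactly 0.15 retained
    # upper bound is strict too
    big <- matrix(1L, 2600, 1,
        dimnames = list(sprintf("g%d", 1:2600), "cBig"))
    sceBig <- CellCountsExperiment(cbind(big,
        cOk = c(rep(1L, 300), rep(0L, 2300))),
        cellType = c("a", "a"), mitoGenes = character(0))
    expect_identical(colnames(qcFilterCells(sceBig)), "cOk")
    # QC filters commute
    a <- qcFilterCells(qcFilterCells(sce, maxMitoFrac = 1),
        minFeatures = 0, maxFeatures = Inf)
    b <- qcFilterCells(qcFilterCells(sce, minFeatures = 0,
        maxFeatures = Inf), maxMitoFrac = 1)
    expect_identical(colnames(a), colnames(b))
    # empty result fails with attrition counts
    expect_error(qcFilterCells(sce, minFeatures = 5000), "no cells pass")
})

test_that("log-normalisation matches its closed form", {
    counts <- matrix(c(10L, 0L, 0L, 3L, 4L, 5L), nrow = 3,
        dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
    sce <- CellCountsExperiment(counts, cellType = c("a", "a"))
    norm <- SummarizedExperiment::assay(logNormalizeCells(sce), "lognorm")
    # one expressed gene, count 10 of total 10
    expect_equal(norm["g1", "c1"], log(1 + 10000))
    # elementwise formula oracle
    total <- colSums(counts)
    expect_equal(unname(norm),
        unname(log1p(sweep(counts, 2, total, "/") * 1e4)))
    # compositional invariance: doubling a cell's counts changes nothing
    sce2 <- CellCountsExperiment(cbind(counts, c3 = 2L * counts[, "c1"]),
        cellType = c("a", "a", "a"))
    n2 <- SummarizedExperiment::assay(logNormalizeCells(sce2), "lognorm")
    expect_equal(n2[, "c3"], n2[, "c1"])
    # zero-total cell refuses
    sce0 <- CellCountsExperiment(cbind(counts, c0 = c(0L, 0L, 0L)),
        cellType = c("a", "a", "a"))
    expect_error(logNormalizeCells(sce0), "zero total")
})

test_that("per-type averaging equals brute-force group means", {
    sce <- logNormalizeCells(make_tiny_sce())
    avg <- averageExpressionByType(sce)
    norm <- SummarizedExperiment::assay(sce, "lognorm")
    lab <- SummarizedExperiment::colData(sce)$cell_type
    for (tp in unique(lab))
        expect_equal(avg[, tp],
            rowMeans(expm1(norm[, lab == tp, drop = FALSE])))
    # arithmetic-mean-of-logs option
    avgLog <- averageExpressionByType(sce, delog = FALSE)
    expect_equal(avgLog[, "ductal"],
        rowMeans(norm[, lab == "ductal"]))
    # zero-everywhere gene averages zero in all types
    expect_true(all(avg["g1", c("ductal", "acinar")] == 0))
})

test_that("percent-of-total rows sum to 100 and detect exclusivity", {
    sce <- logNormalizeCells(make_tiny_sce())
    pct <- percentOfTotal(averageExpressionByType(sce))
    expect_true(all(abs(rowSums(pct) - 100) < 1e-6))
    # fibroblast-exclusive gene: 100% fibroblast, 0 elsewhere
    expect_equal(pct["g1", "fibroblast"], 100)
    expect_equal(unname(pct["g1", c("ductal", "acinar")]), c(0, 0))
    # scale invariance of a row
    avg <- averageExpressionByType(sce)
    avg2 <- avg; avg2["g2", ] <- avg2["g2", ] * 7.3
    expect_equal(percentOfTotal(avg2)["g2", ], pct["g2", ])
    # uniform gene across equal library sizes: ~100/ntypes each
    counts <- matrix(5L, 4, 9, dimnames = list(sprintf("g%d", 1:4),
        sprintf("c%d", 1:9)))
    sceU <- logNormalizeCells(CellCountsExperiment(counts,
        cellType = defaultCellTypes()))
    pctU <- percentOfTotal(averageExpressionByType(sceU))
    expect_equal(unname(pctU[1, ]), rep(100 / 9, 9))
    # zero-total gene: all-zero row, flagged
    avg0 <- rbind(avg, gz = 0)
    p0 <- percentOfTotal(avg0)
    expect_true(all(p0["gz", ] == 0))
    expect_identical(attr(p0, "zero_total"), "gz")
})

test_that("enrichment test separates planted from uniform signals", {
    pct <- matrix(100 / 3, 6, 3, dimnames = list(sprintf("g%d", 1:6),
        c("fibroblast", "ductal", "acinar")))
    flat <- enrichmentTest(pct, rownames(pct), "fibroblast")
    expect_gt(flat$raw_p, 0.99)
    expect_equal(flat$bonferroni_p, 1)
    # exclusive expression: p -> 0
    excl <- pct; excl[, ] <- 0; excl[, "fibroblast"] <- 100
    strong <- enrichmentTest(excl +
        matrix(abs(rnorm(18, 0, 1e-6)), 6, 3), rownames(pct),
        "fibroblast")
    expect_lt(strong$bonferroni_p, 1e-10)
    # bonferroni arithmetic
    expect_equal(strong$bonferroni_p,
        min(1, strong$raw_p * strong$n_comparisons))
    # absent genes are skipped; too few genes refuse; 1 type refuses
    expect_message(enrichmentTest(pct, c("g1", "g2", "nope"),
        "fibroblast"), "absent")
    expect_error(enrichmentTest(pct, c("g1", "zz"), "fibroblast"),
        ">= 2 genes")
    expect_error(enrichmentTest(pct[, 1, drop = FALSE], c("g1", "g2"),
        "fibroblast"), ">= 2 cell types")
})

test_that("planted fibroblast enrichment is flagged across seeds", {
    genes <- sprintf("gene%03d", 1:16)
    hits <- vapply(1:25, function(s) {
        sce <- simulateCellCounts(cellsPerType = 25,
            plantedEnriched = data.frame(gene = genes,
                cell_type = "fibroblast", multiplier = 5),
            seed = 700 + s)
        sce <- logNormalizeCells(qcFilterCells(sce))
        pct <- percentOfTotal(averageExpressionByType(sce))
        enrichmentTest(pct, genes, "fibroblast")$bonferroni_p < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("cohort-wise attribution mirrors the two-cohort analysis", {
    sce <- simulateCellCounts(cellsPerType = 30,
        plantedEnriched = data.frame(gene = sprintf("gene%03d", 1:16),
            cell_type = "fibroblast", multiplier = 5), seed = 41)
    SummarizedExperiment::colData(sce)$cohort <-
        rep(c("SS", "nonSS"), length.out = ncol(sce))
    rep2 <- attributeGeneList(sce, sprintf("gene%03d", 1:16))
    expect_setequal(names(rep2), c("SS", "nonSS"))
    expect_true(all(vapply(rep2, function(r) r$bonferroni_p,
        numeric(1)) < 0.05))
})
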