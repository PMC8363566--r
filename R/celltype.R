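# Single-cell attribution of a gene list to cell types: QC filtering,
# log-normalisation, per-cell-type averaging on the de-logged scale, the
# percent-of-total-expression statistic, and the enrichment test that asks
# whether a gene list is preferentially expressed by one cell type
# (fibroblasts, in the motivating analysis). Counts travel as a
# SingleCellExperiment (genes x cells) with cell types in
# colData(sce)$cell_type and mitochondrial genes flagged in
# rowData(sce)$is_mito.

#' Build a single-cell counts experiment
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param cellType per-cell type labels (character), length ncol(counts).
#' @param mitoGenes character vector of mitochondrial gene ids (subset of
#'   rownames) used for the QC fraction.
#' @param cohort optional per-cell cohort labels (e.g. SS / non-SS).
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
CellCountsExperiment <- function(counts, cellType = NULL, mitoGenes = character(0),
                                 cohort = NULL) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    storage.mode(counts) <- "integer"
    stopifnot(all(mitoGenes %in% rownames(counts)))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(cellType)) {
        stopifnot(length(cellType) == ncol(counts))
        cd$cell_type <- as.character(cellType)
    }
    if (!is.null(cohort)) cd$cohort <- as.character(cohort)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    SummarizedExperiment::rowData(sce)$is_mito <-
        rownames(counts) %in% mitoGenes
    sce
}

#' Quality-control filtering of cells
#'
#' Retains cells with a unique-feature count strictly greater than
#' \code{minFeatures} and strictly fewer than \code{maxFeatures}, then
#' removes cells whose mitochondrial count fraction is strictly greater
#' than \code{maxMitoFrac} (a cell at exactly the threshold is retained).
#' The two filters commute.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay and
#'   \code{rowData(sce)$is_mito}.
#' @param minFeatures,maxFeatures exclusive feature-count bounds
#'   (defaults 200 and 2500).
#' @param maxMitoFrac maximum mitochondrial fraction (default 0.15).
#' @return the filtered SingleCellExperiment, with a per-criterion
#'   attrition record in \code{metadata(sce)$qc_attrition}.
#' @export
qcFilterCells <- function(sce, minFeatures = 200, maxFeatures = 2500,
                          maxMitoFrac = 0.15) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    isMito <- SummarizedExperiment::rowData(sce)$is_mito
    nFeatures <- colSums(counts > 0)
    total <- colSums(counts)
    mitoFrac <- ifelse(total > 0,
        colSums(counts[isMito, , drop = FALSE]) / total, 0)
    passFeat <- nFeatures > minFeatures & nFeatures < maxFeatures
    passMito <- mitoFrac <= maxMitoFrac
    keep <- passFeat & passMito
    attrition <- list(
        n_input = ncol(counts),
        failed_features = sum(!passFeat),
        failed_mito = sum(!passMito),
        n_retained = sum(keep))
    if (!any(keep))
        stop("no cells pass QC (", attrition$failed_features,
             " failed the feature filter, ", attrition$failed_mito,
             " the mitochondrial filter)")
    out <- sce[, keep]
    S4Vectors::metadata(out)$qc_attrition <- attrition
    out
}

#' Log-normalise single-cell counts
#'
#' Per cell: value = ln(1 + count / total_counts * scale), the standard
#' library-size normalisation with natural-log transform.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay; no cell may
#'   have zero total counts (QC removes such cells).
#' @param scale scale factor (default 10000).
#' @return the SingleCellExperiment with a \code{lognorm} assay added.
#' @export
logNormalizeCells <- function(sce, scale = 10000) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    total <- colSums(counts)
    if (any(total == 0))
        stop("cell(s) with zero total counts; run qcFilterCells first")
    norm <- log1p(sweep(counts, 2L, total, "/") * scale)
    SummarizedExperiment::assay(sce, "lognorm") <- norm
    sce
}

#' Average expression per cell type
#'
#' For each gene and cell type, the mean over that type's cells of the
#' de-logged normalised expression, expm1(lognorm) -- the average-expression
#' convention of the standard single-cell workflow. Set
#' \code{delog = FALSE} for an arithmetic mean of the log values.
#'
#' @param sce SingleCellExperiment with \code{lognorm} assay and
#'   \code{colData(sce)$cell_type}; every cell must be labelled.
#' @param delog average on the de-logged scale (default TRUE).
#' @return genes x cell-types matrix of average expression.
#' @export
averageExpressionByType <- function(sce, delog = TRUE) {
    labels <- SummarizedExperiment::colData(sce)$cell_type
    if (is.null(labels) || anyNA(labels))
        stop("every cell must carry a cell_type label")
    m <- SummarizedExperiment::assay(sce, "lognorm")
    if (delog) m <- expm1(m)
    types <- sort(unique(labels))
    avg <- vapply(types, function(tp)
        rowMeans(m[, labels == tp, drop = FALSE]),
        numeric(nrow(m)))
    if (nrow(m) == 1L) avg <- matrix(avg, nrow = 1L,
        dimnames = list(rownames(m), types))
    avg
}

#' Percent-of-total expression across cell types
#'
#' For each gene, 100 times its average expression in one cell type divided
#' by the sum of its average expression over all cell types. Rows of genes
#' with any expression sum to 100; genes expressed nowhere get an all-zero
#' row and are flagged in the "zero_total" attribute.
#'
#' @param avgExpr genes x cell-types non-negative matrix from
#'   [averageExpressionByType()].
#' @return matrix of the same shape with rows scaled to percent.
#' @export
percentOfTotal <- function(avgExpr) {
    avgExpr <- as.matrix(avgExpr)
    if (any(avgExpr < 0)) stop("average expression must be non-negative")
    total <- rowSums(avgExpr)
    pct <- avgExpr
    nz <- total > 0
    pct[nz, ] <- 100 * avgExpr[nz, , drop = FALSE] / total[nz]
    pct[!nz, ] <- 0
    attr(pct, "zero_total") <- rownames(avgExpr)[!nz]
    pct
}

#' Cell-type enrichment test for a gene list
#'
#' Asks whether a gene list's percent-of-total expression is concentrated
#' in a target cell type. The primary report is a two-sample two-sided
#' t-test of the target-type percent values (one per gene) against the
#' pooled percent values of all other types, Bonferroni-corrected by the
#' number of cell types (every type could have been the target). Per-type
#' tests (target versus each other type, Bonferroni over n_types - 1) are
#' also returned.
#'
#' @param pct percent matrix from [percentOfTotal()].
#' @param geneList character vector of >= 2 gene ids; genes absent from the
#'   matrix are skipped with a message.
#' @param targetType column name of the target cell type.
#' @param varEqual pooled-variance t (default TRUE).
#' @return list with \code{target_type}, \code{mean_percent} (per-type mean
#'   for the list), \code{raw_p}, \code{bonferroni_p} (target vs rest),
#'   \code{n_comparisons}, and \code{per_type} (data.frame of per-type
#'   tests).
#' @export
enrichmentTest <- function(pct, geneList, targetType, varEqual = TRUE) {
    types <- colnames(pct)
    if (length(types) < 2L)
        stop("enrichment test needs >= 2 cell types")
    if (!targetType %in% types)
        stop("unknown target type: ", targetType)
    present <- geneList %in% rownames(pct)
    if (!all(present))
        message(sum(!present), " gene(s) in the list absent from the ",
            "matrix; skipped")
    geneList <- geneList[present]
    if (length(geneList) < 2L)
        stop("need >= 2 genes present in the matrix")
    sub <- pct[geneList, , drop = FALSE]
    target <- sub[, targetType]
    others <- sub[, setdiff(types, targetType), drop = FALSE]
    tt <- twoSampleT(target, as.numeric(others), varEqual = varEqual)
    nTypes <- length(types)
    perType <- do.call(rbind, lapply(setdiff(types, targetType),
        function(tp) {
            t2 <- twoSampleT(target, sub[, tp], varEqual = varEqual)
            data.frame(other_type = tp, t = t2$t, raw_p = t2$p,
                bonferroni_p = min(1, t2$p * (nTypes - 1L)),
                stringsAsFactors = FALSE)
        }))
    list(target_type = targetType,
         mean_percent = colMeans(sub),
         raw_p = tt$p,
         bonferroni_p = min(1, tt$p * nTypes),
         n_comparisons = nTypes,
         per_type = perType)
}

#' Run the attribution chain per cohort
#'
#' Convenience wrapper mirroring the two-cohort analysis: QC,
#' normalisation, averaging, percent-of-total and the enrichment test are
#' run separately for every cohort label present (or once when no cohort
#' column exists).
#'
#' @param sce SingleCellExperiment from [CellCountsExperiment()].
#' @param geneList gene ids to attribute.
#' @param targetType target cell type (default "fibroblast").
#' @param ... passed to [qcFilterCells()].
#' @return named list of [enrichmentTest()] reports, one per cohort.
#' @export
attributeGeneList <- function(sce, geneList, targetType = "fibroblast", ...) {
    cohorts <- SummarizedExperiment::colData(sce)$cohort
    splitIds <- if (is.null(cohorts)) list(all = seq_len(ncol(sce)))
        else split(seq_len(ncol(sce)), cohorts)
    lapply(splitIds, function(idx) {
        sub <- qcFilterCells(sce[, idx], ...)
        sub <- logNormalizeCells(sub)
        pct <- percentOfTotal(averageExpressionByType(sub))
        enrichmentTest(pct, geneList, targetType)
    })
}
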