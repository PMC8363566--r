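# Pipeline driver: a declarative configuration whose numeric defaults are
# the study's printed values, a manifest for reproducibility, and a driver
# that runs the enabled stages in dependency order on a synthetic bundle
# or user-supplied inputs.

#' Pipeline configuration with study defaults
#'
#' Every numeric default is the study's printed value: the 50 um^2 island
#' rule, fold change > 1.5 and p < 0.05 for differential expression,
#' detection in at least 4 of 20 samples, 200/2500 unique-feature bounds
#' and the 15 percent mitochondrial cap for single-cell QC, the 10000
#' normalisation scale factor, 1000-bp promoters. All are overridable.
#'
#' @param ... overrides of any default, by name.
#' @return a named list of class \code{rifaPipelineConfig}.
#' @seealso [explainDefaults()] for the provenance of each default.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        minIslandUm2 = 50,
        fcThreshold = 1.5,
        pThreshold = 0.05,
        minPM = 4,
        minFeatures = 200,
        maxFeatures = 2500,
        maxMitoFrac = 0.15,
        scaleFactor = 10000,
        upstream = 1000,
        scoreFraction = 0.8,
        targetCellType = "fibroblast",
        seed = 1,
        stages = c("histology", "expression", "celltype", "promoters"))
    over <- list(...)
    bad <- setdiff(names(over), c(names(cfg)))
    if (length(bad)) stop("unknown config field(s): ",
        paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    class(cfg) <- "rifaPipelineConfig"
    cfg
}

#' Explain the provenance of each configuration default
#'
#' @return data.frame with \code{param}, \code{default} and the study
#'   quantity it encodes.
#' @export
explainDefaults <- function() {
    data.frame(
        param = c("minIslandUm2", "fcThreshold", "pThreshold", "minPM",
            "minFeatures", "maxFeatures", "maxMitoFrac", "scaleFactor",
            "upstream", "scoreFraction"),
        default = c(50, 1.5, 0.05, 4, 200, 2500, 0.15, 10000, 1000, 0.8),
        meaning = c(
            "enclosed non-fibrotic objects below this area (um^2) are kept as fibrosis",
            "differential expression requires fold change above this",
            "significance threshold for DE, correlation and t-tests",
            "genes need Present/Marginal flags in at least this many samples (of 20)",
            "cells must have strictly more unique features than this",
            "cells must have strictly fewer unique features than this",
            "cells above this mitochondrial count fraction are removed",
            "library-size normalisation scale factor",
            "promoter length: bp upstream of the transcription start site",
            "motif hit threshold as a fraction of the maximum PWM score"),
        stringsAsFactors = FALSE)
}

#' Generate the full synthetic input bundle
#'
#' One call producing coherent inputs for every stage: a trichrome slide,
#' an expression dataset with 16 planted RIFA-correlated genes and planted
#' group fold changes, single-cell counts with the planted genes enriched
#' in fibroblasts, and a toy genome whose open promoters are the planted
#' genes' promoters with one motif consensus planted in six of them.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param nPlanted number of planted RIFA-correlated genes (default 16).
#' @return named list with \code{slide}, \code{expression},
#'   \code{cells}, \code{genome}, and \code{plantedGenes}.
#' @export
simulateStudyBundle <- function(seed = 1, nPlanted = 16) {
    s <- as.integer(seed) %% 100000L
    plantedGenes <- sprintf("gene%03d", seq_len(nPlanted))
    slide <- simulateTrichromeImage(fibrosisFraction = 0.3,
        islandAreasUm2 = c(40, 80), seed = s + 11L)
    # slope/noise sized for ~0.9 power at n = 20 (r ~ 0.65)
    expr <- simulateExpressionData(
        plantedCorrelated = data.frame(gene = plantedGenes,
            slope = 400, noise_sd = NA),
        plantedDE = data.frame(gene = sprintf("gene%03d", 21:35),
            fold_change = 3, group = "SCS"),
        seed = s + 23L)
    cells <- simulateCellCounts(
        plantedEnriched = data.frame(gene = plantedGenes,
            cell_type = "fibroblast", multiplier = 5),
        seed = s + 37L)
    genome <- simulateGenomeCoverage(
        openGenes = plantedGenes, openMultiplier = 3,
        plantedMotifs = data.frame(gene = plantedGenes[1:6],
            consensus = "TGCGTGGGCG", offset = 100),
        seed = s + 51L)
    list(slide = slide, expression = expr, cells = cells,
        genome = genome, plantedGenes = plantedGenes)
}

#' Run the analysis pipeline on a synthetic bundle
#'
#' Executes the enabled stages in dependency order -- histology RIFA,
#' expression screens (normalisation, flag filtering, RIFA correlation,
#' differential expression with Venn intersection), cell-type attribution
#' of the RIFA-correlated genes, and promoter accessibility with motif
#' ranking -- writing per-stage TSV/JSON outputs and a run manifest.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   writing files.
#' @param bundle a [simulateStudyBundle()] result; default generated from
#'   \code{config$seed}.
#' @return list with per-stage results and \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        bundle = NULL) {
    stopifnot(inherits(config, "rifaPipelineConfig"))
    if (is.null(bundle)) bundle <- simulateStudyBundle(config$seed)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    results <- list()
    counts <- list()

    if ("histology" %in% config$stages) {
        sl <- bundle$slide
        est <- rifaFromImage(sl$image, umPerPx = sl$umPerPx,
            minIslandUm2 = config$minIslandUm2)
        results$histology <- list(
            rifa_estimate = rifa(est), rifa_truth = sl$truth$rifa,
            result = est)
        counts$histology <- 1L
    }

    if ("expression" %in% config$stages) {
        se <- quantileNormalize(bundle$expression)
        se <- filterLowIntensity(se, minPM = config$minPM)
        corr <- correlateWithRifa(se, pThreshold = config$pThreshold)
        cd <- SummarizedExperiment::colData(se)
        deA <- differentialExpression(se,
            groupA = which(cd$group == "SCS"),
            groupB = which(cd$group == "NSCS"))
        deB <- differentialExpression(se,
            groupA = which(cd$group == "SCS"),
            groupB = which(cd$group == "FLS/SCS"))
        setA <- selectDE(deA, config$fcThreshold, config$pThreshold, "up")
        setB <- selectDE(deB, config$fcThreshold, config$pThreshold, "up")
        venn <- intersectGeneSets(list(SCSvsNSCS = setA,
            SCSvsFLSSCS = setB))
        reg <- linearRegressionFit(cd$rifa, cd$uws_flow)
        results$expression <- list(correlation = corr,
            selected = corr$gene_id[corr$selected],
            de = list(SCSvsNSCS = deA, SCSvsFLSSCS = deB),
            deSets = list(SCSvsNSCS = setA, SCSvsFLSSCS = setB),
            venn = venn, uwsRegression = reg)
        counts$expression <- nrow(corr)
    }

    if ("celltype" %in% config$stages) {
        genes <- if (!is.null(results$expression))
            intersect(results$expression$selected,
                rownames(bundle$cells)) else character(0)
        if (length(genes) < 2L) genes <- bundle$plantedGenes
        sce <- qcFilterCells(bundle$cells,
            minFeatures = config$minFeatures,
            maxFeatures = config$maxFeatures,
            maxMitoFrac = config$maxMitoFrac)
        sce <- logNormalizeCells(sce, scale = config$scaleFactor)
        pct <- percentOfTotal(averageExpressionByType(sce))
        enr <- enrichmentTest(pct, genes, config$targetCellType)
        results$celltype <- list(percent = pct, enrichment = enr,
            genes = genes,
            qc = S4Vectors::metadata(sce)$qc_attrition)
        counts$celltype <- ncol(sce)
    }

    if ("promoters" %in% config$stages) {
        gn <- bundle$genome
        prom <- mergePromoters(gn$promoters)
        cov <- meanRegionCoverage(gn$coverage, prom)
        isOpen <- vapply(GenomicRanges::mcols(prom)$gene_ids,
            function(g) any(g %in% bundle$plantedGenes), logical(1))
        cmp <- compareRegionSets(cov[isOpen, ], cov[!isOpen, ],
            nComparisons = 1L)
        models <- list(
            pfmToPwm(consensusPfm("TGCGTGGGCG"), tfName = "KLF-like"),
            pfmToPwm(consensusPfm("ATATCGAT"), tfName = "decoy"))
        ranks <- rankTFs(models,
            gn$promoterSeqs[bundle$plantedGenes],
            scoreFraction = config$scoreFraction)
        # the openness multiplier is estimated against the background
        # (non-set) promoters; with genome-scale promoter counts the
        # all-promoter mean converges to the same denominator
        results$promoters <- list(coverage = cov, comparison = cmp,
            tfRanks = ranks,
            openRatio = mean(cov$mean_depth[isOpen]) /
                mean(cov$mean_depth[!isOpen]))
        counts$promoters <- nrow(cov)
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("rifaquant")),
        config = unclass(config),
        stage_counts = counts,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    if (!is.null(outDir)) {
        if (!is.null(results$expression)) {
            utils::write.table(results$expression$correlation,
                file.path(outDir, "rifa_correlation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            utils::write.table(results$expression$de$SCSvsNSCS,
                file.path(outDir, "de_scs_vs_nscs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        }
        if (!is.null(results$promoters)) {
            utils::write.table(results$promoters$coverage,
                file.path(outDir, "promoter_coverage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            utils::write.table(results$promoters$tfRanks,
                file.path(outDir, "tf_ranks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        }
        report <- list(manifest = manifest,
            histology = results$histology[c("rifa_estimate",
                "rifa_truth")],
            uws_regression = results$expression$uwsRegression,
            enrichment = results$celltype$enrichment[
                c("target_type", "raw_p", "bonferroni_p")],
            promoter_comparison = results$promoters$comparison)
        jsonlite::write_json(report,
            file.path(outDir, "report.json"), auto_unbox = TRUE,
            digits = NA, force = TRUE)
        manifest$output_md5 <- as.list(tools::md5sum(
            list.files(outDir, full.names = TRUE, pattern = "\\.tsv$")))
    }
    results$manifest <- manifest
    results
}

# A near-deterministic PFM for a consensus sequence: 97 counts on the
# consensus base, 1 on each alternative.
consensusPfm <- function(consensus) {
    codes <- encodeDNA(consensus)
    pfmMat <- matrix(1, 4, length(codes))
    pfmMat[cbind(codes, seq_along(codes))] <- 97
    pfmMat
}
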