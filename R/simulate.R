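# Seeded synthetic-data generators covering every input the pipeline
# consumes, each with recorded ground truth: trichrome slide images with a
# known fibrosis fraction and enclosed non-fibrotic islands; a 20-sample
# expression matrix with genes planted to correlate linearly with a RIFA
# vector and planted group fold changes; multi-cell-type negative-binomial
# counts with planted fibroblast enrichment and controlled mitochondrial
# fractions; and a toy genome with planted open promoters and planted motif
# occurrences.

# Evaluate code under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    ge <- globalenv()
    old <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
        get(".Random.seed", envir = ge) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = ge, inherits = FALSE))
                rm(".Random.seed", envir = ge)
        } else assign(".Random.seed", old, envir = ge)
    })
    set.seed(seed)
    force(code)
}

# A quasi-disc mask of exactly nPx pixels centred at (ci, cj): the nPx grid
# cells closest to the centre. Deterministic tie-break by (distance, index).
discMaskExact <- function(nPx, nr, nc, ci, cj) {
    r <- ceiling(sqrt(nPx / pi)) + 2L
    ii <- max(1L, ci - r):min(nr, ci + r)
    jj <- max(1L, cj - r):min(nc, cj + r)
    grid <- expand.grid(i = ii, j = jj)
    d <- (grid$i - ci)^2 + (grid$j - cj)^2
    ord <- order(d, grid$i, grid$j)
    sel <- grid[ord[seq_len(min(nPx, nrow(grid)))], ]
    cbind(sel$i, sel$j)
}

#' Simulate a Masson-trichrome-stained slide image with known truth
#'
#' Builds an elliptical gland region, grows a fibrotic region inside it to
#' a target area fraction, carves enclosed non-fibrotic islands of exact
#' pixel areas into the fibrosis, and renders the section in optical
#' density space with two stain vectors (collagen blue, cytoplasm red)
#' plus Gaussian sensor noise. The returned truth RIFA applies the minimum
#' island rule to the truth masks: carved islands at or above
#' \code{minIslandUm2} stay subtracted, smaller ones count as fibrosis.
#'
#' @param widthPx,heightPx image size in pixels (default 192 x 192).
#' @param umPerPx micrometres per pixel (default 1).
#' @param fibrosisFraction target fibrosis fraction of the gland area, in
#'   [0, 1); an unreachable target (> 0.95 of the growable region) fails.
#' @param islandAreasUm2 numeric vector of enclosed non-fibrotic island
#'   areas to carve into the fibrosis, in um^2.
#' @param minIslandUm2 island-subtraction threshold used for the truth
#'   RIFA (default 50).
#' @param noiseSd Gaussian sensor noise on the rendered RGB intensities
#'   (default 0.01).
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @return list with \code{image} (H x W x 3 array in [0, 1]),
#'   \code{glandMask}, \code{fibrosisMask} (logical, islands carved out),
#'   \code{truth} (list: rifa, fibrosisAreaMm2, glandAreaMm2,
#'   subtractedAreaMm2, islandAreasPx, concentrations), \code{umPerPx}.
#' @export
simulateTrichromeImage <- function(widthPx = 192, heightPx = 192,
                                   umPerPx = 1, fibrosisFraction = 0.3,
                                   islandAreasUm2 = numeric(0),
                                   minIslandUm2 = 50, noiseSd = 0.01,
                                   seed = 1) {
    stopifnot(fibrosisFraction >= 0, fibrosisFraction < 1)
    withSeed(seed, {
        nr <- heightPx; nc <- widthPx
        ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
        ra <- 0.44 * nr; rb <- 0.44 * nc
        ii <- matrix(seq_len(nr), nr, nc)
        jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        gland <- ((ii - ci) / ra)^2 + ((jj - cj) / rb)^2 <= 1
        glandPx <- sum(gland)
        fib <- matrix(FALSE, nr, nc)
        targetPx <- round(fibrosisFraction * glandPx)
        if (targetPx > 0.95 * glandPx)
            stop("fibrosis fraction target unreachable for this geometry")
        # islands first: each one is carved into the centre of its own
        # fibrotic anchor disc, which guarantees full enclosure; island
        # pixels are protected from later fibrosis growth
        islandPx <- integer(0)
        protected <- matrix(FALSE, nr, nc)
        if (length(islandAreasUm2)) {
            occupied <- matrix(FALSE, nr, nc)
            for (aUm2 in islandAreasUm2) {
                nPx <- round(aUm2 / umPerPx^2)
                rAnchor <- ceiling(sqrt(nPx / pi)) + 4L
                cand <- which(erodeMask(gland, rAnchor + 1L) &
                    erodeMask(!occupied, rAnchor + 1L))
                if (!length(cand))
                    stop("no room to enclose an island of ", aUm2,
                         " um^2 in this gland geometry")
                centre <- arrayInd(cand[sample.int(length(cand), 1L)],
                    dim(fib))
                anchor <- discMaskExact(round(pi * rAnchor^2), nr, nc,
                    centre[1], centre[2])
                fib[anchor] <- TRUE
                occupied[anchor] <- TRUE
                px <- discMaskExact(nPx, nr, nc, centre[1], centre[2])
                fib[px] <- FALSE
                protected[px] <- TRUE
                islandPx <- c(islandPx, nrow(px))
            }
        }
        # grow fibrosis to the target by adding quasi-discs inside the
        # gland, shrinking the disc size as the target is approached
        glandIdx <- which(gland & !protected)
        guard <- 0L
        while (sum(fib) < targetPx) {
            guard <- guard + 1L
            if (guard > 5000L)
                stop("fibrosis fraction target unreachable (growth stalled)")
            remaining <- targetPx - sum(fib)
            discPx <- max(9L, min(round(0.03 * glandPx), remaining))
            centre <- arrayInd(sample(glandIdx, 1L), dim(gland))
            px <- discMaskExact(discPx, nr, nc, centre[1], centre[2])
            sel <- gland[px] & !protected[px]
            px <- px[sel, , drop = FALSE]
            if (remaining < nrow(px)) {
                new <- !fib[px]
                px <- px[which(new)[seq_len(min(remaining, sum(new)))], ,
                    drop = FALSE]
            }
            fib[px] <- TRUE
        }
        # truth RIFA: the island rule applied to the final truth masks
        # (random growth can enclose additional small non-fibrotic holes
        # beyond the planted islands, so the rule is applied to every
        # enclosed component, not just the planted list)
        minPx <- minIslandUm2 / umPerPx^2
        comp <- enclosedNonFibroticComponents(fib, gland)
        encAreas <- comp$areasPx[comp$enclosed]
        fibEffPx <- sum(fib) + sum(encAreas[encAreas < minPx])
        subtractedPx <- sum(encAreas[encAreas >= minPx])
        truthRifa <- fibEffPx / glandPx
        px2mm2 <- umPerPx^2 * 1e-6
        # render: optical densities from two stains + sensor noise
        V <- massonStainVectors()
        cFib <- matrix(0, nr, nc)
        cTis <- matrix(0, nr, nc)
        cFib[fib] <- pmax(0.2, stats::rnorm(sum(fib), 1.0, 0.08))
        tis <- gland & !fib
        cTis[tis] <- pmax(0.2, stats::rnorm(sum(tis), 0.9, 0.08))
        od <- array(0, dim = c(nr, nc, 3))
        for (k in 1:3)
            od[, , k] <- cFib * V[k, 1] + cTis * V[k, 2]
        img <- 10^(-od)
        img <- img + array(stats::rnorm(length(img), 0, noiseSd), dim(img))
        img[img < 0] <- 0; img[img > 1] <- 1
        list(image = img, glandMask = gland, fibrosisMask = fib,
            truth = list(
                rifa = truthRifa,
                fibrosisAreaMm2 = fibEffPx * px2mm2,
                glandAreaMm2 = glandPx * px2mm2,
                subtractedAreaMm2 = subtractedPx * px2mm2,
                islandAreasPx = islandPx,
                concentrations = list(collagen = cFib, cytoplasm = cTis)),
            umPerPx = umPerPx,
            params = list(fibrosisFraction = fibrosisFraction,
                noiseSd = noiseSd, seed = seed))
    })
}

erodeMask <- function(mask, radius) {
    if (!any(mask)) return(mask)
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- EBImage::erode(EBImage::Image(mask * 1), brush) > 0.5
    matrix(as.logical(m), nrow = nrow(mask))
}

#' Simulate a microarray-style expression dataset with planted structure
#'
#' Intensities are log-normal on the linear scale. Genes listed in
#' \code{plantedCorrelated} follow E[expr] = baseline + slope * RIFA with
#' additive Gaussian noise; genes in \code{plantedDE} have their mean
#' multiplied by a fold change in the affected group. Detection flags are
#' P/M except for randomly injected Absent calls. The default RIFA vector
#' mirrors the four microscopic groups (FLS, NSCS, FLS/SCS, SCS; five
#' samples each) with group means near 0.06, 0.27, 0.32 and 0.60, and the
#' clinical table includes an unstimulated whole saliva flow rate
#' generated as a noisy negative linear function of RIFA.
#'
#' @param nGenes number of genes (default 200).
#' @param groups per-sample group labels (default 5 each of FLS, NSCS,
#'   FLS/SCS, SCS).
#' @param rifa per-sample RIFA in [0, 1]; default drawn per group.
#' @param plantedCorrelated data.frame(gene, slope, noise_sd); gene ids
#'   must exist. A noise_sd of NA is calibrated to the realised RIFA
#'   spread for a planted correlation of ~0.66 (power ~0.9 at n = 20).
#' @param plantedDE data.frame(gene, fold_change, group); fold_change > 0
#'   and >= 2 groups must be present.
#' @param flagAbsentRate probability of an Absent flag per gene x sample
#'   (default 0.1).
#' @param baselineMeanLog,baselineSdLog log-normal baseline parameters.
#' @param noiseSdLog multiplicative log-scale noise for unplanted genes.
#' @param seed integer seed.
#' @return a SummarizedExperiment (see [ExpressionExperiment()]) with
#'   planted truth in \code{metadata(se)$truth}.
#' @export
simulateExpressionData <- function(nGenes = 200,
        groups = rep(c("FLS", "NSCS", "FLS/SCS", "SCS"), each = 5),
        rifa = NULL,
        plantedCorrelated = NULL, plantedDE = NULL,
        flagAbsentRate = 0.1,
        baselineMeanLog = log(100), baselineSdLog = 0.8,
        noiseSdLog = 0.25, seed = 1) {
    nSamples <- length(groups)
    if (!is.null(rifa) && length(rifa) != nSamples)
        stop("'rifa' must have one value per sample")
    if (!is.null(plantedDE) && length(unique(groups)) < 2L)
        stop("planted differential expression needs >= 2 groups")
    if (!is.null(plantedDE) && any(plantedDE$fold_change <= 0))
        stop("fold_change must be > 0")
    withSeed(seed, {
        geneIds <- sprintf("gene%03d", seq_len(nGenes))
        sampleIds <- sprintf("s%02d", seq_len(nSamples))
        if (is.null(rifa)) {
            groupMeans <- c(FLS = 0.06, NSCS = 0.27, `FLS/SCS` = 0.32,
                SCS = 0.60)
            # group SDs = published SEMs (0.02, 0.12, 0.10, 0.08) * sqrt(5)
            groupSds <- c(FLS = 0.045, NSCS = 0.27, `FLS/SCS` = 0.22,
                SCS = 0.18)
            mu <- groupMeans[groups]
            sdv <- groupSds[groups]
            mu[is.na(mu)] <- 0.3; sdv[is.na(sdv)] <- 0.15
            rifa <- pmin(0.95, pmax(0.01, stats::rnorm(nSamples, mu, sdv)))
        }
        baseline <- stats::rlnorm(nGenes, baselineMeanLog, baselineSdLog)
        m <- baseline * matrix(
            exp(stats::rnorm(nGenes * nSamples, 0, noiseSdLog)),
            nGenes, nSamples)
        dimnames(m) <- list(geneIds, sampleIds)
        if (!is.null(plantedCorrelated)) {
            stopifnot(all(plantedCorrelated$gene %in% geneIds))
            for (k in seq_len(nrow(plantedCorrelated))) {
                g <- plantedCorrelated$gene[k]
                nsd <- plantedCorrelated$noise_sd[k]
                if (is.na(nsd)) {
                    # calibrate the noise to the realised RIFA spread so
                    # the planted population correlation is ~0.66 (power
                    # ~0.9 for a two-sided 0.05 test at n = 20)
                    r0 <- 0.66
                    nsd <- abs(plantedCorrelated$slope[k]) *
                        stats::sd(rifa) * sqrt(1 / r0^2 - 1)
                }
                m[g, ] <- pmax(1e-3,
                    baseline[match(g, geneIds)] +
                    plantedCorrelated$slope[k] * rifa +
                    stats::rnorm(nSamples, 0, nsd))
            }
        }
        if (!is.null(plantedDE)) {
            stopifnot(all(plantedDE$gene %in% geneIds),
                all(plantedDE$group %in% groups))
            for (k in seq_len(nrow(plantedDE))) {
                g <- plantedDE$gene[k]
                sel <- groups == plantedDE$group[k]
                m[g, sel] <- m[g, sel] * plantedDE$fold_change[k]
            }
        }
        flags <- matrix(
            ifelse(stats::runif(nGenes * nSamples) < flagAbsentRate,
                "A", "P"),
            nGenes, nSamples, dimnames = dimnames(m))
        marginal <- flags == "P" &
            matrix(stats::runif(nGenes * nSamples) < 0.05, nGenes, nSamples)
        flags[marginal] <- "M"
        # UWS flow: negative linear function of RIFA, noise sized so the
        # regression recovers r^2 near 1/3
        uwsSlope <- -0.67
        uwsNoiseSd <- abs(uwsSlope) * stats::sd(rifa) * sqrt(2)
        uws <- pmax(0, 0.75 + uwsSlope * rifa +
            stats::rnorm(nSamples, 0, uwsNoiseSd))
        clinical <- data.frame(sample_id = sampleIds, group = groups,
            rifa = rifa, uws_flow = uws, stringsAsFactors = FALSE)
        se <- ExpressionExperiment(m, flags = flags, clinical = clinical)
        S4Vectors::metadata(se)$truth <- list(
            baseline = stats::setNames(baseline, geneIds),
            plantedCorrelated = plantedCorrelated,
            plantedDE = plantedDE, uwsSlope = uwsSlope, seed = seed)
        se
    })
}

#' Default cell-type panel for the synthetic single-cell generator
#'
#' Nine labels matching the cluster panel of a labial salivary gland
#' dissociation: fibroblast, ductal, acinar, myoepithelial, endothelial,
#' T cell, B cell, plasma cell and other.
#'
#' @return character vector of 9 cell-type names.
#' @export
defaultCellTypes <- function() {
    c("fibroblast", "ductal", "acinar", "myoepithelial", "endothelial",
      "T_cell", "B_cell", "plasma", "other")
}

#' Simulate multi-cell-type single-cell counts with planted enrichment
#'
#' Negative-binomial counts with per-gene means and a common dispersion;
#' genes listed in \code{plantedEnriched} have their expected counts
#' multiplied in their target cell type (a multiplier of \code{Inf} makes
#' the gene exclusive to that type). Each cell's expected mitochondrial
#' fraction is drawn from \code{mitoFractionRange}; optionally a subset of
#' cells is planted at a high mitochondrial fraction to exercise the QC
#' filter.
#'
#' @param cellTypes cell-type names (default [defaultCellTypes()]).
#' @param cellsPerType cells per type (default 40).
#' @param nGenes number of genes (default 400); the first
#'   \code{nMitoGenes} are named MT-like and flagged mitochondrial.
#' @param nMitoGenes number of mitochondrial genes (default 10).
#' @param plantedEnriched data.frame(gene, cell_type, multiplier).
#' @param mitoFractionRange range of per-cell expected mitochondrial
#'   fraction (default c(0.02, 0.08)).
#' @param highMitoCells number of cells (spread over types) planted at
#'   \code{highMitoFraction} (default 0).
#' @param highMitoFraction planted high mitochondrial fraction
#'   (default 0.2).
#' @param meanLog,sdLog log-normal parameters of per-gene mean counts.
#' @param dispersion negative-binomial size parameter (default 2).
#' @param seed integer seed.
#' @return a SingleCellExperiment (see [CellCountsExperiment()]) with the
#'   planted truth in \code{metadata(sce)$truth} (including each cell's
#'   expected mitochondrial fraction and the high-mito cell ids).
#' @export
simulateCellCounts <- function(cellTypes = defaultCellTypes(),
        cellsPerType = 40, nGenes = 400, nMitoGenes = 10,
        plantedEnriched = NULL,
        mitoFractionRange = c(0.02, 0.08),
        highMitoCells = 0, highMitoFraction = 0.2,
        meanLog = 0.3, sdLog = 0.8, dispersion = 2, seed = 1) {
    if (!is.null(plantedEnriched) &&
        !all(plantedEnriched$cell_type %in% cellTypes))
        stop("planted enrichment targets unknown cell type(s)")
    withSeed(seed, {
        nCells <- length(cellTypes) * cellsPerType
        labels <- rep(cellTypes, each = cellsPerType)
        cellIds <- sprintf("cell%04d", seq_len(nCells))
        mitoGenes <- sprintf("MT-g%02d", seq_len(nMitoGenes))
        geneIds <- c(mitoGenes, sprintf("gene%03d",
            seq_len(nGenes - nMitoGenes)))
        mu <- stats::rlnorm(nGenes, meanLog, sdLog)
        names(mu) <- geneIds
        libScale <- stats::rlnorm(nCells, 0, 0.1)
        # genes x cells expected counts before mito adjustment
        M <- outer(mu, libScale)
        if (!is.null(plantedEnriched)) {
            stopifnot(all(plantedEnriched$gene %in% geneIds))
            for (k in seq_len(nrow(plantedEnriched))) {
                g <- plantedEnriched$gene[k]
                tgt <- labels == plantedEnriched$cell_type[k]
                mult <- plantedEnriched$multiplier[k]
                if (is.infinite(mult)) {
                    M[g, !tgt] <- 0
                    M[g, tgt] <- M[g, tgt] * 5   # exclusive, boosted
                } else {
                    M[g, tgt] <- M[g, tgt] * mult
                }
            }
        }
        # per-cell expected mitochondrial fraction
        mitoFrac <- stats::runif(nCells, mitoFractionRange[1],
            mitoFractionRange[2])
        highIds <- character(0)
        if (highMitoCells > 0) {
            hi <- sample.int(nCells, min(highMitoCells, nCells))
            mitoFrac[hi] <- highMitoFraction
            highIds <- cellIds[hi]
        }
        isMito <- geneIds %in% mitoGenes
        sNon <- colSums(M[!isMito, , drop = FALSE])
        sMito <- colSums(M[isMito, , drop = FALSE])
        k <- mitoFrac * sNon / ((1 - mitoFrac) * pmax(sMito, 1e-12))
        M[isMito, ] <- sweep(M[isMito, , drop = FALSE], 2L, k, "*")
        counts <- matrix(
            stats::rnbinom(length(M), size = dispersion, mu = M),
            nrow = nGenes, dimnames = list(geneIds, cellIds))
        sce <- CellCountsExperiment(counts, cellType = labels,
            mitoGenes = mitoGenes)
        S4Vectors::metadata(sce)$truth <- list(
            plantedEnriched = plantedEnriched,
            mitoFraction = stats::setNames(mitoFrac, cellIds),
            highMitoCells = highIds, mu = mu, seed = seed)
        sce
    })
}

#' Simulate a toy genome with coverage and planted promoter signal
#'
#' Generates random chromosome sequences, gene TSS positions on both
#' strands, uniform background reads, extra reads over the promoters of a
#' chosen "open" gene subset (multiplying their expected depth), and
#' optionally writes motif consensus sequences into promoter sequences at
#' stated offsets.
#'
#' @param nChroms number of chromosomes (default 2).
#' @param chromLength length of each chromosome in bp (default 200000).
#' @param nGenes number of genes (default 60), TSS placed away from the
#'   chromosome ends so promoters are unclipped.
#' @param openGenes character vector of gene ids with boosted promoter
#'   coverage (default none).
#' @param openMultiplier depth multiplier over open promoters (default 3).
#' @param backgroundDepth mean background depth in reads per base
#'   (default 3).
#' @param readLength read length in bp (default 50).
#' @param upstream promoter length (default 1000).
#' @param plantedMotifs data.frame(gene, consensus, offset): write the
#'   consensus into the gene's promoter at the 0-based offset from the
#'   region start; a motif extending past the promoter fails.
#' @param seed integer seed.
#' @return list with \code{genome} (DNAStringSet), \code{genes} (GRanges
#'   of width-1 TSS with gene_id), \code{reads} (GRanges),
#'   \code{coverage} (RleList), \code{promoters} (unmerged GRanges),
#'   \code{promoterSeqs} (named character, forward-strand promoter
#'   sequence per gene) and \code{truth} (data.frame: gene_id, open,
#'   multiplier, expected_depth).
#' @export
simulateGenomeCoverage <- function(nChroms = 2, chromLength = 200000,
        nGenes = 60, openGenes = character(0), openMultiplier = 3,
        backgroundDepth = 3, readLength = 50, upstream = 1000,
        plantedMotifs = NULL, seed = 1) {
    withSeed(seed, {
        chromNames <- paste0("chr", seq_len(nChroms))
        sizes <- stats::setNames(rep(chromLength, nChroms), chromNames)
        seqs <- vapply(chromNames, function(cn)
            paste(sample(BASES, chromLength, replace = TRUE),
                collapse = ""), character(1))
        geneIds <- sprintf("gene%03d", seq_len(nGenes))
        chrom <- sample(chromNames, nGenes, replace = TRUE)
        # keep promoters clear of chromosome bounds
        tss0 <- sample.int(chromLength - 2L * (upstream + 100L),
            nGenes, replace = TRUE) + upstream + 50L
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        genesDf <- data.frame(gene_id = geneIds, chrom = chrom,
            tss = tss0, strand = strand, stringsAsFactors = FALSE)
        prom <- buildPromoters(genesDf, upstream = upstream,
            chromSizes = sizes)
        # plant motif consensi into promoter (genomic) sequence
        if (!is.null(plantedMotifs)) {
            for (k in seq_len(nrow(plantedMotifs))) {
                g <- plantedMotifs$gene[k]
                cons <- toupper(plantedMotifs$consensus[k])
                off <- plantedMotifs$offset[k]
                i <- match(g, GenomicRanges::mcols(prom)$gene_id)
                if (is.na(i)) stop("unknown gene in plantedMotifs: ", g)
                s <- GenomicRanges::start(prom)[i]       # 1-based
                e <- GenomicRanges::end(prom)[i]
                if (off + nchar(cons) > e - s + 1L)
                    stop("motif extends past the promoter bounds for ", g)
                cn <- as.character(GenomicRanges::seqnames(prom))[i]
                substr(seqs[cn], s + off, s + off + nchar(cons) - 1L) <- cons
            }
        }
        genome <- Biostrings::DNAStringSet(seqs)
        names(genome) <- chromNames
        # background reads: uniform starts per chromosome
        readsList <- lapply(chromNames, function(cn) {
            n <- stats::rpois(1, backgroundDepth * chromLength / readLength)
            starts <- sample.int(chromLength - readLength + 1L, n,
                replace = TRUE)
            GenomicRanges::GRanges(cn,
                IRanges::IRanges(start = starts, width = readLength),
                strand = sample(c("+", "-"), n, replace = TRUE),
                seqlengths = sizes)
        })
        # extra reads over open promoters
        if (length(openGenes)) {
            sel <- match(openGenes, GenomicRanges::mcols(prom)$gene_id)
            if (anyNA(sel)) stop("unknown gene id in openGenes")
            for (i in sel) {
                w <- GenomicRanges::width(prom)[i]
                nExtra <- stats::rpois(1,
                    backgroundDepth * (openMultiplier - 1) * w / readLength)
                if (nExtra == 0) next
                s <- GenomicRanges::start(prom)[i]
                starts <- s + sample.int(max(1L, w - readLength + 1L),
                    nExtra, replace = TRUE) - 1L
                readsList[[length(readsList) + 1L]] <-
                    GenomicRanges::GRanges(
                        as.character(GenomicRanges::seqnames(prom))[i],
                        IRanges::IRanges(start = starts,
                            width = readLength),
                        strand = sample(c("+", "-"), nExtra,
                            replace = TRUE),
                        seqlengths = sizes)
            }
        }
        reads <- suppressWarnings(do.call(c, readsList))
        cov <- coverageFromReads(reads)
        promSeqs <- vapply(seq_along(prom), function(i) {
            cn <- as.character(GenomicRanges::seqnames(prom))[i]
            substr(seqs[cn], GenomicRanges::start(prom)[i],
                GenomicRanges::end(prom)[i])
        }, character(1))
        names(promSeqs) <- GenomicRanges::mcols(prom)$gene_id
        truth <- data.frame(
            gene_id = geneIds,
            open = geneIds %in% openGenes,
            multiplier = ifelse(geneIds %in% openGenes, openMultiplier, 1),
            expected_depth = backgroundDepth *
                ifelse(geneIds %in% openGenes, openMultiplier, 1),
            stringsAsFactors = FALSE)
        list(genome = genome, genes = GenomicRanges::GRanges(
                seqnames = genesDf$chrom,
                ranges = IRanges::IRanges(start = genesDf$tss + 1L,
                    width = 1L),
                strand = genesDf$strand, gene_id = genesDf$gene_id,
                seqlengths = sizes),
            reads = reads, coverage = cov, promoters = prom,
            promoterSeqs = promSeqs, truth = truth,
            chromSizes = sizes,
            params = list(backgroundDepth = backgroundDepth,
                openMultiplier = openMultiplier, readLength = readLength,
                upstream = upstream, seed = seed))
    })
}
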