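# Promoter accessibility: build 1-kb upstream promoter intervals from
# annotated TSS positions, merge overlapping promoters, compute per-base
# read coverage, average it over regions, and compare region sets.
#
# Coordinates: the external convention is BED-style 0-based half-open;
# in-memory intervals are GRanges (1-based closed), and the readers/writers
# convert. For a + strand TSS at 0-based position t, the promoter is the
# 0-based interval [t - 1000, t); for a - strand TSS it is [t + 1, t + 1001),
# i.e. the 1000 bases 3' of the TSS position in genome coordinates. Promoters
# are clipped at chromosome bounds and flagged when clipped.

#' Build upstream promoter regions
#'
#' @param genes a \code{GRanges} of width-1 TSS positions with strand and a
#'   \code{gene_id} metadata column, carrying seqlengths; or a data.frame
#'   with \code{gene_id}, \code{chrom}, \code{tss} (0-based), \code{strand}
#'   plus a named \code{chromSizes} vector.
#' @param upstream promoter length in bp (default 1000).
#' @param chromSizes named chromosome lengths (required for data.frame
#'   input).
#' @return a \code{GRanges} of promoters with \code{gene_id} and
#'   \code{clipped} metadata columns; genes on unknown chromosomes are
#'   skipped with a message.
#' @export
buildPromoters <- function(genes, upstream = 1000, chromSizes = NULL) {
    if (is.data.frame(genes)) {
        if (is.null(chromSizes))
            stop("'chromSizes' is required for data.frame input")
        known <- genes$chrom %in% names(chromSizes)
        if (!all(known))
            message(sum(!known), " gene(s) on unknown chromosomes skipped")
        genes <- genes[known, , drop = FALSE]
        gr <- GenomicRanges::GRanges(
            seqnames = genes$chrom,
            ranges = IRanges::IRanges(start = genes$tss + 1L, width = 1L),
            strand = genes$strand,
            gene_id = genes$gene_id,
            seqlengths = chromSizes)
    } else {
        gr <- genes
        if (is.null(GenomicRanges::mcols(gr)$gene_id))
            stop("'genes' must carry a gene_id metadata column")
        if (anyNA(GenomeInfoDb::seqlengths(gr)))
            stop("'genes' must carry seqlengths for clipping")
    }
    tss0 <- GenomicRanges::start(gr) - 1L       # 0-based TSS
    plus <- as.character(GenomicRanges::strand(gr)) != "-"
    start0 <- ifelse(plus, tss0 - upstream, tss0 + 1L)
    end0 <- ifelse(plus, tss0, tss0 + 1L + upstream)
    L <- GenomeInfoDb::seqlengths(gr)[as.character(
        GenomicRanges::seqnames(gr))]
    clippedStart <- pmax(start0, 0L)
    clippedEnd <- pmin(end0, L)
    if (any(clippedEnd <= clippedStart))
        stop("a promoter collapses to zero width; is the TSS inside its ",
             "chromosome?")
    prom <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(gr),
        ranges = IRanges::IRanges(start = clippedStart + 1L,
            end = clippedEnd),
        strand = GenomicRanges::strand(gr),
        seqlengths = GenomeInfoDb::seqlengths(gr))
    GenomicRanges::mcols(prom)$gene_id <- GenomicRanges::mcols(gr)$gene_id
    GenomicRanges::mcols(prom)$clipped <-
        clippedStart != start0 | clippedEnd != end0
    S4Vectors::metadata(prom)$merged <- FALSE
    prom
}

#' Merge overlapping or book-ended promoters
#'
#' Unions overlapping and directly adjacent promoter intervals on the same
#' chromosome regardless of strand; each merged region carries the union of
#' the gene ids it covers. Idempotent.
#'
#' @param promoters \code{GRanges} from [buildPromoters()] (or any GRanges
#'   with a \code{gene_id} column).
#' @return merged, sorted \code{GRanges} with a \code{gene_ids}
#'   CharacterList column.
#' @export
mergePromoters <- function(promoters) {
    red <- GenomicRanges::reduce(promoters, ignore.strand = TRUE,
        min.gapwidth = 1L)
    hits <- GenomicRanges::findOverlaps(red, promoters,
        ignore.strand = TRUE)
    mc <- GenomicRanges::mcols(promoters)
    idsList <- if (!is.null(mc$gene_id)) as.list(as.character(mc$gene_id))
        else if (!is.null(mc$gene_ids)) as.list(mc$gene_ids)
        else as.list(as.character(seq_along(promoters)))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    gl <- lapply(seq_along(red), function(i)
        sort(unique(unlist(idsList[sh[qh == i]]))))
    GenomicRanges::mcols(red)$gene_ids <- IRanges::CharacterList(gl)
    red <- GenomicRanges::sort(red, ignore.strand = TRUE)
    S4Vectors::metadata(red)$merged <- TRUE
    red
}

#' Per-base coverage from read intervals
#'
#' depth(b) = number of reads covering base b, optionally after removing
#' duplicate reads (identical chromosome, start, end and strand). Reads
#' extending beyond their chromosome are clipped with a warning.
#'
#' @param reads \code{GRanges} of aligned-read intervals with seqlengths.
#' @param dedup remove coordinate-identical duplicates (default FALSE).
#' @return an \code{RleList} of per-base depth, one run-length vector per
#'   chromosome, tiling each chromosome.
#' @export
coverageFromReads <- function(reads, dedup = FALSE) {
    if (anyNA(GenomeInfoDb::seqlengths(reads)))
        stop("'reads' must carry seqlengths")
    L <- GenomeInfoDb::seqlengths(reads)[as.character(
        GenomicRanges::seqnames(reads))]
    if (any(GenomicRanges::end(reads) > L) ||
        any(GenomicRanges::start(reads) < 1L)) {
        warning("read(s) beyond chromosome bounds were clipped")
        reads <- GenomicRanges::trim(reads)
    }
    if (dedup) reads <- unique(reads)
    GenomicRanges::coverage(reads)
}

#' Mean per-base coverage of regions
#'
#' mean_depth = sum of depth over the region's bases divided by the region
#' width, zero-depth bases included (set \code{excludeZero = TRUE} to
#' average over covered bases only).
#'
#' @param track \code{RleList} coverage from [coverageFromReads()] or a
#'   bedGraph import.
#' @param regions \code{GRanges} of (merged) regions.
#' @param excludeZero average over non-zero bases only (default FALSE).
#' @return data.frame with \code{chrom}, \code{start} (0-based),
#'   \code{end}, \code{mean_depth}, and \code{gene_ids} when present.
#' @export
meanRegionCoverage <- function(track, regions, excludeZero = FALSE) {
    if (length(regions) == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
            end = integer(0), mean_depth = numeric(0)))
    chroms <- as.character(GenomicRanges::seqnames(regions))
    if (!all(chroms %in% names(track)))
        stop("coverage track lacks chromosome(s): ",
             paste(setdiff(chroms, names(track)), collapse = ", "))
    meanDepth <- vapply(seq_along(regions), function(i) {
        v <- track[[chroms[i]]]
        s <- GenomicRanges::start(regions)[i]
        e <- GenomicRanges::end(regions)[i]
        w <- S4Vectors::window(v, s, e)
        if (excludeZero) {
            nz <- w[w > 0]
            if (length(nz) == 0L) 0 else mean(nz)
        } else mean(w)
    }, numeric(1))
    out <- data.frame(
        chrom = chroms,
        start = GenomicRanges::start(regions) - 1L,
        end = GenomicRanges::end(regions),
        mean_depth = as.numeric(meanDepth),
        stringsAsFactors = FALSE)
    ids <- GenomicRanges::mcols(regions)$gene_ids
    if (!is.null(ids))
        out$gene_ids <- vapply(ids, paste, character(1), collapse = ",")
    out
}

#' Compare promoter coverage between two region sets
#'
#' Two-sided two-sample t-test on per-region mean depths with Bonferroni
#' correction over the number of comparisons performed in the run; group
#' mean +/- SEM is reported.
#'
#' @param covA,covB data.frames from [meanRegionCoverage()] (or numeric
#'   vectors of mean depths); each side needs >= 2 regions.
#' @param nComparisons Bonferroni multiplier (default 1).
#' @param varEqual pooled-variance t (default TRUE).
#' @return list with per-set \code{mean}, \code{sem}, \code{n}, the test
#'   \code{t}, \code{df}, \code{raw_p} and \code{bonferroni_p}.
#' @export
compareRegionSets <- function(covA, covB, nComparisons = 1L,
                              varEqual = TRUE) {
    a <- if (is.data.frame(covA)) covA$mean_depth else as.numeric(covA)
    b <- if (is.data.frame(covB)) covB$mean_depth else as.numeric(covB)
    if (length(a) < 2L || length(b) < 2L)
        stop("each region set needs >= 2 regions")
    tt <- twoSampleT(a, b, varEqual = varEqual)
    list(
        meanA = mean(a), semA = stats::sd(a) / sqrt(length(a)),
        nA = length(a),
        meanB = mean(b), semB = stats::sd(b) / sqrt(length(b)),
        nB = length(b),
        t = tt$t, df = tt$df, raw_p = tt$p,
        bonferroni_p = min(1, tt$p * nComparisons),
        n_comparisons = nComparisons)
}
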