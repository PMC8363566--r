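# Microarray-style expression statistics: quantile normalisation,
# detection-flag filtering, differential expression with fold-change
# selection, gene-set intersection, and the RIFA correlation/regression
# screens. Expression data travel as a SummarizedExperiment with an
# 'intensities' assay (genes x samples, linear scale), an optional 'flags'
# assay (P/M/A detection calls) and clinical covariates in colData.

#' Build an expression experiment
#'
#' @param intensities genes x samples numeric matrix (linear scale,
#'   non-negative). Rows with missing values are dropped with a message
#'   (imputation is refused).
#' @param flags optional character matrix of detection calls in
#'   \{P, M, A\}, same dimension.
#' @param clinical optional data.frame with one row per sample (matched by
#'   \code{sample_id} column or by order) carrying e.g. \code{group},
#'   \code{rifa}, \code{uws_flow}.
#' @return a [SummarizedExperiment::SummarizedExperiment] with metadata
#'   flag \code{normalized = FALSE}.
#' @export
ExpressionExperiment <- function(intensities, flags = NULL, clinical = NULL) {
    intensities <- as.matrix(intensities)
    keep <- stats::complete.cases(intensities)
    if (!all(keep)) {
        message(sum(!keep), " gene(s) dropped for missing intensities")
        intensities <- intensities[keep, , drop = FALSE]
        if (!is.null(flags)) flags <- flags[keep, , drop = FALSE]
    }
    assays <- list(intensities = intensities)
    if (!is.null(flags)) {
        flags <- as.matrix(flags)
        stopifnot(identical(dim(flags), dim(intensities)),
            all(flags %in% c("P", "M", "A")))
        assays$flags <- flags
    }
    cd <- if (is.null(clinical)) {
        S4Vectors::DataFrame(row.names = colnames(intensities))
    } else {
        clinical <- as.data.frame(clinical)
        if ("sample_id" %in% names(clinical)) {
            rownames(clinical) <- clinical$sample_id
            clinical <- clinical[colnames(intensities), , drop = FALSE]
        }
        S4Vectors::DataFrame(clinical, row.names = colnames(intensities))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd)
    S4Vectors::metadata(se)$normalized <- FALSE
    se
}

#' Quantile normalisation of intensity columns
#'
#' Forces every sample (column) to the same empirical distribution: the
#' vector of row-wise means of the sorted columns. Tied values receive the
#' mean of the reference values spanning their ranks. Idempotent.
#'
#' @param se a SummarizedExperiment with an \code{intensities} assay, or a
#'   bare matrix.
#' @return same class as the input, normalised; a single-sample input is
#'   returned unchanged with a warning.
#' @export
quantileNormalize <- function(se) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "intensities") else as.matrix(se)
    if (ncol(m) < 2L) {
        warning("single-sample matrix: quantile normalisation is a no-op")
        return(se)
    }
    norm <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(norm) <- dimnames(m)
    if (is(se, "SummarizedExperiment")) {
        SummarizedExperiment::assay(se, "intensities") <- norm
        S4Vectors::metadata(se)$normalized <- TRUE
        se
    } else norm
}

#' Low-intensity filtering by detection flags
#'
#' Retains genes detected (flag P or M) in at least \code{minPM} samples.
#' The study default is 4 of 20 samples; when \code{minPM} is omitted it
#' generalises as \code{ceiling(0.2 * n_samples)}.
#'
#' @param se SummarizedExperiment with \code{intensities} and \code{flags}
#'   assays.
#' @param minPM minimum number of P/M samples per retained gene.
#' @return the SummarizedExperiment restricted to retained genes.
#' @export
filterLowIntensity <- function(se, minPM = NULL) {
    flags <- SummarizedExperiment::assay(se, "flags")
    if (is.null(minPM)) minPM <- ceiling(0.2 * ncol(flags))
    pm <- rowSums(flags == "P" | flags == "M")
    se[pm >= minPM, ]
}

#' Differential expression between two sample groups
#'
#' Per-gene fold change as the ratio of the linear-scale group means
#' (A over B) and a two-sided two-sample t-test (pooled variance by
#' default, Welch optionally). Genes whose group-B mean is zero have an
#' undefined fold change and are excluded with a message.
#'
#' @param se SummarizedExperiment (or matrix) of linear-scale intensities.
#' @param groupA,groupB character vectors of sample ids, or logical/integer
#'   column indices; each group needs >= 2 samples.
#' @param varEqual pooled-variance t (default) or Welch when FALSE.
#' @param logScale set TRUE if intensities are log2: they are converted
#'   back to linear scale before averaging.
#' @return data.frame with \code{gene_id}, \code{fold_change},
#'   \code{p_value}, \code{direction} ("up" iff fold change > 1).
#' @export
differentialExpression <- function(se, groupA, groupB, varEqual = TRUE,
                                   logScale = FALSE) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "intensities") else as.matrix(se)
    if (logScale) m <- 2^m
    a <- m[, groupA, drop = FALSE]
    b <- m[, groupB, drop = FALSE]
    if (ncol(a) < 2L || ncol(b) < 2L)
        stop("each group needs at least 2 samples")
    mb <- rowMeans(b)
    ok <- mb != 0
    if (!all(ok))
        message(sum(!ok), " gene(s) excluded: zero mean in group B ",
            "makes the fold change undefined")
    res <- lapply(which(ok), function(i) {
        tt <- twoSampleT(a[i, ], b[i, ], varEqual = varEqual)
        fc <- mean(a[i, ]) / mb[i]
        data.frame(
            gene_id = if (is.null(rownames(m))) as.character(i)
                else rownames(m)[i],
            fold_change = fc, p_value = tt$p,
            direction = if (fc > 1) "up" else "down",
            stringsAsFactors = FALSE)
    })
    if (!length(res))
        return(data.frame(gene_id = character(0),
            fold_change = numeric(0), p_value = numeric(0),
            direction = character(0)))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Select significantly differentially expressed genes
#'
#' Strict thresholds: fold change > \code{fcThreshold} (direction "up") or
#' < 1/\code{fcThreshold} ("down"), and p < \code{pThreshold}. A gene at
#' exactly the fold-change threshold is excluded.
#'
#' @param results data.frame from [differentialExpression()].
#' @param fcThreshold fold-change cut (default 1.5).
#' @param pThreshold p-value cut (default 0.05).
#' @param direction "up", "down" or "both" (default "up").
#' @return character vector of selected gene ids.
#' @export
selectDE <- function(results, fcThreshold = 1.5, pThreshold = 0.05,
                     direction = c("up", "down", "both")) {
    direction <- match.arg(direction)
    up <- results$fold_change > fcThreshold
    down <- results$fold_change < 1 / fcThreshold
    dirOk <- switch(direction, up = up, down = down, both = up | down)
    results$gene_id[dirOk & results$p_value < pThreshold]
}

#' Intersect gene sets with Venn region counts
#'
#' @param sets named list of >= 2 character vectors.
#' @return list with \code{common} (intersection of all sets) and
#'   \code{regions}, a data.frame of every membership pattern with its
#'   count; region counts sum to the size of the union.
#' @export
intersectGeneSets <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2L)
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    sets <- lapply(sets, unique)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
        logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
        dimnames = list(NULL, names(sets)))
    pattern <- apply(member, 1L, function(z) paste(ifelse(z, "1", "0"),
        collapse = ""))
    regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
    names(regions) <- c("pattern", "count")
    common <- Reduce(intersect, sets)
    list(common = common, regions = regions, union_size = length(universe))
}

#' Screen gene expression for positive correlation with RIFA
#'
#' Per-gene Pearson correlation of normalised expression against the
#' per-sample RIFA vector; two-sided p from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. A gene is
#' selected when r > 0 and p < \code{pThreshold} (the screen is one-sided in
#' selection but the p-value is two-sided). Zero-variance genes are
#' excluded with a message; samples missing RIFA are dropped pairwise.
#'
#' @param se SummarizedExperiment with RIFA in \code{colData(se)$rifa}, or
#'   a matrix (then supply \code{rifa}).
#' @param rifa per-sample RIFA vector (needed for matrix input).
#' @param pThreshold selection threshold (default 0.05).
#' @return data.frame with \code{gene_id}, \code{pearson_r},
#'   \code{p_value}, \code{selected}, sorted by decreasing r.
#' @export
correlateWithRifa <- function(se, rifa = NULL, pThreshold = 0.05) {
    if (is(se, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(se, "intensities")
        if (is.null(rifa)) rifa <- SummarizedExperiment::colData(se)$rifa
    } else m <- as.matrix(se)
    if (is.null(rifa)) stop("no RIFA vector available")
    ok <- !is.na(rifa)
    if (!all(ok)) {
        message(sum(!ok), " sample(s) dropped: missing RIFA")
        m <- m[, ok, drop = FALSE]; rifa <- rifa[ok]
    }
    n <- length(rifa)
    if (n < 3L) stop("need >= 3 samples with both expression and RIFA")
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
        message(sum(sds == 0), " zero-variance gene(s) excluded from the ",
            "correlation screen")
    m <- m[sds > 0, , drop = FALSE]
    r <- as.numeric(stats::cor(t(m), rifa))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    out <- data.frame(
        gene_id = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
            else rownames(m),
        pearson_r = r, p_value = p,
        selected = r > 0 & p < pThreshold, stringsAsFactors = FALSE)
    out[order(-out$pearson_r), , drop = FALSE]
}

#' Simple linear regression with r-squared
#'
#' Ordinary least squares of y on x, as used for RIFA versus unstimulated
#' whole saliva flow. r_squared equals the square of the Pearson
#' correlation of x and y.
#'
#' @param x,y numeric vectors, >= 3 points, var(x) > 0.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (two-sided t-test on the slope).
#' @export
linearRegressionFit <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (stats::var(x) == 0) stop("constant x: regression is undefined")
    fit <- stats::lm(y ~ x)
    # a perfect fit is a legitimate input here (noiseless worked examples)
    sm <- suppressWarnings(summary(fit))
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L])
}
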