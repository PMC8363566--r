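# RIFA quantification: annotation (vector) path, automated segmentation
# (raster) path, and the shared score arithmetic.
#
# RIFA = total interstitial fibrosis area / total gland area, where the
# fibrosis area is the green-outlined area minus enclosed non-fibrotic
# ("yellow") areas; enclosed non-fibrotic objects smaller than 50 um^2 are
# kept as fibrosis (not subtracted). The boundary case of exactly 50 um^2 is
# subtracted (the subtraction rule is "area >= minIslandUm2").

#' RIFA from polygon annotations
#'
#' Computes the relative interstitial fibrosis area from pathologist-style
#' outlines: fibrosis area = sum of green polygon areas minus the areas of
#' yellow (enclosed non-fibrotic) polygons at or above the minimum island
#' size; RIFA = fibrosis area / gland area. Yellow polygons below
#' \code{minIslandUm2} are deliberately not subtracted.
#'
#' @param ann an [AnnotationSet-class].
#' @param minIslandUm2 minimum area (um^2) for a non-fibrotic region to be
#'   subtracted; default 50.
#' @param strictContainment if TRUE, yellow polygons not contained in any
#'   green polygon are ignored (with a warning); if FALSE (default) they are
#'   still subtracted but a warning is emitted.
#' @return a [RifaResult-class].
#' @examples
#' gland <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' green <- cbind(c(0, 1000, 1000, 0), c(0, 0, 500, 500))
#' yellow <- cbind(c(100, 300, 300, 100), c(100, 100, 1100, 1100)) / sqrt(5)
#' @export
rifaFromAnnotations <- function(ann, minIslandUm2 = 50,
                                strictContainment = FALSE) {
    stopifnot(is(ann, "AnnotationSet"))
    validObject(ann)
    umpp <- ann@umPerPx
    glandMm2 <- sum(vapply(ann@gland, polygonArea, numeric(1),
        umPerPx = umpp))
    if (glandMm2 <= 0)
        stop("total gland area is zero; RIFA is undefined")
    greenMm2 <- sum(vapply(ann@green, polygonArea, numeric(1),
        umPerPx = umpp))
    subtractedMm2 <- 0
    for (y in ann@yellow) {
        contained <- any(vapply(ann@green, function(g)
            polygonContained(y, g), logical(1)))
        if (!contained) {
            warning("a yellow polygon is not contained in any green polygon",
                if (strictContainment) "; ignored (strict containment)"
                else "; subtracted anyway")
            if (strictContainment) next
        }
        aUm2 <- polygonAreaUm2(y, umpp)
        if (aUm2 >= minIslandUm2)
            subtractedMm2 <- subtractedMm2 + aUm2 * 1e-6
    }
    fibrosisMm2 <- greenMm2 - subtractedMm2
    if (fibrosisMm2 > glandMm2 * (1 + 1e-9))
        stop("fibrosis area exceeds gland area; check the annotation layers")
    RifaResult(fibrosisArea = fibrosisMm2, glandArea = glandMm2,
        subtractedArea = subtractedMm2)
}

#' Default Masson-trichrome stain optical-density vectors
#'
#' Published optical-density triplets for the collagen stain (aniline/methyl
#' blue) and the cytoplasm counterstain (Biebrich scarlet-acid fuchsin),
#' unit-normalised; columns are stains, rows R, G, B.
#'
#' @return a 3 x 2 matrix with columns \code{collagen}, \code{cytoplasm}.
#' @export
massonStainVectors <- function() {
    v <- cbind(
        collagen = c(0.09997159, 0.73738605, 0.66803260),
        cytoplasm = c(0.79951070, 0.59135210, 0.10528667))
    rownames(v) <- c("R", "G", "B")
    sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Colour deconvolution of a trichrome image
#'
#' Converts an RGB image to optical densities (Beer-Lambert,
#' OD = -log10(I / I0) with I0 = 1 for intensities in [0, 1]) and solves the
#' least-squares stain mixture OD = V C for the per-pixel stain
#' concentrations C given unit-norm stain vectors V.
#'
#' @param image numeric array H x W x 3 with values in [0, 1] (8- or 16-bit
#'   images should be scaled by their maximum representable value first).
#' @param stainVectors 3 x 2 matrix of unit-norm stain OD vectors;
#'   default [massonStainVectors()].
#' @return list with \code{channels} (H x W x 2 array, clipped at 0, named
#'   by stain), \code{residualRms} (root-mean-square OD reconstruction
#'   error), and \code{stainVectors}.
#' @export
deconvolveStains <- function(image, stainVectors = massonStainVectors()) {
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
        stop("'image' must be an H x W x 3 RGB array")
    if (max(image) > 1 + 1e-6 || min(image) < 0)
        stop("'image' values must lie in [0, 1]")
    V <- as.matrix(stainVectors)
    if (ncol(V) != 2L || nrow(V) != 3L)
        stop("'stainVectors' must be a 3 x 2 matrix")
    if (abs(det(crossprod(V))) < 1e-8)
        stop("stain vectors are collinear; the stain matrix is singular")
    d <- dim(image)
    od <- -log10(pmax(image, 1e-6))
    odm <- matrix(od, ncol = 3L)             # pixels x 3
    conc <- odm %*% V %*% solve(crossprod(V))  # least squares, pixels x 2
    recon <- conc %*% t(V)
    residualRms <- sqrt(mean((odm - recon)^2))
    conc[conc < 0] <- 0
    channels <- array(conc, dim = c(d[1], d[2], 2L))
    dimnames(channels) <- list(NULL, NULL, colnames(V))
    list(channels = channels, residualRms = residualRms, stainVectors = V)
}

#' Segment the gland (tissue) region of a slide image
#'
#' Tissue-versus-background segmentation by luminance threshold (slide
#' background is near-white) followed by hole filling, so that unstained
#' lumina inside the gland outline count as gland tissue.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param luminanceThreshold pixels with luminance below this are tissue;
#'   default 0.92.
#' @param fillHoles fill enclosed background holes; default TRUE.
#' @return logical gland mask (H x W).
#' @export
segmentGland <- function(image, luminanceThreshold = 0.92, fillHoles = TRUE) {
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
        stop("'image' must be an H x W x 3 RGB array")
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    mask <- lum < luminanceThreshold
    if (fillHoles && any(mask))
        mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
    m <- matrix(as.logical(mask), nrow = dim(image)[1])
    m
}

#' Segment fibrosis from deconvolved stain channels
#'
#' Thresholds the collagen optical-density channel within the gland mask;
#' the default threshold is Otsu's method computed on the in-gland collagen
#' values, with a small OD floor so that unstained tiles yield an empty mask.
#' An optional morphological opening removes speckle.
#'
#' @param channels H x W x 2 array from [deconvolveStains()] (collagen
#'   first).
#' @param glandMask logical H x W gland mask; must be non-empty.
#' @param umPerPx micrometres per pixel, carried into the result.
#' @param threshold explicit OD threshold; \code{NULL} (default) uses Otsu.
#'   \code{Inf} gives an empty mask, \code{-Inf} the whole gland.
#' @param openingRadius radius (px) of a disc opening applied to the mask;
#'   0 (default) disables it.
#' @param minOD optical-density floor: pixels below it are never fibrosis
#'   and Otsu is skipped when the in-gland collagen signal never exceeds it.
#' @return a [SegmentationMask-class] with \code{paramsUsed} recording the
#'   effective threshold and options.
#' @export
segmentFibrosis <- function(channels, glandMask, umPerPx,
                            threshold = NULL, openingRadius = 0,
                            minOD = 0.05) {
    if (!any(glandMask))
        stop("gland mask is empty; cannot segment fibrosis")
    collagen <- channels[, , 1]
    method <- if (is.null(threshold)) "otsu" else "fixed"
    if (is.null(threshold)) {
        vals <- collagen[glandMask]
        if (max(vals) <= minOD) {
            threshold <- Inf        # no collagen signal anywhere
        } else {
            r <- range(vals)
            scaled <- (vals - r[1]) / diff(r)
            th <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1)),
                range = c(0, 1))
            threshold <- r[1] + th * diff(r)
        }
    }
    mask <- collagen > threshold & collagen >= minOD & glandMask
    if (openingRadius > 0 && any(mask)) {
        brush <- EBImage::makeBrush(2L * as.integer(openingRadius) + 1L,
            shape = "disc")
        mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
        mask <- matrix(as.logical(mask), nrow = nrow(glandMask)) & glandMask
    }
    SegmentationMask(
        fibrosis = matrix(as.logical(mask), nrow = nrow(glandMask)),
        gland = glandMask, umPerPx = umPerPx,
        paramsUsed = list(threshold = threshold,
            openingRadius = openingRadius, minOD = minOD, method = method))
}

# Connected components of the non-fibrotic tissue inside the gland, with an
# enclosure call: a component is "enclosed" when every pixel adjacent to it
# (4-neighbourhood) that is not part of the component is fibrosis -- i.e. the
# component is an island inside the fibrotic area. Components touching the
# image border or non-gland pixels are exterior stroma and never subtracted.
enclosedNonFibroticComponents <- function(fibrosis, gland) {
    inner <- gland & !fibrosis
    if (!any(inner))
        return(list(labels = matrix(0L, nrow(fibrosis), ncol(fibrosis)),
            enclosed = integer(0), areasPx = integer(0)))
    lab <- EBImage::bwlabel(EBImage::Image(inner * 1))
    lab <- matrix(as.integer(lab), nrow = nrow(fibrosis))
    nlab <- max(lab)
    nr <- nrow(lab); nc <- ncol(lab)
    # classify every pixel: 0 = same/other island, 1 = fibrosis, 2 = exterior
    cls <- matrix(2L, nr, nc)
    cls[gland & !fibrosis] <- 0L
    cls[fibrosis] <- 1L
    bad <- rep(FALSE, nlab)   # touches exterior (incl. image border)
    shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
    for (s in shifts) {
        di <- s[1]; dj <- s[2]
        iSrc <- seq_len(nr); jSrc <- seq_len(nc)
        iDst <- iSrc + di; jDst <- jSrc + dj
        okI <- iDst >= 1L & iDst <= nr
        okJ <- jDst >= 1L & jDst <= nc
        # pixels whose neighbour falls off the image: exterior contact
        edgeLabs <- unique(c(lab[!okI, , drop = FALSE],
            lab[, !okJ, drop = FALSE]))
        bad[edgeLabs[edgeLabs > 0L]] <- TRUE
        subLab <- lab[iSrc[okI], jSrc[okJ], drop = FALSE]
        nbCls <- cls[iDst[okI], jDst[okJ], drop = FALSE]
        nbLab <- lab[iDst[okI], jDst[okJ], drop = FALSE]
        sel <- subLab > 0L & (nbCls == 2L | (nbCls == 0L & nbLab != subLab))
        bad[unique(subLab[sel])] <- TRUE
    }
    enclosed <- which(!bad)
    areasPx <- tabulate(lab[lab > 0L], nbins = nlab)
    list(labels = lab, enclosed = enclosed, areasPx = areasPx)
}

#' RIFA from segmentation masks
#'
#' Raster analogue of [rifaFromAnnotations()]: non-fibrotic connected
#' components fully enclosed by fibrosis are the "yellow" areas. Enclosed
#' components with physical area >= \code{minIslandUm2} stay subtracted
#' (non-fibrotic); smaller enclosed components are merged into the fibrosis
#' area. RIFA = fibrosis pixels / gland pixels.
#'
#' @param seg a [SegmentationMask-class].
#' @param minIslandUm2 minimum island area in um^2 for subtraction
#'   (default 50).
#' @return a [RifaResult-class].
#' @export
rifaFromMasks <- function(seg, minIslandUm2 = 50) {
    stopifnot(is(seg, "SegmentationMask"))
    validObject(seg)
    glandPx <- sum(seg@gland)
    if (glandPx == 0L)
        stop("gland mask is empty; RIFA is undefined")
    umpp <- seg@umPerPx
    px2mm2 <- umpp^2 * 1e-6
    comp <- enclosedNonFibroticComponents(seg@fibrosis, seg@gland)
    minPx <- minIslandUm2 / umpp^2
    enclosedAreas <- comp$areasPx[comp$enclosed]
    keepSubtracted <- enclosedAreas >= minPx
    mergedPx <- sum(enclosedAreas[!keepSubtracted])
    subtractedPx <- sum(enclosedAreas[keepSubtracted])
    fibPx <- sum(seg@fibrosis) + mergedPx
    RifaResult(
        fibrosisArea = fibPx * px2mm2,
        glandArea = glandPx * px2mm2,
        subtractedArea = subtractedPx * px2mm2)
}

#' Automated RIFA from a trichrome image
#'
#' Convenience wrapper running the automated path end to end: gland
#' segmentation, stain deconvolution, fibrosis segmentation and the RIFA
#' arithmetic.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param umPerPx micrometres per pixel; required (no default is guessed).
#' @param minIslandUm2 minimum island size for subtraction (um^2).
#' @param stainVectors stain OD matrix; default [massonStainVectors()].
#' @param ... further arguments to [segmentFibrosis()].
#' @return a [RifaResult-class].
#' @export
rifaFromImage <- function(image, umPerPx, minIslandUm2 = 50,
                          stainVectors = massonStainVectors(), ...) {
    if (missing(umPerPx) || is.null(umPerPx) || is.na(umPerPx))
        stop("'umPerPx' is required: physical pixel size cannot be guessed")
    gland <- segmentGland(image)
    dec <- deconvolveStains(image, stainVectors)
    seg <- segmentFibrosis(dec$channels, gland, umPerPx, ...)
    rifaFromMasks(seg, minIslandUm2 = minIslandUm2)
}

#' Pairwise group comparison of RIFA scores
#'
#' Two-sided unpaired t-tests between every pair of groups, with group
#' mean +/- SEM, as used to compare microscopic categories (FLS, NSCS,
#' FLS/SCS, SCS).
#'
#' @param values numeric vector of RIFA scores (or any per-sample measure).
#' @param groups factor or character vector of group labels, same length.
#' @param varEqual pooled-variance t (default TRUE); FALSE for Welch.
#' @return list with \code{groups} (group, n, mean, sem) and \code{pairs}
#'   (groupA, groupB, t, df, p) data frames. Pairs where either group has
#'   fewer than 2 values are skipped with a warning.
#' @export
compareGroupsRifa <- function(values, groups, varEqual = TRUE) {
    stopifnot(length(values) == length(groups))
    groups <- as.character(groups)
    gl <- unique(groups)
    gstats <- data.frame(
        group = gl,
        n = vapply(gl, function(g) sum(groups == g), integer(1)),
        mean = vapply(gl, function(g) mean(values[groups == g]), numeric(1)),
        sem = vapply(gl, function(g) {
            v <- values[groups == g]
            stats::sd(v) / sqrt(length(v))
        }, numeric(1)),
        stringsAsFactors = FALSE)
    pairs <- utils::combn(gl, 2L)
    out <- list()
    for (k in seq_len(ncol(pairs))) {
        a <- values[groups == pairs[1, k]]
        b <- values[groups == pairs[2, k]]
        if (length(a) < 2L || length(b) < 2L) {
            warning(sprintf("pair %s vs %s skipped: fewer than 2 values",
                pairs[1, k], pairs[2, k]))
            next
        }
        tt <- twoSampleT(a, b, varEqual = varEqual)
        out[[length(out) + 1L]] <- data.frame(
            groupA = pairs[1, k], groupB = pairs[2, k],
            t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
    list(groups = gstats,
         pairs = if (length(out)) do.call(rbind, out)
                 else data.frame(groupA = character(0),
                     groupB = character(0), t = numeric(0),
                     df = numeric(0), p = numeric(0)))
}

# Two-sample two-sided t with graceful handling of degenerate (zero
# variance) inputs: equal means -> t = 0, p = 1; different means with no
# variance -> p = 0.
twoSampleT <- function(a, b, varEqual = TRUE) {
    na <- length(a); nb <- length(b)
    ma <- mean(a); mb <- mean(b)
    va <- stats::var(a); vb <- stats::var(b)
    if (varEqual) {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        se <- sqrt(sp2 * (1 / na + 1 / nb))
        df <- na + nb - 2
    } else {
        se <- sqrt(va / na + vb / nb)
        df <- (va / na + vb / nb)^2 /
            ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
        if (!is.finite(df)) df <- na + nb - 2
    }
    if (se == 0) {
        if (ma == mb) return(list(t = 0, df = df, p = 1))
        return(list(t = sign(ma - mb) * Inf, df = df, p = 0))
    }
    t <- (ma - mb) / se
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
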