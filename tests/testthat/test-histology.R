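# RIFA quantification: polygon geometry, the annotation path, stain
# deconvolution, segmentation, the raster path and group comparison.

test_that("polygonArea matches exact geometry and a Monte-Carlo oracle", {
    sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
    expect_equal(polygonArea(sq, umPerPx = 1), 1.0)
    tri <- cbind(c(0, 2, 0), c(0, 0, 2))
    expect_equal(polygonArea(tri, umPerPx = 1000), 2.0)
    # winding direction must not matter
    expect_equal(polygonArea(sq[4:1, ], umPerPx = 1),
        polygonArea(sq, umPerPx = 1))
    # random simple 20-gon (star-shaped construction) vs rejection sampling
    set.seed(42)
    ang <- sort(runif(20, 0, 2 * pi))
    rad <- runif(20, 50, 100)
    poly <- cbind(100 + rad * cos(ang), 100 + rad * sin(ang))
    aPkg <- polygonArea(poly, umPerPx = 1) * 1e6   # back to px^2
    aMc <- oracle_mc_polygon_area(poly, n = 4e5)
    expect_lt(abs(aPkg - aMc) / aMc, 0.005)
})

test_that("self-intersecting polygons are rejected with a diagnostic", {
    bow <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
    expect_false(isSimplePolygon(bow))
    expect_error(polygonArea(bow, 1), "self-intersecting")
})

test_that("rifaFromAnnotations implements the subtraction equation", {
    umpp <- 1
    gland <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
    green <- cbind(c(0, 1000, 1000, 0), c(0, 0, 500, 500))
    # 0.2 mm^2 yellow region inside the green band
    yellow <- cbind(c(50, 850, 850, 50), c(50, 50, 300, 300))
    ann <- AnnotationSet(green = list(green), yellow = list(yellow),
        gland = list(gland), umPerPx = umpp)
    res <- rifaFromAnnotations(ann)
    expect_equal(rifa(res), 0.3)
    expect_equal(fibrosisArea(res), 0.3)
    expect_equal(subtractedArea(res), 0.2)

    # below-threshold yellow region is kept as fibrosis
    tiny <- cbind(c(100, 100 + sqrt(40), 100 + sqrt(40), 100),
                  c(100, 100, 100 + sqrt(40), 100 + sqrt(40)))
    ann2 <- AnnotationSet(green = list(green), yellow = list(tiny),
        gland = list(gland), umPerPx = umpp)
    expect_equal(rifa(rifaFromAnnotations(ann2)), 0.5)

    # exactly 50 um^2 is subtracted
    at50 <- cbind(c(100, 110, 110, 100), c(100, 100, 105, 105))
    ann3 <- AnnotationSet(green = list(green), yellow = list(at50),
        gland = list(gland), umPerPx = umpp)
    expect_equal(rifa(rifaFromAnnotations(ann3)), 0.49995)

    # gland of zero area fails; non-contained yellow warns
    degenerate <- cbind(c(0, 1, 2), c(0, 0, 0))
    expect_error(rifaFromAnnotations(AnnotationSet(
        green = list(green), gland = list(degenerate), umPerPx = 1)))
    outside <- cbind(c(0, 300, 300, 0), c(600, 600, 900, 900))
    annW <- AnnotationSet(green = list(green), yellow = list(outside),
        gland = list(gland), umPerPx = umpp)
    expect_warning(rifaFromAnnotations(annW), "not contained")
})

test_that("stain deconvolution recovers pure stains and background", {
    V <- massonStainVectors()
    # pure collagen pixel at OD 1 along the collagen vector
    img <- array(0, dim = c(2, 2, 3))
    for (k in 1:3) img[1, 1, k] <- 10^(-V[k, 1])
    for (k in 1:3) img[1, 2, k] <- 10^(-V[k, 2])
    img[2, , ] <- 1   # white background
    dec <- deconvolveStains(img)
    expect_gt(dec$channels[1, 1, 1], 10 * dec$channels[1, 1, 2])
    expect_gt(dec$channels[1, 2, 2], 10 * dec$channels[1, 2, 1])
    expect_lt(max(dec$channels[2, , ]), 1e-4)
    # collinear stain matrix is singular
    Vbad <- cbind(V[, 1], V[, 1])
    expect_error(deconvolveStains(img, Vbad), "singular|collinear")
})

test_that("deconvolution concentrations correlate with generator truth", {
    sl <- simulateTrichromeImage(widthPx = 96, heightPx = 96,
        fibrosisFraction = 0.35, noiseSd = 0.005, seed = 5)
    dec <- deconvolveStains(sl$image)
    truthC <- sl$truth$concentrations$collagen
    sel <- sl$glandMask
    expect_gt(cor(dec$channels[, , 1][sel], truthC[sel]), 0.99)
})

test_that("fibrosis segmentation behaves at threshold limits", {
    sl <- simulateTrichromeImage(widthPx = 96, heightPx = 96,
        fibrosisFraction = 0.3, noiseSd = 0, seed = 2)
    dec <- deconvolveStains(sl$image)
    segHi <- segmentFibrosis(dec$channels, sl$glandMask, 1,
        threshold = Inf)
    expect_false(any(fibrosisMask(segHi)))
    segLo <- segmentFibrosis(dec$channels, sl$glandMask, 1,
        threshold = -Inf, minOD = 0)
    expect_true(all(fibrosisMask(segLo) == sl$glandMask))
    # noiseless synthetic image: near-perfect Dice against truth
    seg <- segmentFibrosis(dec$channels, sl$glandMask, 1)
    dice <- 2 * sum(fibrosisMask(seg) & sl$fibrosisMask) /
        (sum(fibrosisMask(seg)) + sum(sl$fibrosisMask))
    expect_gte(dice, 0.99)
    expect_error(segmentFibrosis(dec$channels,
        matrix(FALSE, 96, 96), 1), "empty")
})

test_that("gland segmentation separates tissue from background", {
    sl <- simulateTrichromeImage(widthPx = 96, heightPx = 96,
        fibrosisFraction = 0.3, noiseSd = 0.005, seed = 9)
    g <- segmentGland(sl$image)
    iou <- sum(g & sl$glandMask) / sum(g | sl$glandMask)
    expect_gte(iou, 0.98)
    white <- array(1, dim = c(8, 8, 3))
    expect_false(any(segmentGland(white)))
    tissue <- array(rep(c(0.8, 0.55, 0.6), each = 64), dim = c(8, 8, 3))
    expect_true(all(segmentGland(tissue)))
})

test_that("rifaFromMasks applies the island rule on rasters", {
    # fibrosis == gland, no holes
    g <- make_rect_mask(60, 60, 10, 50, 10, 50)
    seg <- SegmentationMask(g, g, umPerPx = 1)
    expect_equal(rifa(rifaFromMasks(seg)), 1)

    # 100 um^2 enclosed hole at 1 um/px is subtracted
    fib <- g
    fib[30:39, 30:39] <- FALSE   # 100 px hole
    seg2 <- SegmentationMask(fib, g, umPerPx = 1)
    res2 <- rifaFromMasks(seg2)
    expect_equal(rifa(res2), (sum(g) - 100) / sum(g))
    expect_equal(subtractedArea(res2), 100 * 1e-6)

    # a 40 px hole is merged back into fibrosis
    fib3 <- g
    fib3[30:34, 30:37] <- FALSE   # 40 px
    res3 <- rifaFromMasks(SegmentationMask(fib3, g, umPerPx = 1))
    expect_equal(rifa(res3), 1)

    # exactly 50 px at 1 um/px is subtracted (boundary case)
    fib4 <- g
    fib4[30:34, 30:39] <- FALSE   # 50 px
    res4 <- rifaFromMasks(SegmentationMask(fib4, g, umPerPx = 1))
    expect_equal(rifa(res4), (sum(g) - 50) / sum(g))

    # holes touching the gland border are exterior stroma, never subtracted
    fib5 <- g
    fib5[10:15, 10:15] <- FALSE
    res5 <- rifaFromMasks(SegmentationMask(fib5, g, umPerPx = 1))
    expect_equal(fibrosisArea(res5), sum(fib5) * 1e-6)

    expect_error(rifaFromMasks(SegmentationMask(
        matrix(FALSE, 4, 4), matrix(FALSE, 4, 4), 1)), "empty")
})

test_that("raster and vector paths agree on the worked rectangle example", {
    nr <- nc <- 1000
    gland <- make_rect_mask(nr, nc, 1, 1000, 1, 1000)
    green <- make_rect_mask(nr, nc, 1, 500, 1, 1000)
    yellow <- make_rect_mask(nr, nc, 51, 300, 51, 850)  # 0.2 mm^2
    fib <- green & !yellow
    res <- rifaFromMasks(SegmentationMask(fib, gland, umPerPx = 1))
    expect_lt(abs(rifa(res) - 0.3), 0.005)
})

test_that("raster RIFA matches the brute-force flood-fill oracle", {
    sl <- simulateTrichromeImage(widthPx = 96, heightPx = 96,
        fibrosisFraction = 0.4, islandAreasUm2 = c(30, 70, 120),
        seed = 17)
    seg <- SegmentationMask(sl$fibrosisMask, sl$glandMask, sl$umPerPx)
    expect_equal(rifa(rifaFromMasks(seg)),
        oracle_rifa_from_masks(sl$fibrosisMask, sl$glandMask, minPx = 50))
    expect_equal(rifa(rifaFromMasks(seg)), sl$truth$rifa)
})

test_that("RIFA is bounded, monotone in fibrosis, and scale invariant", {
    sl <- simulateTrichromeImage(widthPx = 96, heightPx = 96,
        fibrosisFraction = 0.3, seed = 21)
    g <- sl$glandMask; f <- sl$fibrosisMask
    r1 <- rifa(rifaFromMasks(SegmentationMask(f, g, 1)))
    expect_gte(r1, 0); expect_lte(r1, 1)
    # grow fibrosis: rifa must not decrease
    fGrow <- f | (g & rbind(f[-1, ], FALSE))
    r2 <- rifa(rifaFromMasks(SegmentationMask(fGrow, g, 1)))
    expect_gte(r2, r1)
    # doubling resolution changes rifa by < 1%
    up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                        rep(seq_len(ncol(m)), each = 2)]
    r3 <- rifa(rifaFromMasks(SegmentationMask(up(f), up(g), 0.5)))
    expect_lt(abs(r3 - r1) / r1, 0.01)
})

test_that("group comparison reports t-tests and mean +/- SEM", {
    # identical groups: t = 0, p = 1
    cmp0 <- compareGroupsRifa(c(1, 2, 3, 1, 2, 3),
        rep(c("a", "b"), each = 3))
    expect_equal(cmp0$pairs$t, 0)
    expect_equal(cmp0$pairs$p, 1)
    # fully separated groups with tiny jitter
    set.seed(1)
    v <- c(rnorm(5, 0, 1e-4), rnorm(5, 1, 1e-4))
    cmpSep <- compareGroupsRifa(v, rep(c("lo", "hi"), each = 5))
    expect_lt(cmpSep$pairs$p, 1e-6)
    # hand-computed 3-value example against the textbook pooled formula
    a <- c(0.1, 0.2, 0.3); b <- c(0.5, 0.55, 0.7)
    cmp <- compareGroupsRifa(c(a, b), rep(c("A", "B"), each = 3))
    orc <- oracle_pooled_t(a, b)
    expect_equal(cmp$pairs$t, orc$t)
    expect_equal(cmp$pairs$p, orc$p)
    expect_equal(cmp$groups$sem[cmp$groups$group == "A"],
        sd(a) / sqrt(3))
    # singleton group pairs are skipped with a warning
    expect_warning(compareGroupsRifa(c(1, 2, 3), c("x", "x", "y")),
        "skipped")
})
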