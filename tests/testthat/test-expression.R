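# Expression statistics: quantile normalisation, flag filtering,
# differential expression, gene-set intersection and the RIFA screens.

test_that("quantile normalisation has its defining properties", {
    # hand-executed 2x2 example: sorted-row means are (2, 3)
    m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
    rownames(m) <- c("g1", "g2")
    norm <- quantileNormalize(m)
    expect_equal(unname(norm), cbind(c(2, 3), c(2, 3)))
    # identical columns are a fixed point
    m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
    expect_equal(quantileNormalize(m2), m2)
    # all columns share the same sorted vector; idempotent
    set.seed(2)
    m3 <- matrix(rlnorm(200), 20, 10)
    n3 <- quantileNormalize(m3)
    sorted <- apply(n3, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    expect_equal(quantileNormalize(n3), n3)
    # single sample is a no-op with warning
    expect_warning(quantileNormalize(m3[, 1, drop = FALSE]), "no-op")
})

test_that("flag filtering keeps genes detected in enough samples", {
    set.seed(3)
    n <- 20
    flags <- matrix(sample(c("P", "M", "A"), 50 * n, replace = TRUE,
        prob = c(0.3, 0.1, 0.6)), 50, n)
    flags[1, ] <- "A"                       # always absent: removed
    flags[2, ] <- c(rep("P", 4), rep("A", n - 4))  # exactly 4: retained
    m <- matrix(rlnorm(50 * n), 50, n,
        dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:n)))
    dimnames(flags) <- dimnames(m)
    se <- ExpressionExperiment(m, flags = flags)
    kept <- rownames(filterLowIntensity(se, minPM = 4))
    expect_false("g01" %in% kept)
    expect_true("g02" %in% kept)
    # recount oracle
    expect_setequal(kept,
        rownames(m)[rowSums(flags == "P" | flags == "M") >= 4])
    # default threshold generalises as ceiling(0.2 * n)
    expect_identical(rownames(filterLowIntensity(se)),
        rownames(filterLowIntensity(se, minPM = ceiling(0.2 * n))))
})

test_that("differential expression matches textbook arithmetic", {
    m <- rbind(g1 = c(4.0, 4.2, 3.8, 2.0, 2.1, 1.9),
               g2 = rep(3, 6))
    colnames(m) <- sprintf("s%d", 1:6)
    de <- differentialExpression(m, groupA = 1:3, groupB = 4:6)
    expect_equal(de$fold_change[de$gene_id == "g1"], 2.0)
    orc <- oracle_pooled_t(c(4.0, 4.2, 3.8), c(2.0, 2.1, 1.9))
    expect_equal(de$p_value[de$gene_id == "g1"], orc$p)
    # identical groups: fold change 1, p = 1
    expect_equal(de$fold_change[de$gene_id == "g2"], 1)
    expect_equal(de$p_value[de$gene_id == "g2"], 1)
    # antisymmetry: swapping groups inverts the fold change, p unchanged
    deSwap <- differentialExpression(m, groupA = 4:6, groupB = 1:3)
    expect_equal(de$fold_change * deSwap$fold_change, c(1, 1))
    expect_equal(de$p_value, deSwap$p_value)
    # zero group-B mean excludes the gene with a message
    m0 <- rbind(g1 = c(1, 2, 3, 0, 0, 0))
    expect_message(
        de0 <- differentialExpression(m0, 1:3, 4:6), "undefined")
    expect_equal(nrow(de0), 0)
    # Welch option agrees with t.test
    a <- c(4.1, 4.4, 3.6, 4.9); b <- c(2.2, 2.0, 2.6)
    deW <- differentialExpression(rbind(g = c(a, b)), 1:4, 5:7,
        varEqual = FALSE)
    expect_equal(deW$p_value, t.test(a, b)$p.value)
})

test_that("DE selection uses strict thresholds", {
    res <- data.frame(
        gene_id = c("at", "up", "dn", "ns"),
        fold_change = c(1.5, 2.0, 0.4, 3.0),
        p_value = c(0.01, 0.04, 0.01, 0.2),
        direction = c("up", "up", "down", "up"))
    expect_identical(selectDE(res, direction = "up"), "up")
    expect_identical(selectDE(res, direction = "down"), "dn")
    expect_setequal(selectDE(res, direction = "both"), c("up", "dn"))
    # brute-force recount on a random table
    set.seed(4)
    rr <- data.frame(gene_id = sprintf("g%03d", 1:200),
        fold_change = rlnorm(200, 0, 0.5), p_value = runif(200))
    expect_setequal(selectDE(rr, direction = "both"),
        rr$gene_id[(rr$fold_change > 1.5 | rr$fold_change < 1 / 1.5) &
            rr$p_value < 0.05])
})

test_that("gene-set intersection produces exact Venn regions", {
    v <- intersectGeneSets(list(x = c("A", "B", "C"), y = c("B", "C", "D")))
    expect_setequal(v$common, c("B", "C"))
    expect_equal(sum(v$regions$count), v$union_size)
    expect_length(intersectGeneSets(list(a = "A", b = "B"))$common, 0)
    # enumeration oracle on 3 random sets
    set.seed(5)
    sets <- lapply(1:3, function(i) sample(LETTERS, 12))
    names(sets) <- c("s1", "s2", "s3")
    v3 <- intersectGeneSets(sets)
    expect_setequal(v3$common, Reduce(intersect, sets))
    uni <- unique(unlist(sets))
    pat <- sapply(uni, function(g) paste(
        ifelse(sapply(sets, function(s) g %in% s), "1", "0"),
        collapse = ""))
    expect_equal(sort(v3$regions$count),
        sort(as.integer(table(pat))))
})

test_that("RIFA correlation screen is exact and positively one-sided", {
    rifaVec <- seq(0.05, 0.6, length.out = 12)
    m <- rbind(pos = 2 * rifaVec + 1,
               neg = -rifaVec + 2,
               flat = rep(1, 12))
    colnames(m) <- sprintf("s%02d", 1:12)
    expect_message(res <- correlateWithRifa(m, rifa = rifaVec),
        "zero-variance")
    expect_equal(res$pearson_r[res$gene_id == "pos"], 1)
    expect_true(res$selected[res$gene_id == "pos"])
    expect_equal(res$pearson_r[res$gene_id == "neg"], -1)
    expect_false(res$selected[res$gene_id == "neg"])
    expect_false("flat" %in% res$gene_id)
})

test_that("correlation p-values agree with a permutation null", {
    set.seed(6)
    n <- 20
    rifaVec <- runif(n, 0, 0.7)
    g <- 1.5 * rifaVec + rnorm(n, 0, 0.35)
    res <- correlateWithRifa(matrix(g, 1, n,
        dimnames = list("g", NULL)), rifa = rifaVec)
    rObs <- res$pearson_r
    nPerm <- 20000
    permR <- vapply(seq_len(nPerm), function(i)
        cor(g, sample(rifaVec)), numeric(1))
    pPerm <- mean(abs(permR) >= abs(rObs))
    expect_lt(abs(pPerm - res$p_value),
        0.005 + 3 * sqrt(pPerm * (1 - pPerm) / nPerm))
})

test_that("linear regression recovers exact and null relationships", {
    x <- seq(0, 1, length.out = 10)
    y <- -0.67 * x + 0.8
    fit <- linearRegressionFit(x, y)
    expect_equal(fit$slope, -0.67)
    expect_equal(fit$intercept, 0.8)
    expect_equal(fit$r_squared, 1)
    # r_squared equals the squared Pearson r from the screen machinery
    set.seed(7)
    y2 <- -0.5 * x + rnorm(10, 0, 0.2)
    fit2 <- linearRegressionFit(x, y2)
    expect_equal(fit2$r_squared, cor(x, y2)^2)
    # 5-point hand example against the normal equations
    xs <- c(1, 2, 3, 4, 5); ys <- c(2.1, 3.9, 6.2, 8.1, 9.8)
    fh <- linearRegressionFit(xs, ys)
    slopeHat <- sum((xs - mean(xs)) * (ys - mean(ys))) /
        sum((xs - mean(xs))^2)
    expect_equal(fh$slope, slopeHat)
    expect_equal(fh$intercept, mean(ys) - slopeHat * mean(xs))
    # independence: r^2 near 0 for pure noise at larger n
    set.seed(8)
    xl <- runif(500); yl <- rnorm(500)
    expect_lt(linearRegressionFit(xl, yl)$r_squared, 0.02)
    expect_error(linearRegressionFit(rep(1, 5), 1:5), "constant")
})

test_that("null data fire the screens at their nominal rates", {
    nSim <- 200
    posRate <- deRate <- numeric(nSim)
    for (s in seq_len(nSim)) {
        se <- simulateExpressionData(nGenes = 40, seed = 50000 + s)
        corr <- suppressMessages(correlateWithRifa(se))
        posRate[s] <- mean(corr$selected)
        cd <- SummarizedExperiment::colData(se)
        de <- suppressMessages(differentialExpression(se,
            which(cd$group == "SCS"), which(cd$group == "NSCS")))
        deRate[s] <- mean(de$p_value < 0.05)
    }
    # positive half of a two-sided 0.05 test
    expect_lt(abs(mean(posRate) - 0.025), 0.008)
    # t-test fires at ~5%; the joint FC & p rule can only be rarer
    expect_lt(abs(mean(deRate) - 0.05), 0.012)
})

test_that("the screen recovers planted genes at power-0.9 effect sizes", {
    planted <- sprintf("gene%03d", 1:16)
    rec <- vapply(1:15, function(s) {
        se <- simulateExpressionData(nGenes = 200,
            plantedCorrelated = data.frame(gene = planted, slope = 400,
                noise_sd = NA), seed = 60000 + s)
        corr <- suppressMessages(correlateWithRifa(se))
        sum(planted %in% corr$gene_id[corr$selected])
    }, numeric(1))
    expect_gte(mean(rec), 14)
    # the planted genes rank by |r| consistently with effect size:
    # stronger planted slopes beat weaker ones on average
    se <- simulateExpressionData(nGenes = 100,
        plantedCorrelated = data.frame(
            gene = c("gene001", "gene002"),
            slope = c(600, 150), noise_sd = c(60, 60)),
        seed = 99)
    corr <- suppressMessages(correlateWithRifa(se))
    expect_lt(match("gene001", corr$gene_id),
        match("gene002", corr$gene_id))
})
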