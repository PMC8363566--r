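# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: naive per-base arrays, flood fill,
# textbook formulas.

# Pooled two-sample t-test, textbook arithmetic.
oracle_pooled_t <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# Naive per-base depth array from read intervals (1-based closed).
oracle_depth_array <- function(starts, ends, L) {
    d <- integer(L)
    for (k in seq_along(starts)) {
        idx <- starts[k]:ends[k]
        d[idx] <- d[idx] + 1L
    }
    d
}

# Boolean-array union length of 1-based closed intervals.
oracle_union_length <- function(starts, ends, L) {
    b <- logical(L)
    for (k in seq_along(starts)) b[starts[k]:ends[k]] <- TRUE
    sum(b)
}

# Exhaustive PWM window scoring of one sequence (one strand), naive loops.
oracle_scan_scores <- function(seqChar, pwmMat) {
    bases <- c("A", "C", "G", "T")
    s <- strsplit(seqChar, "")[[1]]
    L <- ncol(pwmMat)
    n <- length(s) - L + 1
    if (n < 1) return(numeric(0))
    sapply(seq_len(n), function(i) {
        sc <- 0
        for (j in seq_len(L)) {
            b <- match(s[i + j - 1], bases)
            if (!is.na(b)) sc <- sc + pwmMat[b, j]
        }
        sc
    })
}

oracle_revcomp <- function(seqChar) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(seqChar, "")[[1]]]), collapse = "")
}

# Flood-fill connected components (4-connectivity) of a logical matrix;
# returns an integer label matrix. Iterative stack, independent of EBImage.
oracle_label_components <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    for (start in which(mask & lab == 0L)) {
        if (lab[start] != 0L) next
        cur <- cur + 1L
        stack <- start
        while (length(stack)) {
            p <- stack[length(stack)]
            stack <- stack[-length(stack)]
            if (lab[p] != 0L) next
            lab[p] <- cur
            i <- (p - 1L) %% nr + 1L
            j <- (p - 1L) %/% nr + 1L
            for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
                ii <- i + d[1]; jj <- j + d[2]
                if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
                    q <- (jj - 1L) * nr + ii
                    if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
                }
            }
        }
    }
    lab
}

# Brute-force RIFA from truth masks: fibrosis px plus enclosed non-fibrotic
# components below the pixel threshold, over gland px. A component is
# enclosed when none of its pixels touches the image border or a
# non-gland/non-fibrosis exterior pixel.
oracle_rifa_from_masks <- function(fibrosis, gland, minPx) {
    nr <- nrow(fibrosis); nc <- ncol(fibrosis)
    inner <- gland & !fibrosis
    lab <- oracle_label_components(inner)
    fibPx <- sum(fibrosis)
    for (comp in seq_len(max(lab))) {
        px <- which(lab == comp)
        i <- (px - 1L) %% nr + 1L
        j <- (px - 1L) %/% nr + 1L
        enclosed <- TRUE
        for (k in seq_along(px)) {
            for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
                ii <- i[k] + d[1]; jj <- j[k] + d[2]
                if (ii < 1L || ii > nr || jj < 1L || jj > nc) {
                    enclosed <- FALSE; break
                }
                q <- (jj - 1L) * nr + ii
                if (!fibrosis[q] && lab[q] != comp) {
                    enclosed <- FALSE; break
                }
            }
            if (!enclosed) break
        }
        if (enclosed && length(px) < minPx) fibPx <- fibPx + length(px)
    }
    fibPx / sum(gland)
}

# Monte-Carlo polygon area by rejection sampling (pixel^2 units).
oracle_mc_polygon_area <- function(polygon, n = 2e5) {
    xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
    x <- runif(n, xr[1], xr[2]); y <- runif(n, yr[1], yr[2])
    frac <- mean(rifaquant::pointInPolygon(x, y, polygon))
    frac * diff(xr) * diff(yr)
}

# Build a small axis-aligned-rectangle mask scene used in several tests.
make_rect_mask <- function(nr, nc, i1, i2, j1, j2) {
    m <- matrix(FALSE, nr, nc)
    m[i1:i2, j1:j2] <- TRUE
    m
}
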