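# Polygon geometry helpers shared by the annotation-based RIFA path and the
# synthetic slide generator. Polygons are 2-column (x, y) matrices in pixel
# coordinates, open (no repeated closing vertex).

segmentsProperlyIntersect <- function(p1, p2, q1, q2) {
    orient <- function(a, b, c) {
        v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
        sign(v)
    }
    o1 <- orient(p1, p2, q1)
    o2 <- orient(p1, p2, q2)
    o3 <- orient(q1, q2, p1)
    o4 <- orient(q1, q2, p2)
    o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Pairwise proper-intersection test over non-adjacent edges; O(n^2), intended
#' for the modest vertex counts of pathology outlines.
#'
#' @param polygon 2-column (x, y) matrix of vertices.
#' @return TRUE if no two non-adjacent edges properly cross.
#' @export
isSimplePolygon <- function(polygon) {
    n <- nrow(polygon)
    if (n < 3L) return(FALSE)
    idx <- c(seq_len(n), 1L)
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            # skip adjacent edges (they share a vertex)
            if (j == i + 1L || (i == 1L && j == n)) next
            if (segmentsProperlyIntersect(
                    polygon[idx[i], ], polygon[idx[i + 1L], ],
                    polygon[idx[j], ], polygon[idx[j + 1L], ]))
                return(FALSE)
        }
    }
    TRUE
}

#' Area of a simple polygon in mm^2
#'
#' Shoelace area in pixel^2, converted to mm^2 through the physical pixel
#' size: area_mm2 = area_px * umPerPx^2 * 1e-6. The result is independent of
#' vertex winding direction.
#'
#' @param polygon 2-column (x, y) matrix of >= 3 vertices, simple.
#' @param umPerPx micrometres per pixel (> 0).
#' @return area in mm^2.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' polygonArea(sq, umPerPx = 1)  # 1 mm^2
#' @export
polygonArea <- function(polygon, umPerPx) {
    polygonAreaUm2(polygon, umPerPx) * 1e-6
}

# Area in um^2 (kept exact for the island-size comparison: no mm^2 detour).
polygonAreaUm2 <- function(polygon, umPerPx) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L)
        stop("polygon must have at least 3 vertices")
    if (!is.numeric(umPerPx) || length(umPerPx) != 1L || umPerPx <= 0)
        stop("'umPerPx' must be a single positive number")
    if (!isSimplePolygon(polygon))
        stop("polygon is self-intersecting; areas of non-simple polygons ",
             "are ill-defined")
    x <- polygon[, 1]
    y <- polygon[, 2]
    xn <- c(x[-1], x[1])
    yn <- c(y[-1], y[1])
    areaPx <- abs(sum(x * yn - xn * y)) / 2
    areaPx * umPerPx^2
}

#' Point-in-polygon test (ray casting)
#'
#' @param x,y coordinates of query points.
#' @param polygon 2-column (x, y) matrix.
#' @return logical vector; points on an edge may fall on either side.
#' @export
pointInPolygon <- function(x, y, polygon) {
    px <- polygon[, 1]
    py <- polygon[, 2]
    n <- length(px)
    inside <- rep(FALSE, length(x))
    j <- n
    for (i in seq_len(n)) {
        crosses <- ((py[i] > y) != (py[j] > y)) &
            (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
        inside <- xor(inside, crosses)
        j <- i
    }
    inside
}

polygonContained <- function(inner, outer) {
    all(pointInPolygon(inner[, 1], inner[, 2], outer))
}

# Rasterize a polygon onto an nrow x ncol pixel grid by testing pixel
# centres; pixel (i, j) covers centre (j - 0.5, i - 0.5) with x along
# columns and y along rows.
rasterizePolygon <- function(polygon, nrowPx, ncolPx) {
    xs <- seq_len(ncolPx) - 0.5
    ys <- seq_len(nrowPx) - 0.5
    grid <- expand.grid(y = ys, x = xs)
    m <- matrix(pointInPolygon(grid$x, grid$y, polygon), nrow = nrowPx)
    m
}
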