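#' @import methods
NULL

#' RifaResult: a relative interstitial fibrosis area measurement
#'
#' Holds the components of a RIFA measurement for one section: the total
#' interstitial fibrosis area (green outlines minus subtractable enclosed
#' non-fibrotic areas), the total gland area, the area that was subtracted
#' under the 50 um^2 rule, and the resulting dimensionless score.
#'
#' @slot fibrosisArea numeric, fibrosis area in mm^2 (after subtraction).
#' @slot glandArea numeric, total gland area in mm^2.
#' @slot subtractedArea numeric, enclosed non-fibrotic area in mm^2 that was
#'   subtracted (only components at or above the minimum island size).
#' @slot rifa numeric in [0, 1], \code{fibrosisArea / glandArea}.
#'
#' @seealso [rifaFromAnnotations()], [rifaFromMasks()]
#' @export
setClass("RifaResult",
    representation(
        fibrosisArea = "numeric",
        glandArea = "numeric",
        subtractedArea = "numeric",
        rifa = "numeric"
    )
)

setValidity("RifaResult", function(object) {
    msg <- NULL
    if (length(object@rifa) != 1L || is.na(object@rifa))
        msg <- c(msg, "'rifa' must be a single non-missing number")
    else {
        if (object@rifa < -1e-9 || object@rifa > 1 + 1e-9)
            msg <- c(msg, "'rifa' must lie in [0, 1]")
        if (object@glandArea <= 0)
            msg <- c(msg, "'glandArea' must be > 0")
        if (object@fibrosisArea > object@glandArea * (1 + 1e-9))
            msg <- c(msg, "'fibrosisArea' cannot exceed 'glandArea'")
        if (abs(object@rifa - object@fibrosisArea / object@glandArea) > 1e-8)
            msg <- c(msg, "'rifa' must equal fibrosisArea / glandArea")
    }
    if (is.null(msg)) TRUE else msg
})

RifaResult <- function(fibrosisArea, glandArea, subtractedArea = 0) {
    new("RifaResult",
        fibrosisArea = fibrosisArea, glandArea = glandArea,
        subtractedArea = subtractedArea,
        rifa = fibrosisArea / glandArea)
}

#' @describeIn RifaResult-class the RIFA score (dimensionless fraction)
#' @param object a \code{RifaResult}
#' @export
setGeneric("rifa", function(object) standardGeneric("rifa"))

#' @export
setMethod("rifa", "RifaResult", function(object) object@rifa)

#' @describeIn RifaResult-class fibrosis area in mm^2
#' @export
setGeneric("fibrosisArea", function(object) standardGeneric("fibrosisArea"))

#' @export
setMethod("fibrosisArea", "RifaResult", function(object) object@fibrosisArea)

#' @describeIn RifaResult-class total gland area in mm^2
#' @export
setGeneric("glandArea", function(object) standardGeneric("glandArea"))

#' @export
setMethod("glandArea", "RifaResult", function(object) object@glandArea)

#' @describeIn RifaResult-class subtracted enclosed non-fibrotic area in mm^2
#' @export
setGeneric("subtractedArea", function(object) standardGeneric("subtractedArea"))

#' @export
setMethod("subtractedArea", "RifaResult", function(object) object@subtractedArea)

setMethod("show", "RifaResult", function(object) {
    cat("RifaResult\n")
    cat(sprintf("  fibrosis area : %.5f mm^2\n", object@fibrosisArea))
    cat(sprintf("  gland area    : %.5f mm^2\n", object@glandArea))
    cat(sprintf("  subtracted    : %.5f mm^2\n", object@subtractedArea))
    cat(sprintf("  RIFA          : %.4f\n", object@rifa))
})

#' AnnotationSet: pathologist-style polygon outlines of a stained section
#'
#' Vector annotations of a trichrome-stained section: fibrosis outlines
#' ("green"), enclosed non-fibrotic outlines ("yellow") and total gland
#' outlines, all as polygons in pixel coordinates, with the physical pixel
#' size. Polygons are two-column numeric matrices (x, y), one row per vertex,
#' without a repeated closing vertex.
#'
#' @slot green list of fibrosis polygons.
#' @slot yellow list of enclosed non-fibrotic polygons.
#' @slot gland list of gland-outline polygons.
#' @slot umPerPx physical pixel size in micrometres per pixel (> 0).
#'
#' @seealso [rifaFromAnnotations()], [readAnnotationGeoJSON()]
#' @export
setClass("AnnotationSet",
    representation(
        green = "list",
        yellow = "list",
        gland = "list",
        umPerPx = "numeric"
    )
)

setValidity("AnnotationSet", function(object) {
    msg <- NULL
    if (length(object@umPerPx) != 1L || is.na(object@umPerPx) ||
        object@umPerPx <= 0)
        msg <- c(msg, "'umPerPx' must be a single positive number")
    for (layer in c("green", "yellow", "gland")) {
        polys <- slot(object, layer)
        for (p in polys) {
            if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
                msg <- c(msg, sprintf(
                    "layer '%s': polygons must be >=3-row, 2-column matrices",
                    layer))
                break
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an AnnotationSet
#'
#' @param green,yellow,gland lists of polygons (2-column x/y matrices in
#'   pixel coordinates).
#' @param umPerPx micrometres per pixel.
#' @return an [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(green = list(), yellow = list(), gland = list(),
                          umPerPx) {
    asMat <- function(p) {
        p <- as.matrix(p)
        storage.mode(p) <- "double"
        dimnames(p) <- NULL
        p
    }
    new("AnnotationSet",
        green = lapply(green, asMat), yellow = lapply(yellow, asMat),
        gland = lapply(gland, asMat), umPerPx = umPerPx)
}

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet\n")
    cat(sprintf("  gland outlines : %d\n", length(object@gland)))
    cat(sprintf("  green (fibrosis) : %d\n", length(object@green)))
    cat(sprintf("  yellow (non-fibrotic) : %d\n", length(object@yellow)))
    cat(sprintf("  resolution : %.4g um/px\n", object@umPerPx))
})

#' SegmentationMask: raster fibrosis and gland masks for one section
#'
#' Binary rasters aligned to the source image: a fibrosis mask and a gland
#' (tissue) mask, the physical pixel size, and a record of the parameters
#' that produced them.
#'
#' @slot fibrosis logical matrix, TRUE where collagen/fibrosis was called.
#' @slot gland logical matrix, TRUE inside the gland outline.
#' @slot umPerPx micrometres per pixel.
#' @slot paramsUsed list recording thresholds and options for provenance.
#'
#' @seealso [segmentFibrosis()], [rifaFromMasks()]
#' @export
setClass("SegmentationMask",
    representation(
        fibrosis = "matrix",
        gland = "matrix",
        umPerPx = "numeric",
        paramsUsed = "list"
    )
)

setValidity("SegmentationMask", function(object) {
    msg <- NULL
    if (!identical(dim(object@fibrosis), dim(object@gland)))
        msg <- c(msg, "'fibrosis' and 'gland' must have identical dimensions")
    if (!is.logical(object@fibrosis) || !is.logical(object@gland))
        msg <- c(msg, "masks must be logical matrices")
    else if (any(object@fibrosis & !object@gland))
        msg <- c(msg, "'fibrosis' must be contained in 'gland'")
    if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
        msg <- c(msg, "'umPerPx' must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SegmentationMask
#'
#' @param fibrosis,gland logical matrices of identical dimension; fibrosis
#'   must be contained in gland.
#' @param umPerPx micrometres per pixel.
#' @param paramsUsed list of segmentation parameters, for provenance.
#' @return a [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(fibrosis, gland, umPerPx, paramsUsed = list()) {
    new("SegmentationMask", fibrosis = fibrosis, gland = gland,
        umPerPx = umPerPx, paramsUsed = paramsUsed)
}

#' @describeIn SegmentationMask-class the fibrosis mask
#' @param object a \code{SegmentationMask}
#' @export
setGeneric("fibrosisMask", function(object) standardGeneric("fibrosisMask"))

#' @export
setMethod("fibrosisMask", "SegmentationMask", function(object) object@fibrosis)

#' @describeIn SegmentationMask-class the gland mask
#' @export
setGeneric("glandMask", function(object) standardGeneric("glandMask"))

#' @export
setMethod("glandMask", "SegmentationMask", function(object) object@gland)

#' @describeIn SegmentationMask-class micrometres per pixel
#' @export
setGeneric("umPerPx", function(object) standardGeneric("umPerPx"))

#' @export
setMethod("umPerPx", "SegmentationMask", function(object) object@umPerPx)

#' @export
setMethod("umPerPx", "AnnotationSet", function(object) object@umPerPx)

setMethod("show", "SegmentationMask", function(object) {
    d <- dim(object@fibrosis)
    cat("SegmentationMask\n")
    cat(sprintf("  dimensions : %d x %d px at %.4g um/px\n",
        d[1], d[2], object@umPerPx))
    cat(sprintf("  gland px   : %d\n", sum(object@gland)))
    cat(sprintf("  fibrosis px: %d\n", sum(object@fibrosis)))
})

#' MotifModel: a transcription-factor binding motif as PFM and PWM
#'
#' A position frequency matrix (base counts or probabilities per motif
#' column) together with its log-odds position weight matrix under a
#' background base composition, as used for promoter scanning.
#'
#' @slot tfName transcription factor name.
#' @slot pfm 4 x L numeric matrix, rows A, C, G, T.
#' @slot pwm 4 x L log2-odds matrix derived from the PFM.
#' @slot pseudocount pseudocount used in the log-odds transform.
#' @slot background named numeric(4) of base probabilities summing to 1.
#'
#' @seealso [pfmToPwm()], [scanPromoters()]
#' @export
setClass("MotifModel",
    representation(
        tfName = "character",
        pfm = "matrix",
        pwm = "matrix",
        pseudocount = "numeric",
        background = "numeric"
    )
)

setValidity("MotifModel", function(object) {
    msg <- NULL
    if (nrow(object@pfm) != 4L || nrow(object@pwm) != 4L)
        msg <- c(msg, "'pfm' and 'pwm' must have 4 rows (A, C, G, T)")
    if (any(object@pfm < 0))
        msg <- c(msg, "'pfm' must be non-negative")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "'background' must be 4 probabilities summing to 1")
    if (any(!is.finite(object@pwm)))
        msg <- c(msg, "'pwm' must be finite (is the pseudocount positive?)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MotifModel-class transcription factor name
#' @param object a \code{MotifModel}
#' @export
setGeneric("tfName", function(object) standardGeneric("tfName"))

#' @export
setMethod("tfName", "MotifModel", function(object) object@tfName)

#' @describeIn MotifModel-class the position frequency matrix
#' @export
setGeneric("pfm", function(object) standardGeneric("pfm"))

#' @export
setMethod("pfm", "MotifModel", function(object) object@pfm)

#' @describeIn MotifModel-class the log2-odds position weight matrix
#' @export
setGeneric("pwm", function(object) standardGeneric("pwm"))

#' @export
setMethod("pwm", "MotifModel", function(object) object@pwm)

setMethod("show", "MotifModel", function(object) {
    cat(sprintf("MotifModel '%s' (%d bp)\n", object@tfName,
        ncol(object@pfm)))
    cat("  consensus:", motifConsensus(object), "\n")
})
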