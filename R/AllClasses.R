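#' @import methods
#' @importFrom stats rnorm runif sd quantile integrate median
#' @importFrom utils head read.csv write.csv
#' @importFrom graphics hist
#' @importFrom grDevices chull
#' @useDynLib PanicleScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Calibrated scan image
#'
#' An 8-bit RGB raster together with the scanner resolution that produced it.
#' The physical scale is always derived from the resolution: a scan at
#' `dpi` dots per inch has `25.4 / dpi` millimetres per pixel, so a 600 dpi
#' panicle scan resolves 0.0423 mm per pixel.
#'
#' Pixel coordinates are 0-based with y pointing down; a pixel at `(x, y)`
#' covers the half-open unit square so that a box `[x0, x1) x [y0, y1)` has
#' area `(x1 - x0) * (y1 - y0)` pixels. Channel order is (R, G, B) regardless
#' of the file format the raster came from.
#'
#' @slot pixels integer array `H x W x 3`, values in 0..255.
#' @slot dpi scanner resolution in dots per inch (> 0). Stored per image so
#'   that mixed-resolution batches are legal.
#'
#' @seealso [ScanImage()], [mmPerPx()], [readScan()], [cropCenter()]
#' @export
setClass("ScanImage", slots = c(pixels = "array", dpi = "numeric"))

setValidity("ScanImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1L] < 1L || dim(p)[2L] < 1L)
    return("image must have H >= 1 and W >= 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in 0..255")
  if (any(p != round(p)))
    return("pixel values must be integers (8-bit per channel)")
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    return("dpi must be a single positive number")
  TRUE
})

#' Construct a ScanImage
#'
#' @param pixels `H x W x 3` numeric array of 8-bit values (0..255).
#' @param dpi scanner resolution in dots per inch.
#' @return A [ScanImage-class] object.
#' @examples
#' img <- ScanImage(array(0L, dim = c(4, 4, 3)), dpi = 600)
#' mmPerPx(img)
#' @export
ScanImage <- function(pixels, dpi) {
  storage.mode(pixels) <- "integer"
  new("ScanImage", pixels = pixels, dpi = as.numeric(dpi))
}

#' @describeIn ScanImage physical scale of the image in mm per pixel
#'   (`25.4 / dpi`).
#' @param x,object a `ScanImage`.
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname ScanImage-class
#' @export
setMethod("mmPerPx", "ScanImage", function(x) mmPerPixel(x@dpi))

#' @describeIn ScanImage raw 8-bit pixel array.
#' @export
setGeneric("scanPixels", function(x) standardGeneric("scanPixels"))

#' @rdname ScanImage-class
#' @export
setMethod("scanPixels", "ScanImage", function(x) x@pixels)

#' @describeIn ScanImage scanner resolution in dpi.
#' @export
setGeneric("scanDpi", function(x) standardGeneric("scanDpi"))

#' @rdname ScanImage-class
#' @export
setMethod("scanDpi", "ScanImage", function(x) x@dpi)

setMethod("show", "ScanImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ScanImage: %d x %d px, %g dpi (%.4f mm/px)\n",
              d[1L], d[2L], object@dpi, mmPerPx(object)))
})

#' @describeIn ScanImage image dimensions as c(H, W, 3).
#' @export
setMethod("dim", "ScanImage", function(x) dim(x@pixels))

#' Parametric grain silhouette model
#'
#' A single rice grain is modelled as a rotated superellipse
#' `|u/a|^n + |v/b|^n = 1` with semi-axes `a = length/2`, `b = width/2`.
#' The exponent `n` interpolates between an ellipse (`n = 2`) and a rounded
#' rectangle (`n -> Inf`); the default `n = 2.5` reproduces the intermediate
#' circularity of real grains (circularity about 0.5 at the 3:1 aspect ratio
#' typical of rice).
#'
#' @slot lengthMm grain length (major axis) in mm.
#' @slot widthMm grain width (minor axis) in mm; `lengthMm >= widthMm > 0`.
#' @slot orientation major-axis angle in radians (0 = x axis, y down).
#' @slot center grain centre in scene pixel coordinates, `c(x, y)`.
#' @slot shapeExponent superellipse exponent `n >= 2`.
#' @slot fillColor RGB fill triple in 0..255.
#' @slot textureSd Gaussian intensity noise added on top of the fill, in 8-bit
#'   intensity units.
#' @seealso [sampleGrain()], [renderGrain()], [generateScene()]
#' @export
setClass("GrainModel",
  slots = c(lengthMm = "numeric", widthMm = "numeric", orientation = "numeric",
            center = "numeric", shapeExponent = "numeric",
            fillColor = "numeric", textureSd = "numeric"))

setValidity("GrainModel", function(object) {
  if (object@widthMm <= 0) return("width must be > 0")
  if (object@lengthMm < object@widthMm) return("length must be >= width")
  if (object@shapeExponent < 2) return("shape exponent must be >= 2")
  if (length(object@fillColor) != 3L) return("fillColor must be an RGB triple")
  if (object@textureSd < 0) return("textureSd must be >= 0")
  TRUE
})

#' Construct a GrainModel
#'
#' @param lengthMm,widthMm grain axes in mm (`lengthMm >= widthMm > 0`).
#' @param orientation major-axis angle in radians.
#' @param center scene-coordinate centre `c(x, y)` in px.
#' @param shapeExponent superellipse exponent (>= 2).
#' @param fillColor RGB triple, 0..255.
#' @param textureSd intensity noise sd, 8-bit units.
#' @return A [GrainModel-class] object.
#' @export
GrainModel <- function(lengthMm, widthMm, orientation = 0,
                       center = c(0, 0), shapeExponent = 2.5,
                       fillColor = c(205, 175, 120), textureSd = 0) {
  new("GrainModel", lengthMm = as.numeric(lengthMm),
      widthMm = as.numeric(widthMm), orientation = as.numeric(orientation),
      center = as.numeric(center), shapeExponent = as.numeric(shapeExponent),
      fillColor = as.numeric(fillColor), textureSd = as.numeric(textureSd))
}

setMethod("show", "GrainModel", function(object) {
  cat(sprintf("GrainModel: %.2f x %.2f mm, n = %.2f, theta = %.2f rad\n",
              object@lengthMm, object@widthMm, object@shapeExponent,
              object@orientation))
})

#' Ground-truth annotation of a synthetic scene
#'
#' Exact per-grain truth for a generated panicle scene: bounding boxes of the
#' full (unoccluded) silhouettes, per-grain binary masks stored as cropped
#' rasters with offsets, analytic trait truth, and per-grain occlusion ratios
#' (1 - visible area / full area, occlusion by grains placed later, i.e.
#' drawn on top).
#'
#' @slot boxes numeric matrix `n x 4` of half-open corners (x0, y0, x1, y1).
#' @slot masks list of `n` entries, each `list(x0, y0, mask)` with `mask` a
#'   logical matrix (rows = y) of the full silhouette in a local crop.
#' @slot truths data.frame of `n` rows with the generating parameters and the
#'   analytic trait values (`length_mm`, `width_mm`, `area_mm2`,
#'   `perimeter_mm`, `lw_ratio`, ...).
#' @slot occlusion numeric vector of `n` occlusion ratios in `[0, 1]`.
#' @export
setClass("SceneAnnotation",
  slots = c(boxes = "matrix", masks = "list", truths = "data.frame",
            occlusion = "numeric"))

setValidity("SceneAnnotation", function(object) {
  n <- nrow(object@boxes)
  if (ncol(object@boxes) != 4L) return("boxes must have 4 columns")
  if (length(object@masks) != n || nrow(object@truths) != n ||
      length(object@occlusion) != n)
    return("boxes, masks, truths and occlusion must have equal length")
  if (n > 0 && (any(object@occlusion < 0) || any(object@occlusion > 1)))
    return("occlusion ratios must lie in [0, 1]")
  if (n > 0 && (any(object@boxes[, 3L] <= object@boxes[, 1L]) ||
                any(object@boxes[, 4L] <= object@boxes[, 2L])))
    return("boxes must satisfy x1 > x0 and y1 > y0")
  TRUE
})

setMethod("show", "SceneAnnotation", function(object) {
  cat(sprintf("SceneAnnotation: %d grains, occlusion %.3f (mean)\n",
              nrow(object@boxes),
              if (nrow(object@boxes)) mean(object@occlusion) else 0))
})

#' @describeIn SceneAnnotation number of annotated grains.
#' @param x a `SceneAnnotation`.
#' @export
setMethod("length", "SceneAnnotation", function(x) nrow(x@boxes))

#' @describeIn SceneAnnotation ground-truth boxes (half-open corners).
#' @export
setGeneric("sceneBoxes", function(x) standardGeneric("sceneBoxes"))

#' @rdname SceneAnnotation-class
#' @export
setMethod("sceneBoxes", "SceneAnnotation", function(x) x@boxes)

#' @describeIn SceneAnnotation true per-grain trait table.
#' @export
setGeneric("sceneTruths", function(x) standardGeneric("sceneTruths"))

#' @rdname SceneAnnotation-class
#' @export
setMethod("sceneTruths", "SceneAnnotation", function(x) x@truths)

#' @describeIn SceneAnnotation per-grain occlusion ratios.
#' @export
setGeneric("sceneOcclusion", function(x) standardGeneric("sceneOcclusion"))

#' @rdname SceneAnnotation-class
#' @export
setMethod("sceneOcclusion", "SceneAnnotation", function(x) x@occlusion)

#' @describeIn SceneAnnotation per-grain full-silhouette masks
#'   (`list(x0, y0, mask)` crops).
#' @export
setGeneric("sceneMasks", function(x) standardGeneric("sceneMasks"))

#' @rdname SceneAnnotation-class
#' @export
setMethod("sceneMasks", "SceneAnnotation", function(x) x@masks)

#' Paired occluded/clean restoration sample
#'
#' One training or evaluation sample for occlusion restoration: the clean
#' render of a grain, the same render with an occluder composited on top, the
#' realised occlusion ratio (fraction of the grain silhouette covered), and
#' the occluder footprint mask. A ratio of 0 means the two images are
#' pixel-identical.
#'
#' @slot occluded `S x S x 3` 8-bit array.
#' @slot clean `S x S x 3` 8-bit array, same grain and pose.
#' @slot ratio realised occlusion ratio in `[0, 1]`.
#' @slot occluderMask logical `S x S` matrix of the occluder footprint.
#' @seealso [makePair()], [restoreBaseline()]
#' @export
setClass("PairedSample",
  slots = c(occluded = "array", clean = "array", ratio = "numeric",
            occluderMask = "matrix"))

setValidity("PairedSample", function(object) {
  if (!identical(dim(object@occluded), dim(object@clean)))
    return("occluded and clean must have identical dimensions")
  if (object@ratio < 0 || object@ratio > 1)
    return("ratio must lie in [0, 1]")
  if (object@ratio == 0 && !identical(object@occluded, object@clean))
    return("ratio 0 requires occluded == clean")
  TRUE
})

setMethod("show", "PairedSample", function(object) {
  d <- dim(object@clean)
  cat(sprintf("PairedSample: %d x %d px, occlusion ratio %.3f\n",
              d[1L], d[2L], object@ratio))
})

#' @describeIn PairedSample realised occlusion ratio.
#' @param x a `PairedSample`.
#' @export
setGeneric("pairRatio", function(x) standardGeneric("pairRatio"))

#' @rdname PairedSample-class
#' @export
setMethod("pairRatio", "PairedSample", function(x) x@ratio)

#' @describeIn PairedSample clean (unoccluded) 8-bit render.
#' @export
setGeneric("cleanImage", function(x) standardGeneric("cleanImage"))

#' @rdname PairedSample-class
#' @export
setMethod("cleanImage", "PairedSample", function(x) x@clean)

#' @describeIn PairedSample occluded 8-bit render.
#' @export
setGeneric("occludedImage", function(x) standardGeneric("occludedImage"))

#' @rdname PairedSample-class
#' @export
setMethod("occludedImage", "PairedSample", function(x) x@occluded)

#' @describeIn PairedSample logical occluder footprint mask.
#' @export
setGeneric("occluderMask", function(x) standardGeneric("occluderMask"))

#' @rdname PairedSample-class
#' @export
setMethod("occluderMask", "PairedSample", function(x) x@occluderMask)
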