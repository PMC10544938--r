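#' Classical grain detector: Otsu + distance-transform watershed
#'
#' Deterministic detection of bright grains on the dark scan background:
#' the red channel is thresholded with Otsu's method and touching grains are
#' separated by a watershed of the Euclidean distance transform, with
#' regional maxima closer than `wsTolerance` in distance value merged into
#' one seed. The tolerance (default 1, the quantization scale of the
#' distance map) makes isolated convex blobs keep exactly one seed, so they
#' are never split. Box scores are the blob solidity (area / convex hull
#' area), a confidence in `[0, 1]`.
#'
#' @param image a [ScanImage-class] (or 8-bit H x W x 3 array).
#' @param minArea smallest blob area kept, px (suppresses noise specks).
#' @param wsTolerance watershed merge tolerance on distance values, px.
#' @param returnLabels also return the per-grain label matrix.
#' @return matrix with columns x0, y0, x1, y1, score (half-open pixel
#'   coordinates), one row per detected grain; with `returnLabels`,
#'   `list(boxes, labels)`. An image with empty foreground yields 0 rows.
#' @export
detectBaseline <- function(image, minArea = 25L, wsTolerance = 1,
                           returnLabels = FALSE) {
  pix <- if (is(image, "ScanImage")) image@pixels else image
  g <- redChannel(pix)
  emptyBoxes <- matrix(numeric(0), 0L, 5L,
                       dimnames = list(NULL,
                                       c("x0", "y0", "x1", "y1", "score")))
  thr <- tryCatch(otsuThreshold(g), degenerateImage = function(e) NULL)
  if (is.null(thr)) {
    if (returnLabels) return(list(boxes = emptyBoxes,
                                  labels = matrix(0L, nrow(g), ncol(g))))
    return(emptyBoxes)
  }
  mask <- g > thr
  if (!any(mask)) {
    if (returnLabels) return(list(boxes = emptyBoxes,
                                  labels = matrix(0L, nrow(g), ncol(g))))
    return(emptyBoxes)
  }
  dist <- EBImage::distmap(matToEB(mask))
  # inclusive merge: maxima whose depth difference equals the tolerance
  # (e.g. the 1 px quantization dips along a thin grain's ridge) still fuse
  ws <- ebToMat(EBImage::imageData(EBImage::watershed(
    dist, tolerance = wsTolerance + 1e-6)))
  out <- matrix(numeric(0), 0L, 5L)
  labels <- matrix(0L, nrow(g), ncol(g))
  nextId <- 0L
  for (p in seq_len(max(ws))) {
    pidx <- which(ws == p, arr.ind = TRUE)
    if (nrow(pidx) < minArea) next
    nextId <- nextId + 1L
    py <- pidx[, 1L]; px <- pidx[, 2L]      # 1-based matrix coordinates
    labels[pidx] <- nextId
    x0 <- min(px) - 1L; x1 <- max(px)       # 0-based half-open
    y0 <- min(py) - 1L; y1 <- max(py)
    out <- rbind(out, c(x0, y0, x1, y1, blobSolidity(px, py)))
  }
  colnames(out) <- c("x0", "y0", "x1", "y1", "score")
  if (returnLabels) list(boxes = out, labels = labels) else out
}

# Solidity of a pixel set: area / convex hull area (of the crack outline),
# clipped into [0, 1]. px, py are 1-based matrix coordinates.
blobSolidity <- function(px, py) {
  n <- length(px)
  if (n < 3L) return(1)
  corners <- rbind(cbind(px - 0.5, py - 0.5), cbind(px + 0.5, py - 0.5),
                   cbind(px - 0.5, py + 0.5), cbind(px + 0.5, py + 0.5))
  h <- grDevices::chull(corners)
  hullArea <- shoelaceArea(corners[h, , drop = FALSE])
  if (hullArea <= 0) return(1)
  clamp(n / hullArea, 0, 1)
}

#' Non-maximum suppression of scored boxes
#'
#' Greedy NMS: boxes are visited in descending score order (ties broken by
#' earlier index); a box is kept unless its IoU with an already-kept box
#' exceeds the threshold. The retained set therefore contains no pair with
#' IoU above the threshold, and the result is invariant to the input order
#' up to score ties.
#'
#' @param boxes matrix with columns x0, y0, x1, y1, score.
#' @param iouThreshold suppression threshold (the detection default is
#'   0.74).
#' @return the retained rows of `boxes`, in descending score order.
#' @export
nms <- function(boxes, iouThreshold = 0.74) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  ord <- order(-boxes[, "score"], seq_len(nrow(boxes)))
  keep <- integer(0)
  for (k in ord) {
    ok <- TRUE
    for (j in keep) {
      if (boxIoU(boxes[k, ], boxes[j, ]) > iouThreshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, k)
  }
  boxes[keep, , drop = FALSE]
}

#' Count grains from detections
#'
#' The grain number of a panicle is the number of detection boxes.
#'
#' @param boxes detection matrix (possibly 0 rows) or `NULL`.
#' @return integer count.
#' @export
countGrains <- function(boxes) {
  if (is.null(boxes)) return(0L)
  nrow(boxes)
}
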