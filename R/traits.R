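#' Red-channel grayscale of a grain crop
#'
#' Rice grains scanned on a dark panel show their strongest
#' grain-to-background contrast in the red channel, so segmentation operates
#' on channel R taken unchanged (no luminance mixing).
#'
#' @param pixels `H x W x 3` 8-bit array (R, G, B).
#' @return `H x W` numeric matrix of red intensities.
#' @export
redChannel <- function(pixels) {
  if (is(pixels, "ScanImage")) pixels <- pixels@pixels
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L)
    psStop("invalidArgument", "expected an H x W x 3 RGB array")
  matrix(as.numeric(pixels[, , 1L]), d[1L], d[2L])
}

#' Otsu's threshold over all 8-bit candidates
#'
#' Picks the intensity threshold `t` in 0..254 that maximizes the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` of the split into
#' intensities `<= t` (background) and `> t` (foreground). Ties resolve to
#' the smallest maximizing threshold. Binarization convention everywhere in
#' the package: foreground is `intensity > threshold`.
#'
#' @param gray numeric matrix of intensities in 0..255.
#' @return the threshold (scalar); binarize with `gray > threshold`.
#' @examples
#' g <- matrix(c(40, 40, 200, 200), 2)
#' otsuThreshold(g)
#' @export
otsuThreshold <- function(gray) {
  v <- as.integer(round(as.numeric(gray)))
  if (anyNA(v) || min(v) < 0 || max(v) > 255)
    psStop("invalidArgument", "intensities must lie in 0..255")
  if (min(v) == max(v))
    psStop("degenerateImage", "constant image has no Otsu threshold")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  w <- cumsum(h) / n                      # P(I <= t), t = 0..255
  m <- cumsum(h * (0:255)) / n            # E[I * 1(I <= t)]
  mt <- m[256L]
  t <- 0:254
  w0 <- w[t + 1L]; m0 <- m[t + 1L]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, 255L)
  bcv[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  t[which.max(bcv)]
}

#' Outer contour of the largest foreground component
#'
#' Labels the binary image, keeps the largest connected component, and traces
#' the boundary of its silhouette along pixel edges ("crack" tracing), so the
#' returned closed polygon has vertices at half-integer coordinates and a
#' shoelace area equal to the component's pixel count (interior holes are
#' ignored by the outer trace).
#'
#' @param binary logical or 0/1 matrix (rows = y, 0-based x/y convention).
#' @return matrix `n x 2` (columns x, y) of polygon vertices, class
#'   `grainContour`, with attributes `area` (pixel count of the component,
#'   holes filled) and `mask` (the component's filled mask).
#' @export
largestOuterContour <- function(binary) {
  m <- binary != 0
  if (!any(m)) psStop("emptyForeground", "no foreground pixels")
  lab <- EBImage::bwlabel(matToEB(m))
  labm <- ebToMat(EBImage::imageData(lab))
  counts <- tabulate(labm[labm > 0])
  big <- which.max(counts)
  comp <- labm == big
  filled <- ebToMat(EBImage::imageData(EBImage::fillHull(matToEB(comp)))) > 0
  poly <- traceCrackBoundary(filled)
  structure(poly, class = c("grainContour", class(poly)),
            area = sum(filled), mask = filled)
}

#' Grain length: farthest point pair on the contour
#'
#' The grain length is the maximum Euclidean distance between two contour
#' points, found exactly via the convex hull. The achieving pair defines the
#' grain's major axis.
#'
#' @param contour polygon from [largestOuterContour()] (columns x, y).
#' @param mmPerPx physical scale.
#' @return length in mm with attribute `axis`, a 2 x 2 matrix of the
#'   achieving endpoint pair (rows = points).
#' @export
grainLength <- function(contour, mmPerPx = 1) {
  fp <- farthestPair(unclass(contour)[, 1:2, drop = FALSE])
  structure(fp$d * mmPerPx, axis = rbind(fp$p, fp$q))
}

#' Grain width: maximal chord perpendicular to the major axis
#'
#' Sweeps lines perpendicular to the major axis at 1 px steps. Contour
#' points are binned by their projection onto the axis; within each bin the
#' chord is the range of the perpendicular coordinate, and the width is the
#' largest chord.
#'
#' @param contour polygon from [largestOuterContour()].
#' @param majorAxis 2 x 2 matrix of the major-axis endpoints (attribute
#'   `axis` of [grainLength()]).
#' @param mmPerPx physical scale.
#' @return width in mm.
#' @export
grainWidth <- function(contour, majorAxis, mmPerPx = 1) {
  u <- majorAxis[2L, ] - majorAxis[1L, ]
  L <- sqrt(sum(u^2))
  if (L < 1e-9) psStop("degenerateAxis", "major axis has zero length")
  u <- u / L
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  s <- (pts[, 1L] - majorAxis[1L, 1L]) * u[1L] +
       (pts[, 2L] - majorAxis[1L, 2L]) * u[2L]
  t <- -(pts[, 1L] - majorAxis[1L, 1L]) * u[2L] +
        (pts[, 2L] - majorAxis[1L, 2L]) * u[1L]
  bin <- floor(s) # 1 px steps along the axis
  lo <- tapply(t, bin, min)
  hi <- tapply(t, bin, max)
  max(hi - lo) * mmPerPx
}

#' Grain projection area and perimeter
#'
#' Area is the foreground pixel count of the largest connected component
#' (holes filled), converted by `mmPerPx^2`; for the crack-traced contour
#' this equals the polygon's shoelace area. Perimeter is the closed arc
#' length of the traced boundary after Douglas-Peucker simplification with a
#' 1 px tolerance, which removes the staircase excess of the raw pixel-edge
#' path; the simplified boundary of a filled 10 x 10 square measures exactly
#' 40 px, and digital disks approach circularity 1 as the radius grows.
#'
#' @param binary binary image (matrix) for `grainArea`.
#' @param contour traced contour for `grainPerimeter`.
#' @param mmPerPx physical scale.
#' @return area in mm^2 / perimeter in mm.
#' @export
grainArea <- function(binary, mmPerPx = 1) {
  m <- binary != 0
  if (!any(m)) psStop("emptyForeground", "no foreground pixels")
  lab <- EBImage::bwlabel(matToEB(m))
  labm <- ebToMat(EBImage::imageData(lab))
  counts <- tabulate(labm[labm > 0])
  max(counts) * mmPerPx^2
}

#' @rdname grainArea
#' @export
grainPerimeter <- function(contour, mmPerPx = 1) {
  poly <- unclass(contour)[, 1:2, drop = FALSE]
  simp <- rdpClosed(poly, eps = 1)
  polyArcLength(simp, closed = TRUE) * mmPerPx
}

#' Shape quantities derived from the four primary measurements
#'
#' Computes the length/width ratio, the area/perimeter ratio (mm), the
#' circularity `4 * pi * area / perimeter^2` (1 for a disk, decreasing with
#' elongation), and the equivalent ellipse, defined as the ellipse whose
#' major axis is the measured length and whose area equals the measured
#' area, so its minor axis is `4 * area / (pi * length)`.
#'
#' @param length,width grain axes in mm (> 0).
#' @param area projection area in mm^2 (> 0).
#' @param perimeter contour length in mm (> 0).
#' @return list with `lw_ratio`, `ap_ratio`, `circularity`,
#'   `eq_major_mm`, `eq_minor_mm`.
#' @examples
#' derivedTraits(8.607, 2.770, 18.140, 21.313)$ap_ratio # 0.851
#' @export
derivedTraits <- function(length, width, area, perimeter) {
  if (any(c(length, width, area, perimeter) <= 0))
    psStop("invalidArgument", "all trait inputs must be > 0")
  list(lw_ratio = length / width,
       ap_ratio = area / perimeter,
       circularity = 4 * pi * area / perimeter^2,
       eq_major_mm = length,
       eq_minor_mm = 4 * area / (pi * length))
}

#' Measure one grain crop end to end
#'
#' The single-grain measurement pipeline: red channel, Otsu threshold,
#' largest-component outer contour, then length (farthest pair), width
#' (perpendicular sweep), projection area (pixel count), perimeter
#' (simplified contour arc length), and the derived shape quantities, all in
#' physical units.
#'
#' @param pixels `H x W x 3` 8-bit array or [ScanImage-class] containing one
#'   grain on a darker background.
#' @param mmPerPx physical scale; taken from the image when a
#'   [ScanImage-class] is supplied.
#' @return one-row data.frame with columns `length_mm`, `width_mm`,
#'   `area_mm2`, `perimeter_mm`, `lw_ratio`, `ap_ratio`, `circularity`,
#'   `eq_minor_mm`.
#' @examples
#' r <- renderGrain(GrainModel(8, 3), mmPerPixel(300))
#' extractGrainTraits(r$pixels, mmPerPixel(300))
#' @export
extractGrainTraits <- function(pixels, mmPerPx = NULL) {
  if (is(pixels, "ScanImage")) {
    if (is.null(mmPerPx)) mmPerPx <- mmPerPx(pixels)
    pixels <- pixels@pixels
  }
  if (is.null(mmPerPx))
    psStop("invalidArgument", "mmPerPx is required for raw arrays")
  stage <- function(name, expr) {
    tryCatch(expr, panicleScanError = function(e) {
      psStop(class(e)[1L], "stage %s: %s", name, conditionMessage(e))
    })
  }
  g <- stage("redChannel", redChannel(pixels))
  thr <- stage("otsu", otsuThreshold(g))
  ct <- stage("contour", largestOuterContour(g > thr))
  len <- grainLength(ct, mmPerPx)
  wid <- grainWidth(ct, attr(len, "axis"), mmPerPx)
  area <- attr(ct, "area") * mmPerPx^2
  per <- grainPerimeter(ct, mmPerPx)
  len <- as.numeric(len)
  if (wid > len) { tmp <- wid; wid <- len; len <- tmp } # near-round grains
  dv <- derivedTraits(len, wid, area, per)
  data.frame(length_mm = len, width_mm = wid, area_mm2 = area,
             perimeter_mm = per, lw_ratio = dv$lw_ratio,
             ap_ratio = dv$ap_ratio, circularity = dv$circularity,
             eq_minor_mm = dv$eq_minor_mm)
}

panicleTraitNames <- c("GN", "MGL", "SGL", "MGW", "SGW", "MGPA", "SGPA",
                       "MGP", "SGP", "MGAPR", "SGAPR", "MGC", "SGC",
                       "MGLWR", "SGLWR")

#' Aggregate per-grain traits to the fifteen panicle traits
#'
#' Summarizes a per-grain trait table into the panicle-level phenotype: the
#' grain number GN plus mean/SD pairs of grain length (MGL/SGL), width
#' (MGW/SGW), projection area (MGPA/SGPA), perimeter (MGP/SGP),
#' area/perimeter ratio (MGAPR/SGAPR), circularity (MGC/SGC), and
#' length/width ratio (MGLWR/SGLWR) -- one quantity trait, eight size traits
#' and six morphology traits.
#'
#' @param traits data.frame with at least the columns produced by
#'   [extractGrainTraits()] (>= 1 row).
#' @param sdType `"sample"` (n - 1 denominator, default) or `"population"`.
#'   A single grain yields SD 0 under either convention.
#' @return one-row data.frame with the 15 columns in standard order.
#' @examples
#' tr <- rbind(extractGrainTraits(renderGrain(GrainModel(8, 3),
#'   0.08)$pixels, 0.08))
#' aggregatePanicle(tr)
#' @export
aggregatePanicle <- function(traits, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (!is.data.frame(traits) || nrow(traits) < 1L)
    psStop("invalidArgument", "need at least one grain")
  n <- nrow(traits)
  sdev <- function(v) {
    if (n == 1L) return(0)
    s <- sd(v)
    if (sdType == "population") s * sqrt((n - 1) / n) else s
  }
  cols <- c(length_mm = "GL", width_mm = "GW", area_mm2 = "GPA",
            perimeter_mm = "GP", ap_ratio = "GAPR", circularity = "GC",
            lw_ratio = "GLWR")
  out <- list(GN = n)
  for (cn in names(cols)) {
    v <- traits[[cn]]
    out[[paste0("M", cols[[cn]])]] <- mean(v)
    out[[paste0("S", cols[[cn]])]] <- sdev(v)
  }
  as.data.frame(out)[, panicleTraitNames]
}

#' Thousand-grain trait distributions
#'
#' Emulates the thousand-grain statistic of seed evaluation: draws `n`
#' grains from a per-grain trait pool (without replacement when the pool is
#' large enough, otherwise with replacement and a warning) and returns fixed
#' bin-edge histograms of grain length, width and length/width ratio plus a
#' mean/SD summary.
#'
#' @param traits per-grain trait pool (data.frame).
#' @param n sample size (default 1000).
#' @param bins named list of histogram break vectors for `length_mm`,
#'   `width_mm`, `lw_ratio`; breaks are extended automatically when the
#'   sample exceeds them, so counts always sum to `n`.
#' @param seed optional integer seed.
#' @return list with `sample` (row indices drawn), `histograms` (named list
#'   of data.frames `mid`/`count`), and `summary` (mean and SD per trait).
#' @export
thousandGrainStats <- function(traits, n = 1000L,
                               bins = list(
                                 length_mm = seq(4, 12, by = 0.5),
                                 width_mm = seq(1.5, 4.5, by = 0.25),
                                 lw_ratio = seq(1, 6, by = 0.25)),
                               seed = NULL) {
  if (!is.data.frame(traits) || nrow(traits) < 1L)
    psStop("invalidArgument", "empty trait pool")
  idx <- withSeed(seed, {
    if (nrow(traits) >= n) sample.int(nrow(traits), n)
    else {
      warning("pool smaller than n; sampling with replacement")
      sample.int(nrow(traits), n, replace = TRUE)
    }
  })
  sub <- traits[idx, , drop = FALSE]
  hists <- list()
  for (tn in names(bins)) {
    v <- sub[[tn]]
    br <- bins[[tn]]
    step <- br[2L] - br[1L]
    while (min(v) < br[1L]) br <- c(br[1L] - step, br)
    while (max(v) > br[length(br)]) br <- c(br, br[length(br)] + step)
    h <- hist(v, breaks = br, plot = FALSE, include.lowest = TRUE)
    hists[[tn]] <- data.frame(mid = h$mids, count = h$counts)
  }
  list(sample = idx, histograms = hists,
       summary = data.frame(
         trait = names(bins),
         mean = vapply(names(bins), function(tn) mean(sub[[tn]]), 0),
         sd = vapply(names(bins), function(tn) sd(sub[[tn]]), 0),
         row.names = NULL))
}
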