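#' Default grain population parameters
#'
#' Distribution configuration emulating the scanned rice populations the
#' package targets: grain lengths centred at 8.607 mm (sd 0.589, truncated to
#' the observed 5-11 mm range), widths at 2.770 mm (sd 0.248, truncated to
#' 2-4 mm), uniform orientation, superellipse exponent 2.5, rice-like bright
#' fill on a dark scanner background.
#'
#' Each of `length` and `width` is a list with `dist` ("normal", "uniform" or
#' "fixed") and its parameters (`mean`/`sd`/`min`/`max` or `value`).
#'
#' @param length,width marginal distribution configs (see Details).
#' @param shapeExponent superellipse exponent.
#' @param fillColor RGB fill triple (0..255).
#' @param textureSd Gaussian texture noise sd in 8-bit units.
#' @return A list of class `grainParams`.
#' @export
grainParams <- function(length = list(dist = "normal", mean = 8.607,
                                      sd = 0.589, min = 5, max = 11),
                        width = list(dist = "normal", mean = 2.770,
                                     sd = 0.248, min = 2, max = 4),
                        shapeExponent = 2.5,
                        fillColor = c(205, 175, 120),
                        textureSd = 4) {
  structure(list(length = length, width = width,
                 shapeExponent = shapeExponent, fillColor = fillColor,
                 textureSd = textureSd), class = "grainParams")
}

drawMarginal <- function(cfg) {
  switch(cfg$dist,
    fixed = cfg$value,
    uniform = {
      if (cfg$min > cfg$max)
        psStop("invalidArgument", "infeasible range: min %g > max %g",
               cfg$min, cfg$max)
      runif(1, cfg$min, cfg$max)
    },
    normal = {
      lo <- if (is.null(cfg$min)) -Inf else cfg$min
      hi <- if (is.null(cfg$max)) Inf else cfg$max
      if (lo > hi) psStop("invalidArgument", "infeasible truncation bounds")
      for (i in 1:100) {
        v <- rnorm(1, cfg$mean, cfg$sd)
        if (v >= lo && v <= hi) return(v)
      }
      clamp(cfg$mean, lo, hi)
    },
    psStop("invalidArgument", "unknown distribution '%s'", cfg$dist))
}

#' Draw one grain from a population configuration
#'
#' Samples length, width and orientation from the configured marginals,
#' re-drawing the width (up to a bounded number of attempts) so that
#' `length >= width` always holds.
#'
#' @param params a [grainParams()] configuration.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [GrainModel-class].
#' @examples
#' g <- sampleGrain(grainParams(), seed = 1)
#' @export
sampleGrain <- function(params = grainParams(), seed = NULL) {
  withSeed(seed, {
    len <- drawMarginal(params$length)
    wid <- drawMarginal(params$width)
    tries <- 0L
    while (wid > len && tries < 50L) {
      wid <- drawMarginal(params$width)
      tries <- tries + 1L
    }
    if (wid > len) wid <- len
    GrainModel(len, wid, orientation = runif(1, 0, pi),
               shapeExponent = params$shapeExponent,
               fillColor = params$fillColor, textureSd = params$textureSd)
  })
}

# Sub-pixel coverage of a rotated superellipse over a pixel grid.
# X, Y are matrices of 0-based pixel-center coordinates (rows = y).
# antialias: 3x3 supersampling; otherwise a center-point inside test.
superellipseCoverage <- function(X, Y, cx, cy, a, b, theta, n,
                                 antialias = TRUE) {
  ct <- cos(theta); st <- sin(theta)
  offs <- if (antialias) c(-1 / 3, 0, 1 / 3) else 0
  cov <- matrix(0, nrow(X), ncol(X))
  for (ox in offs) for (oy in offs) {
    dx <- X + ox - cx; dy <- Y + oy - cy
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    cov <- cov + (abs(u)^n + abs(v)^n <= 1)
  }
  cov / length(offs)^2
}

# Conservative half-extents of the rotated superellipse's bounding box.
grainHalfExtent <- function(a, b, theta) {
  c(hx = a * abs(cos(theta)) + b * abs(sin(theta)),
    hy = a * abs(sin(theta)) + b * abs(cos(theta)))
}

#' Render a single grain crop with its exact mask
#'
#' Rasterizes the grain silhouette at the given physical scale with 3x3
#' supersampled anti-aliasing, quantizes to 8 bits, and returns the binary
#' ground-truth mask defined by >= 50 % pixel coverage. The grain fill is
#' brighter than the dark scanner background so that Otsu segmentation
#' separates the two.
#'
#' @param model a [GrainModel-class].
#' @param mmPerPx physical scale (e.g. `mmPerPixel(600)`).
#' @param pad background margin around the silhouette, px.
#' @param antialias logical; turn off for exactly two-colour renders.
#' @param background RGB triple of the scanner background.
#' @return `list(pixels = H x W x 3 8-bit array, mask = logical matrix,
#'   coverage = numeric matrix)`.
#' @examples
#' r <- renderGrain(GrainModel(8, 3), mmPerPixel(300))
#' sum(r$mask)
#' @export
renderGrain <- function(model, mmPerPx, pad = 4L, antialias = TRUE,
                        background = c(40, 38, 35)) {
  a <- model@lengthMm / 2 / mmPerPx
  b <- model@widthMm / 2 / mmPerPx
  he <- grainHalfExtent(a, b, model@orientation)
  W <- 2L * as.integer(ceiling(he["hx"])) + 1L + 2L * as.integer(pad)
  H <- 2L * as.integer(ceiling(he["hy"])) + 1L + 2L * as.integer(pad)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), W), H, W)
  cov <- superellipseCoverage(X, Y, cx, cy, a, b, model@orientation,
                              model@shapeExponent, antialias)
  if (max(cov) < 0.5)
    psStop("invalidArgument", "grain does not fit the requested crop")
  mask <- cov >= 0.5
  pix <- array(0, dim = c(H, W, 3L))
  noise <- if (model@textureSd > 0)
    matrix(rnorm(H * W, 0, model@textureSd), H, W) * (cov > 0) else 0
  for (ch in 1:3) {
    pix[, , ch] <- background[ch] + cov * (model@fillColor[ch] -
                                           background[ch]) + noise
  }
  list(pixels = quantize8(pix), mask = mask, coverage = cov)
}

# True (analytic) trait row for a model, in mm units.
modelTruth <- function(model) {
  a <- model@lengthMm / 2; b <- model@widthMm / 2; n <- model@shapeExponent
  area <- superellipseArea(a, b, n)
  per <- superellipsePerimeter(a, b, n)
  data.frame(length_mm = model@lengthMm, width_mm = model@widthMm,
             area_mm2 = area, perimeter_mm = per,
             lw_ratio = model@lengthMm / model@widthMm,
             ap_ratio = area / per,
             circularity = 4 * pi * area / per^2,
             orientation = model@orientation,
             shape_exponent = n)
}

#' Generate a synthetic scanned-panicle scene with exact annotation
#'
#' Places `nGrains` grains drawn from `params` on a dark canvas by rejection
#' sampling. Later grains are drawn on top of earlier ones; a candidate
#' placement is rejected when it would push any already-placed grain's
#' occlusion ratio (1 - visible area / full area) above `occlusionMax`.
#' With `occlusionMax = 0` all silhouettes are pairwise disjoint.
#'
#' The default canvas (1425 x 1700 px at 150 dpi) matches the working scale
#' of detection on quarter-resolution panicle scans; panicles carry between
#' roughly 45 and 250 grains at this scale.
#'
#' @param nGrains number of grains (>= 1).
#' @param occlusionMax per-grain occlusion ceiling in `[0, 1)`.
#' @param mmPerPx physical scale of the scene.
#' @param width,height canvas size in px.
#' @param params a [grainParams()] configuration.
#' @param seed optional integer seed.
#' @param maxTries placement attempts per grain before giving up.
#' @param background RGB background triple.
#' @param backgroundNoiseSd Gaussian background noise sd (8-bit units).
#' @return `list(image = ScanImage, annotation = SceneAnnotation)`.
#' @examples
#' sc <- generateScene(5, seed = 1)
#' length(sc$annotation)
#' @export
generateScene <- function(nGrains, occlusionMax = 0,
                          mmPerPx = mmPerPixel(150),
                          width = 1425L, height = 1700L,
                          params = grainParams(), seed = NULL,
                          maxTries = 200L, background = c(40, 38, 35),
                          backgroundNoiseSd = 3) {
  if (!isCount(nGrains) || nGrains < 1)
    psStop("invalidArgument", "nGrains must be a positive integer")
  if (occlusionMax < 0 || occlusionMax >= 1)
    psStop("invalidArgument", "occlusionMax must lie in [0, 1)")
  withSeed(seed, {
    label <- matrix(0L, height, width)
    renders <- vector("list", nGrains)
    offsets <- matrix(0L, nGrains, 2L)
    fullArea <- integer(nGrains)
    covered <- integer(nGrains)
    truths <- vector("list", nGrains)
    models <- vector("list", nGrains)
    for (i in seq_len(nGrains)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        model <- sampleGrain(params)
        a <- model@lengthMm / 2 / mmPerPx; b <- model@widthMm / 2 / mmPerPx
        he <- grainHalfExtent(a, b, model@orientation)
        if (2 * he["hx"] + 2 >= width || 2 * he["hy"] + 2 >= height) next
        cx <- runif(1, he["hx"] + 1, width - he["hx"] - 2)
        cy <- runif(1, he["hy"] + 1, height - he["hy"] - 2)
        # cheap trial mask first; the anti-aliased render only on success
        trial <- renderGrain(model, mmPerPx, pad = 2L, antialias = FALSE,
                             background = background)
        hh <- nrow(trial$mask); ww <- ncol(trial$mask)
        x0 <- as.integer(round(cx - (ww - 1) / 2))
        y0 <- as.integer(round(cy - (hh - 1) / 2))
        if (x0 < 0L || y0 < 0L || x0 + ww > width || y0 + hh > height) next
        sub <- label[(y0 + 1L):(y0 + hh), (x0 + 1L):(x0 + ww)]
        checkMask <- function(m) {
          if (occlusionMax == 0) {
            # require a 1 px gap so disjoint silhouettes never touch
            m <- ebToMat(EBImage::imageData(EBImage::dilate(
              matToEB(m), EBImage::makeBrush(3L, "box")))) > 0
          }
          hit <- sub[m]
          hit[hit > 0L]
        }
        exceeds <- function(hit) {
          if (!length(hit)) return(FALSE)
          if (occlusionMax == 0) return(TRUE)
          newCover <- table(hit)
          ids <- as.integer(names(newCover))
          any((covered[ids] + as.integer(newCover)) / fullArea[ids] >
              occlusionMax)
        }
        if (exceeds(checkMask(trial$mask))) next
        r <- renderGrain(model, mmPerPx, pad = 2L, antialias = TRUE,
                         background = background)
        hit <- checkMask(r$mask)
        if (exceeds(hit)) next
        if (length(hit)) {
          newCover <- table(hit)
          ids <- as.integer(names(newCover))
          covered[ids] <- covered[ids] + as.integer(newCover)
        }
        sub[r$mask] <- i
        label[(y0 + 1L):(y0 + hh), (x0 + 1L):(x0 + ww)] <- sub
        model@center <- c(cx, cy)
        renders[[i]] <- r
        offsets[i, ] <- c(x0, y0)
        fullArea[i] <- sum(r$mask)
        models[[i]] <- model
        truths[[i]] <- modelTruth(model)
        placed <- TRUE
        break
      }
      if (!placed)
        psStop("placementFailed",
               "could not place grain %d of %d after %d attempts", i,
               nGrains, maxTries)
    }
    # Compose the image in z-order (later grains over earlier ones).
    pix <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) {
      pix[, , ch] <- background[ch] +
        matrix(rnorm(height * width, 0, backgroundNoiseSd), height, width)
    }
    for (i in seq_len(nGrains)) {
      r <- renders[[i]]; x0 <- offsets[i, 1L]; y0 <- offsets[i, 2L]
      hh <- nrow(r$mask); ww <- ncol(r$mask)
      ys <- (y0 + 1L):(y0 + hh); xs <- (x0 + 1L):(x0 + ww)
      for (ch in 1:3) {
        base <- pix[ys, xs, ch]
        pix[ys, xs, ch] <- base * (1 - r$coverage) +
          r$coverage * as.numeric(r$pixels[, , ch])
      }
    }
    boxes <- t(vapply(seq_len(nGrains), function(i) {
      r <- renders[[i]]
      rows <- range(which(rowSums(r$mask) > 0))
      cols <- range(which(colSums(r$mask) > 0))
      c(offsets[i, 1L] + cols[1L] - 1L, offsets[i, 2L] + rows[1L] - 1L,
        offsets[i, 1L] + cols[2L], offsets[i, 2L] + rows[2L])
    }, numeric(4)))
    colnames(boxes) <- c("x0", "y0", "x1", "y1")
    masks <- lapply(seq_len(nGrains), function(i)
      list(x0 = offsets[i, 1L], y0 = offsets[i, 2L],
           mask = renders[[i]]$mask))
    ann <- new("SceneAnnotation", boxes = boxes, masks = masks,
               truths = do.call(rbind, truths),
               occlusion = covered / fullArea)
    list(image = ScanImage(quantize8(pix), 25.4 / mmPerPx),
         annotation = ann, label = label, models = models)
  })
}

#' Build a paired occluded/clean restoration sample
#'
#' Renders one grain centred in a square crop, then composites an occluder
#' (a second grain drawn from the same population, or a thin dark branch
#' strip emulating the panicle rachis) whose position is found by bisection
#' so that it covers the requested fraction of the grain silhouette to
#' within `tol`. `ratio = 0` returns a pair with pixel-identical images.
#'
#' @param model a [GrainModel-class] for the target grain.
#' @param ratio requested occlusion ratio in `[0, 0.9]`.
#' @param size crop side length in px (default 256).
#' @param mmPerPx physical scale; `NULL` scales the grain to 60 % of the crop.
#' @param occluder `"grain"` or `"branch"`.
#' @param direction approach direction of the occluder relative to the grain
#'   axis: `"random"`, `"end"` (covers a grain tip) or `"side"`.
#' @param params population for grain-type occluders.
#' @param tol tolerance on the realised ratio (default 0.03).
#' @param maxTries occluder draws before giving up.
#' @param seed optional integer seed.
#' @param background RGB background triple.
#' @return A [PairedSample-class]; its `ratio` slot holds the realised ratio.
#' @examples
#' p <- makePair(GrainModel(8, 3), 0.3, size = 96, seed = 1)
#' pairRatio(p)
#' @export
makePair <- function(model, ratio, size = 256L, mmPerPx = NULL,
                     occluder = c("grain", "branch"),
                     direction = c("random", "end", "side"),
                     params = grainParams(), tol = 0.03, maxTries = 20L,
                     seed = NULL, background = c(40, 38, 35)) {
  occluder <- match.arg(occluder)
  direction <- match.arg(direction)
  if (ratio < 0 || ratio > 0.9)
    psStop("invalidArgument", "ratio must lie in [0, 0.9]")
  if (is.null(mmPerPx)) mmPerPx <- model@lengthMm / (0.6 * size)
  withSeed(seed, {
    a <- model@lengthMm / 2 / mmPerPx; b <- model@widthMm / 2 / mmPerPx
    he <- grainHalfExtent(a, b, model@orientation)
    if (2 * max(he) + 2 > size)
      psStop("invalidArgument", "grain does not fit a %d px crop", size)
    cx <- (size - 1) / 2; cy <- (size - 1) / 2
    X <- matrix(rep(0:(size - 1L), each = size), size, size)
    Y <- matrix(rep(0:(size - 1L), size), size, size)
    cov <- superellipseCoverage(X, Y, cx, cy, a, b, model@orientation,
                                model@shapeExponent, TRUE)
    gmask <- cov >= 0.5
    noise <- if (model@textureSd > 0)
      matrix(rnorm(size * size, 0, model@textureSd), size, size) * (cov > 0)
      else 0
  clean <- array(0, dim = c(size, size, 3L))
    for (ch in 1:3)
      clean[, , ch] <- background[ch] +
        cov * (model@fillColor[ch] - background[ch]) + noise
    clean <- quantize8(clean)
    if (ratio == 0) {
      return(new("PairedSample", occluded = clean, clean = clean, ratio = 0,
                 occluderMask = matrix(FALSE, size, size)))
    }
    gArea <- sum(gmask)
    dirAngle <- switch(direction,
      random = runif(1, 0, 2 * pi),
      end = model@orientation + sample(c(0, pi), 1L),
      side = model@orientation + pi / 2 + sample(c(0, pi), 1L))
    for (try in seq_len(maxTries)) {
      if (occluder == "grain") {
        om <- sampleGrain(params)
        oa <- om@lengthMm / 2 / mmPerPx; ob <- om@widthMm / 2 / mmPerPx
        on_ <- om@shapeExponent; oth <- om@orientation
        ocol <- om@fillColor; osd <- om@textureSd
      } else {
        # strip wide enough to reach the requested cover of the grain's
        # extent along the approach direction
        dA <- dirAngle - model@orientation
        hExt <- sqrt((a * cos(dA))^2 + (b * sin(dA))^2)
        oa <- size * 0.75
        ob <- max(0.5 / mmPerPx / 2,
                  ratio * hExt * runif(1, 1.1, 1.5))
        on_ <- 8; oth <- dirAngle + pi / 2 + runif(1, -0.2, 0.2)
        ocol <- c(110, 85, 60); osd <- 3
      }
      occCover <- function(t) {
        ox <- cx + t * cos(dirAngle); oy <- cy + t * sin(dirAngle)
        m <- superellipseCoverage(X, Y, ox, oy, oa, ob, oth, on_,
                                  FALSE) >= 0.5
        sum(m & gmask) / gArea
      }
      lo <- 0; hi <- sqrt(2) * size
      cov0 <- occCover(lo)
      if (cov0 < ratio - tol) next # occluder too small from this side
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (occCover(mid) >= ratio) lo <- mid else hi <- mid
      }
      t <- lo
      ox <- cx + t * cos(dirAngle); oy <- cy + t * sin(dirAngle)
      ocov <- superellipseCoverage(X, Y, ox, oy, oa, ob, oth, on_, TRUE)
      omask <- ocov >= 0.5
      realised <- sum(omask & gmask) / gArea
      if (abs(realised - ratio) > tol) next
      onoise <- if (osd > 0)
        matrix(rnorm(size * size, 0, osd), size, size) * (ocov > 0) else 0
      occ <- array(0, dim = c(size, size, 3L))
      for (ch in 1:3)
        occ[, , ch] <- as.numeric(clean[, , ch]) * (1 - ocov) +
          ocov * ocol[ch] + onoise
      return(new("PairedSample", occluded = quantize8(occ), clean = clean,
                 ratio = realised, occluderMask = omask))
    }
    psStop("unreachableRatio",
           "could not realise occlusion ratio %.2f within +/- %.2f", ratio,
           tol)
  })
}
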