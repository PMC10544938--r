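test_that("redChannel returns channel R untouched", {
  px <- array(0L, dim = c(2, 2, 3))
  px[1, 1, ] <- c(200L, 10L, 10L)
  expect_equal(redChannel(px)[1, 1], 200)
  blue <- array(0L, dim = c(4, 4, 3)); blue[, , 3] <- 255L
  expect_true(all(redChannel(blue) == 0))
  expect_error(redChannel(array(0L, dim = c(2, 2, 2))),
               class = "invalidArgument")
})

test_that("red channel separates synthetic grain better than blue", {
  r <- renderGrain(sampleGrain(seed = 3), 0.1)
  m <- r$mask
  contrast <- function(ch) mean(r$pixels[, , ch][m]) -
    mean(r$pixels[, , ch][!m])
  expect_gte(contrast(1), contrast(3))
})

test_that("otsuThreshold separates a two-level image exactly", {
  g <- matrix(c(rep(40, 20), rep(200, 12)), 4)
  t <- otsuThreshold(g)
  expect_gte(t, 40); expect_lt(t, 200)
  expect_equal(sum(g > t), 12L)
  expect_equal(sum(g <= t), 20L)
  expect_error(otsuThreshold(matrix(7, 3, 3)), class = "degenerateImage")
})

test_that("otsuThreshold equals the exhaustive brute-force oracle", {
  for (i in 1:20) {
    g <- withr::with_seed(i, matrix(sample(0:255, 400, TRUE), 20))
    expect_equal(otsuThreshold(g), otsuBrute(g))
  }
  # bimodal images as segmentation actually sees them
  for (i in 1:5) {
    g <- withr::with_seed(100 + i,
      matrix(c(rnorm(300, 60, 12), rnorm(100, 190, 15)), 20))
    g <- pmin(pmax(round(g), 0), 255)
    expect_equal(otsuThreshold(g), otsuBrute(g))
  }
})

test_that("otsu segmentation of a rendered grain matches the true mask", {
  r <- renderGrain(sampleGrain(seed = 8), mmPerPixel(600))
  g <- redChannel(r$pixels)
  fg <- g > otsuThreshold(g)
  jac <- sum(fg & r$mask) / sum(fg | r$mask)
  expect_gte(jac, 0.98)
})

test_that("largestOuterContour traces crack boundaries correctly", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 4:13] <- TRUE
  ct <- largestOuterContour(sq)
  expect_equal(attr(ct, "area"), 100)
  expect_equal(PanicleScan:::shoelaceArea(unclass(ct)[, 1:2]), 100)
  corners <- PanicleScan:::dropCollinear(unclass(ct)[, 1:2])
  expect_equal(nrow(corners), 4L)
  # two blobs: contour of the larger one only
  two <- matrix(FALSE, 30, 30)
  two[2:11, 2:11] <- TRUE   # 100 px
  two[20:24, 20:25] <- TRUE # 30 px
  ct2 <- largestOuterContour(two)
  expect_equal(attr(ct2, "area"), 100)
  # interior hole is ignored by the outer trace
  hole <- matrix(FALSE, 20, 20); hole[4:15, 4:15] <- TRUE
  hole[8:10, 8:10] <- FALSE
  ct3 <- largestOuterContour(hole)
  expect_equal(PanicleScan:::shoelaceArea(unclass(ct3)[, 1:2]), 144)
  expect_error(largestOuterContour(matrix(FALSE, 5, 5)),
               class = "emptyForeground")
})

test_that("grainLength is the exact farthest pair", {
  rect <- matrix(FALSE, 20, 40); rect[6:15, 6:35] <- TRUE # 30 x 10 px
  ct <- largestOuterContour(rect)
  L <- grainLength(ct, 1)
  expect_equal(as.numeric(L), sqrt(30^2 + 10^2), tolerance = 1e-9)
  # brute force over all contour points agrees with the hull shortcut
  pts <- unclass(ct)[, 1:2]
  d2 <- 0
  for (i in seq_len(nrow(pts) - 1))
    d2 <- max(d2, (pts[-(1:i), 1] - pts[i, 1])^2 +
                   (pts[-(1:i), 2] - pts[i, 2])^2)
  expect_equal(as.numeric(L), sqrt(max(d2)), tolerance = 1e-12)
  # digital circle: diameter up to crack quantization
  disk <- outer(-55:55, -55:55, function(y, x) x^2 + y^2 <= 50^2)
  Lc <- grainLength(largestOuterContour(disk), 1)
  expect_lt(abs(as.numeric(Lc) - 100), 1.5)
})

test_that("grainWidth sweeps perpendicular chords", {
  disk <- outer(-55:55, -55:55, function(y, x) x^2 + y^2 <= 50^2)
  ct <- largestOuterContour(disk)
  L <- grainLength(ct, 1)
  W <- grainWidth(ct, attr(L, "axis"), 1)
  expect_lt(abs(W - 100), 2)
  # rendered ellipse 2a = 200 px, 2b = 70 px
  ell <- GrainModel(20, 7, orientation = 0.5, shapeExponent = 2)
  r <- renderGrain(ell, 0.1)
  ct2 <- largestOuterContour(r$mask)
  L2 <- grainLength(ct2, 1)
  W2 <- grainWidth(ct2, attr(L2, "axis"), 1)
  expect_lt(abs(as.numeric(L2) - 200) / 200, 0.02)
  expect_lt(abs(W2 - 70) / 70, 0.02)
  # 1 px line degenerates to width <= 2
  line <- matrix(FALSE, 5, 30); line[3, 2:28] <- TRUE
  ct3 <- largestOuterContour(line)
  L3 <- grainLength(ct3, 1)
  expect_lte(grainWidth(ct3, attr(L3, "axis"), 1), 2)
})

test_that("area and perimeter follow the documented conventions", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 4:13] <- TRUE
  expect_equal(grainArea(sq, 1), 100)
  ct <- largestOuterContour(sq)
  # frozen golden value of the crack tracer + simplification: 40 px
  expect_equal(grainPerimeter(ct, 1), 40)
  expect_equal(grainPerimeter(ct, 0.5), 20)
  disk <- outer(-55:55, -55:55, function(y, x) x^2 + y^2 <= 50^2)
  expect_lt(abs(grainArea(disk, 1) - pi * 50^2) / (pi * 50^2), 0.02)
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(grainArea(single, 1), 1)
  expect_error(grainArea(matrix(FALSE, 3, 3)), class = "emptyForeground")
})

test_that("derived traits follow their defining formulas", {
  d <- derivedTraits(8.607, 2.770, 18.140, 21.313)
  expect_equal(round(d$ap_ratio, 3), 0.851)
  expect_equal(d$lw_ratio, 8.607 / 2.770, tolerance = 1e-9)
  expect_equal(d$circularity, 4 * pi * 18.140 / 21.313^2, tolerance = 1e-9)
  # ideal circle has circularity 1
  r <- 3
  dc <- derivedTraits(2 * r, 2 * r, pi * r^2, 2 * pi * r)
  expect_equal(dc$circularity, 1, tolerance = 1e-12)
  # equivalent ellipse: length 8, area 6*pi => minor axis 3
  expect_equal(derivedTraits(8, 4, 6 * pi, 20)$eq_minor_mm, 3,
               tolerance = 1e-12)
  expect_error(derivedTraits(0, 1, 1, 1), class = "invalidArgument")
})

test_that("extractGrainTraits recovers known grains and is deterministic", {
  mm <- mmPerPixel(600)
  g <- GrainModel(8.6, 2.8, orientation = 1.1)
  r <- renderGrain(g, mm)
  tr <- extractGrainTraits(r$pixels, mm)
  expect_lt(abs(tr$length_mm - 8.6) / 8.6, 0.02)
  expect_lt(abs(tr$width_mm - 2.8) / 2.8, 0.02)
  tr2 <- extractGrainTraits(r$pixels, mm)
  expect_identical(tr, tr2)
  blank <- array(10L, dim = c(32, 32, 3))
  expect_error(extractGrainTraits(blank, mm), class = "degenerateImage")
})

test_that("traits are stable across scale and rotation", {
  g <- GrainModel(8.2, 2.9, orientation = 0)
  t300 <- extractGrainTraits(renderGrain(g, mmPerPixel(300))$pixels,
                             mmPerPixel(300))
  t600 <- extractGrainTraits(renderGrain(g, mmPerPixel(600))$pixels,
                             mmPerPixel(600))
  for (cn in c("length_mm", "width_mm", "area_mm2", "perimeter_mm"))
    expect_lt(abs(t300[[cn]] - t600[[cn]]) / t600[[cn]], 0.03)
  # 8 orientations at 600 dpi
  mm <- mmPerPixel(600)
  vals <- t(vapply(seq(0, pi, length.out = 9)[1:8], function(th) {
    gi <- GrainModel(8.2, 2.9, orientation = th)
    tr <- extractGrainTraits(renderGrain(gi, mm)$pixels, mm)
    c(tr$length_mm, tr$width_mm)
  }, numeric(2)))
  expect_lt(diff(range(vals[, 1])) / mean(vals[, 1]), 0.03)
  expect_lt(diff(range(vals[, 2])) / mean(vals[, 2]), 0.03)
})

test_that("length >= width and circularity stays bounded over random grains", {
  mm <- mmPerPixel(300)
  for (i in 1:60) {
    g <- sampleGrain(seed = 6000 + i)
    tr <- extractGrainTraits(renderGrain(g, mm)$pixels, mm)
    expect_gte(tr$length_mm, tr$width_mm)
    expect_lte(tr$circularity, 1.05)
    expect_gt(tr$circularity, 0)
  }
  # digital disks approach circularity 1 from below as radius grows
  circs <- vapply(c(20, 40, 80), function(r) {
    disk <- outer(-(r + 3):(r + 3), -(r + 3):(r + 3),
                  function(y, x) x^2 + y^2 <= r^2)
    ct <- largestOuterContour(disk)
    4 * pi * attr(ct, "area") / grainPerimeter(ct, 1)^2
  }, 0)
  expect_true(all(circs <= 1.05))
  expect_lt(abs(circs[3] - 1), abs(circs[1] - 1) + 0.02)
})

test_that("aggregatePanicle computes the 15 panicle traits", {
  one <- data.frame(length_mm = 8, width_mm = 3, area_mm2 = 18,
                    perimeter_mm = 20, lw_ratio = 8 / 3, ap_ratio = 0.9,
                    circularity = 0.55, eq_minor_mm = 2.9)
  agg1 <- aggregatePanicle(one)
  expect_equal(names(agg1), c("GN", "MGL", "SGL", "MGW", "SGW", "MGPA",
                              "SGPA", "MGP", "SGP", "MGAPR", "SGAPR",
                              "MGC", "SGC", "MGLWR", "SGLWR"))
  expect_equal(agg1$GN, 1)
  expect_true(all(unlist(agg1[grep("^S", names(agg1))]) == 0))
  two <- rbind(one, within(one, { length_mm <- 10; lw_ratio <- 10 / 3 }))
  agg2 <- aggregatePanicle(two)
  expect_equal(agg2$MGL, 9)
  expect_equal(agg2$SGL, sqrt(2), tolerance = 1e-12)
  expect_equal(aggregatePanicle(two, "population")$SGL, 1,
               tolerance = 1e-12)
  # permutation invariance
  many <- one[rep(1, 10), ]
  many$length_mm <- 7:16
  expect_equal(aggregatePanicle(many),
               aggregatePanicle(many[sample(10), ]))
  expect_error(aggregatePanicle(one[0, ]), class = "invalidArgument")
})

test_that("panicle means converge to the generator population mean", {
  mm <- mmPerPixel(300)
  tr <- do.call(rbind, lapply(1:200, function(i) {
    g <- sampleGrain(seed = 9000 + i)
    extractGrainTraits(renderGrain(g, mm)$pixels, mm)
  }))
  agg <- aggregatePanicle(tr)
  se <- 0.589 / sqrt(200)
  # allow the small systematic rasterization bias on top of sampling noise
  expect_lt(abs(agg$MGL - 8.607), 3 * se + 0.05)
  expect_equal(agg$GN, 200)
})

test_that("thousandGrainStats samples deterministically and conserves counts", {
  pool <- data.frame(length_mm = rep(8, 1500), width_mm = rep(3, 1500),
                     lw_ratio = rep(8 / 3, 1500))
  st <- thousandGrainStats(pool, seed = 1)
  for (h in st$histograms) {
    expect_equal(sum(h$count), 1000)
    expect_equal(sum(h$count > 0), 1L) # identical grains: single bin
  }
  # uniform pool: counts uniform within multinomial 3 sigma
  pool2 <- data.frame(length_mm = withr::with_seed(3, runif(5000, 5, 11)))
  pool2$width_mm <- 3; pool2$lw_ratio <- pool2$length_mm / 3
  st2 <- thousandGrainStats(pool2, seed = 2,
                            bins = list(length_mm = seq(5, 11, 1)))
  counts <- st2$histograms$length_mm$count
  p <- 1 / length(counts)
  sigma <- sqrt(1000 * p * (1 - p))
  expect_true(all(abs(counts - 1000 * p) <= 3 * sigma))
  expect_identical(thousandGrainStats(pool2, seed = 2,
                                      bins = list(length_mm = seq(5, 11, 1)))$sample,
                   st2$sample)
  expect_warning(thousandGrainStats(pool[1:10, ], n = 100, seed = 1),
                 "replacement")
  expect_error(thousandGrainStats(pool[0, ]), class = "invalidArgument")
})
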