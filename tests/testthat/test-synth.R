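test_that("sampleGrain respects point-mass and range configurations", {
  pm <- grainParams(length = list(dist = "fixed", value = 8),
                    width = list(dist = "fixed", value = 3))
  g <- sampleGrain(pm, seed = 1)
  expect_equal(g@lengthMm, 8)
  expect_equal(g@widthMm, 3)
  expect_error(
    sampleGrain(grainParams(length = list(dist = "uniform", min = 9,
                                          max = 5)), seed = 1),
    class = "invalidArgument")
  # reproducibility
  g1 <- sampleGrain(seed = 7); g2 <- sampleGrain(seed = 7)
  expect_equal(g1@lengthMm, g2@lengthMm)
  expect_equal(g1@orientation, g2@orientation)
})

test_that("sampled populations match their configured distributions", {
  unif <- grainParams(length = list(dist = "uniform", min = 5, max = 11),
                      width = list(dist = "uniform", min = 2, max = 4))
  lens <- withr::with_seed(11,
    vapply(1:10000, function(i) sampleGrain(unif)@lengthMm, 0))
  expect_lt(abs(mean(lens) - 8), 0.1) # 3 se of uniform(5,11) at n = 1e4
  lens2 <- withr::with_seed(13,
    vapply(1:2000, function(i) sampleGrain()@lengthMm, 0))
  se <- 0.589 / sqrt(2000)
  expect_lt(abs(mean(lens2) - 8.607), 3 * se + 0.01) # truncation allowance
  # length >= width must hold for every draw
  ws <- withr::with_seed(17, vapply(1:500, function(i) {
    g <- sampleGrain(); g@lengthMm - g@widthMm }, 0))
  expect_true(all(ws >= 0))
})

test_that("rendered silhouettes have the analytic area and extent", {
  mm <- 0.1
  # circle case: superellipse with n = 2 and equal axes
  circ <- GrainModel(6, 6, shapeExponent = 2)
  r <- renderGrain(circ, mm)
  expect_lt(abs(sum(r$mask) - pi * 30^2) / (pi * 30^2), 0.02)
  # max pairwise mask distance matches the length
  idx <- which(r$mask, arr.ind = TRUE)
  d <- PanicleScan:::farthestPair(cbind(idx[, 2], idx[, 1]))$d
  expect_lt(abs(d - 6 / mm) / (6 / mm), 0.02)
  ell <- GrainModel(8, 3, orientation = 0.7)
  r2 <- renderGrain(ell, mm)
  a <- 4; b <- 1.5; n <- 2.5
  trueArea <- 4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n) / mm^2
  expect_lt(abs(sum(r2$mask) - trueArea) / trueArea, 0.02)
})

test_that("noise-free renders without anti-aliasing use exactly 2 colors", {
  g <- GrainModel(6, 2.5, textureSd = 0)
  r <- renderGrain(g, 0.2, antialias = FALSE)
  cols <- unique(matrix(as.numeric(r$pixels), ncol = 3))
  expect_equal(nrow(cols), 2L)
})

test_that("generateScene produces consistent annotations", {
  sc <- generateScene(1, seed = 1, width = 200, height = 200)
  expect_equal(length(sc$annotation), 1L)
  expect_equal(sceneOcclusion(sc$annotation), 0)
  expect_s4_class(sc$image, "ScanImage")
  # all pairwise mask intersections empty when overlap is disabled
  sc2 <- generateScene(50, occlusionMax = 0, seed = 2,
                       width = 800, height = 900)
  lab <- sc2$label
  full <- vapply(sceneMasks(sc2$annotation), function(m) sum(m$mask), 0)
  vis <- vapply(seq_len(50), function(i) sum(lab == i), 0)
  expect_equal(vis, full) # nothing hidden => no intersections
  expect_error(generateScene(40, seed = 3, width = 60, height = 60,
                             maxTries = 10),
               class = "placementFailed")
})

test_that("a full-count scene at the working canvas scale succeeds", {
  sc <- generateScene(250, seed = 4)
  expect_equal(length(sc$annotation), 250L)
  expect_true(all(sceneBoxes(sc$annotation)[, "x1"] <= 1425))
  expect_true(all(sceneBoxes(sc$annotation)[, "y1"] <= 1700))
})

test_that("scene area is conserved between visible and occluded parts", {
  sc <- generateScene(60, occlusionMax = 0.4, seed = 5,
                      width = 500, height = 500)
  occ <- sceneOcclusion(sc$annotation)
  full <- vapply(sceneMasks(sc$annotation), function(m) sum(m$mask), 0)
  vis <- vapply(seq_along(full), function(i) sum(sc$label == i), 0)
  expect_equal(vis + occ * full, full, tolerance = 1e-9)
  expect_true(all(occ <= 0.4 + 1e-9))
})

test_that("scenes regenerate bit-identically from the same seed", {
  a <- generateScene(20, occlusionMax = 0.2, seed = 99,
                     width = 400, height = 400)
  b <- generateScene(20, occlusionMax = 0.2, seed = 99,
                     width = 400, height = 400)
  expect_identical(scanPixels(a$image), scanPixels(b$image))
  expect_identical(sceneBoxes(a$annotation), sceneBoxes(b$annotation))
})

test_that("makePair realises the requested occlusion ratio", {
  g <- sampleGrain(seed = 21)
  p0 <- makePair(g, 0, size = 96, seed = 1)
  expect_identical(occludedImage(p0), cleanImage(p0))
  expect_equal(pairRatio(p0), 0)
  for (occl in c("grain", "branch")) {
    p <- makePair(g, 0.3, size = 128, occluder = occl, seed = 2)
    # independent check: the grain silhouette from the clean render is the
    # bright region; count how much of it the occluder footprint covers
    gmask <- cleanImage(p)[, , 1] > 128
    covered <- sum(gmask & occluderMask(p)) / sum(gmask)
    expect_gte(covered, 0.26)
    expect_lte(covered, 0.34)
    expect_equal(pairRatio(p), covered, tolerance = 0.02)
  }
  expect_error(makePair(g, 0.95), class = "invalidArgument")
})

test_that("pair generation is deterministic and varies across seeds", {
  g <- sampleGrain(seed = 30)
  p1 <- makePair(g, 0.25, size = 96, seed = 41)
  p2 <- makePair(g, 0.25, size = 96, seed = 41)
  expect_identical(occludedImage(p1), occludedImage(p2))
  expect_identical(cleanImage(p1), cleanImage(p2))
  p3 <- makePair(g, 0.25, size = 96, seed = 42)
  expect_false(identical(occludedImage(p1), occludedImage(p3)))
})

test_that("measured traits of clean renders recover the model parameters", {
  # central parameter-recovery property linking generator and measurement
  mm <- mmPerPixel(600)
  errs <- vapply(1:25, function(i) {
    g <- sampleGrain(seed = 400 + i)
    r <- renderGrain(g, mm)
    tr <- extractGrainTraits(r$pixels, mm)
    c(abs(tr$length_mm - g@lengthMm) / g@lengthMm,
      abs(tr$width_mm - g@widthMm) / g@widthMm)
  }, numeric(2))
  expect_lt(mean(errs), 0.02)
  expect_lt(max(errs), 0.03)
})
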