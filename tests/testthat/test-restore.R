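smokeConfig <- function(...) {
  RestorerConfig(imageSize = 64, depth = 3, baseChannels = 6,
                 batchSize = 4, ...)
}

test_that("restorer configuration defaults match the published table", {
  cfg <- RestorerConfig()
  expect_equal(cfg@imageSize, 256)
  expect_equal(cfg@batchSize, 64)
  expect_equal(cfg@optimizer, "adam")
  expect_equal(cfg@lr, 2e-4)
  expect_equal(cfg@maxEpochs, 500)
  expect_error(RestorerConfig(imageSize = 100))
})

test_that("restorer configuration survives a save/load round trip", {
  cfg <- RestorerConfig(imageSize = 128, depth = 3, lr = 1e-3,
                        patchGrid = 4)
  f <- tempfile(fileext = ".json")
  writeRestorerConfig(cfg, f)
  back <- readRestorerConfig(f)
  for (s in slotNames(cfg))
    expect_equal(slot(back, s), slot(cfg, s), info = s)
})

test_that("generator output shape equals input shape with U-Net wiring", {
  gen <- buildGenerator(smokeConfig(), seed = 1)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  out <- generatorForward(gen, x)$out
  expect_equal(dim(out), dim(x))
  expect_true(all(out >= 0 & out <= 1))
  # full-size build: 256 in, 256 out
  gen256 <- buildGenerator(RestorerConfig(baseChannels = 4), seed = 2)
  x256 <- array(runif(3 * 256 * 256), c(3, 256, 256))
  expect_equal(dim(generatorForward(gen256, x256)$out), c(3, 256, 256))
  expect_error(buildGenerator(RestorerConfig(imageSize = 48)))
})

test_that("the feature-map ledger halves then doubles", {
  led <- generatorLedger(RestorerConfig())
  enc <- led[grepl("^enc", led$stage), ]
  expect_equal(enc$size, 256 / 2^(1:4))
  expect_equal(enc$channels, c(8, 16, 32, 64))
  dec <- led[grepl("^dec", led$stage), ]
  expect_equal(dec$size, c(32, 64, 128))
  expect_equal(led$size[led$stage == "output"], 256)
  expect_equal(led$channels[led$stage == "output"], 3)
})

test_that("patch head geometry follows the standard schedule", {
  led <- discriminatorLedger(256)
  expect_equal(led$patchMap, 30)
  expect_equal(led$receptiveField, 70)
  expect_equal(led$sizes, c(128, 64, 32, 31, 30))
})

test_that("the fused discriminator emits both heads on one input pair", {
  cfg <- smokeConfig()
  disc <- buildDiscriminator(cfg, seed = 1)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  y <- array(runif(3 * 64 * 64), c(3, 64, 64))
  o <- discriminatorForward(disc, x, y)
  expect_gt(o$global, 0); expect_lt(o$global, 1)
  expect_true(all(o$patch > 0 & o$patch < 1))
  expect_equal(dim(o$patch), rep(discriminatorLedger(64)$patchMap, 2))
  # N = 1 degenerates the patch head into a second global score
  disc1 <- buildDiscriminator(smokeConfig(patchGrid = 1), seed = 1)
  o1 <- discriminatorForward(disc1, x, y)
  expect_equal(dim(o1$patch), c(1L, 1L))
})

test_that("a short adversarial run separates clean from corrupted pairs", {
  cfg <- smokeConfig(lr = 1e-3)
  pairs <- lapply(1:6, function(i)
    makePair(sampleGrain(seed = 500 + i), 0.3, size = 64, seed = 600 + i))
  r <- trainRestorer(pairs, cfg, seed = 3, steps = 50)
  p <- pairs[[1]]
  occ <- PanicleScan:::imageToTensor(occludedImage(p))
  clean <- PanicleScan:::imageToTensor(cleanImage(p))
  # corrupted candidate: the blurry early generator output for this input
  corrupt <- generatorForward(r$generator, occ)$out
  sClean <- discriminatorForward(r$discriminator, occ, clean)
  sBad <- discriminatorForward(r$discriminator, occ, corrupt)
  expect_gt(mean(sClean$patch), mean(sBad$patch))
  expect_gt(sClean$global, sBad$global)
})

test_that("training on identity pairs drives the generator towards identity", {
  cfg <- smokeConfig(lr = 1e-3)
  pairs <- lapply(1:8, function(i)
    makePair(sampleGrain(seed = 100 + i), 0, size = 64, seed = 200 + i))
  trained <- trainRestorer(pairs, cfg, seed = 1, steps = 120,
                           checkpointEvery = 30)
  expect_true(all(diff(trained$checkpoints$reconLoss) < 0))
  untrained <- trainRestorer(pairs, cfg, seed = 1, steps = 1)
  val <- makePair(sampleGrain(seed = 999), 0, size = 64, seed = 998)
  e0 <- mean(abs(as.numeric(untrained$restore(occludedImage(val))) -
                 as.numeric(cleanImage(val))))
  e1 <- mean(abs(as.numeric(trained$restore(occludedImage(val))) -
                 as.numeric(cleanImage(val))))
  expect_gt(e0 / e1, 5)
  expect_error(trainRestorer(list(), cfg), class = "invalidArgument")
})

test_that("training improves validation error over the untrained model", {
  cfg <- smokeConfig(lr = 1e-3)
  pairs <- lapply(1:20, function(i)
    makePair(sampleGrain(seed = 700 + i),
             ratio = 0.25, size = 64, seed = 800 + i))
  split <- splitDataset(seq_along(pairs), c(8, 2), seed = 1)
  trained <- trainRestorer(pairs[split[[1]]], cfg, seed = 2, steps = 100)
  untrained <- trainRestorer(pairs[split[[1]]], cfg, seed = 2, steps = 1)
  valErr <- function(model) mean(vapply(split[[2]], function(i) {
    mean(abs(as.numeric(model$restore(occludedImage(pairs[[i]]))) -
             as.numeric(cleanImage(pairs[[i]]))))
  }, 0))
  expect_lt(valErr(trained), valErr(untrained))
})

test_that("restoreBaseline is exact at zero occlusion and accurate at 30%", {
  g <- GrainModel(8.6, 2.8, orientation = 0.4, shapeExponent = 2)
  p0 <- makePair(g, 0, size = 128, seed = 1)
  r0 <- restoreBaseline(p0)
  expect_identical(r0$pixels, occludedImage(p0))
  mmp <- g@lengthMm / (0.6 * 256)
  # end occlusion: restored length within 3 % of truth
  pe <- makePair(g, 0.3, size = 256, direction = "end", seed = 5)
  re <- restoreBaseline(pe)
  ct <- largestOuterContour(re$mask)
  L <- grainLength(ct, mmp)
  expect_lt(abs(as.numeric(L) - 8.6) / 8.6, 0.03)
  # side occlusion: restored width within 5 % of truth
  ps <- makePair(g, 0.3, size = 256, direction = "side", seed = 7)
  rs <- restoreBaseline(ps)
  ct2 <- largestOuterContour(rs$mask)
  L2 <- grainLength(ct2, mmp)
  W2 <- grainWidth(ct2, attr(L2, "axis"), mmp)
  expect_lt(abs(W2 - 2.8) / 2.8, 0.05)
})

test_that("restoration never shrinks the visible silhouette", {
  for (i in 1:8) {
    p <- makePair(sampleGrain(seed = 900 + i), 0.3, size = 128,
                  seed = 950 + i)
    r <- restoreBaseline(p)
    expect_true(all(r$mask[r$visible]))
  }
  # learned path, post-threshold
  cfg <- smokeConfig()
  pairs <- lapply(1:4, function(i)
    makePair(sampleGrain(seed = 60 + i), 0.2, size = 64, seed = 70 + i))
  model <- trainRestorer(pairs, cfg, seed = 1, steps = 10)
  p <- pairs[[1]]
  vis <- cleanImage(p)[, , 1] > 128 & !occluderMask(p)
  sil <- restoredSilhouette(model$restore(occludedImage(p)), vis)
  expect_true(all(sil[vis]))
})

test_that("restoration fails explicitly when evidence is insufficient", {
  g <- sampleGrain(seed = 31)
  p <- makePair(g, 0.85, size = 128, seed = 32, tol = 0.05)
  expect_error(restoreBaseline(p), class = "insufficientEvidence")
})
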