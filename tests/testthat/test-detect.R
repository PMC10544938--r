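test_that("baseline detector finds each disjoint grain exactly once", {
  sc <- generateScene(30, occlusionMax = 0, seed = 100,
                      width = 700, height = 700)
  boxes <- detectBaseline(sc$image)
  expect_equal(nrow(boxes), 30L)
  expect_true(all(boxes[, "score"] >= 0 & boxes[, "score"] <= 1))
  blank <- ScanImage(array(30L, dim = c(64, 64, 3)), 150)
  expect_equal(nrow(detectBaseline(blank)), 0L)
})

test_that("baseline detection is deterministic", {
  sc <- generateScene(15, occlusionMax = 0.2, seed = 101,
                      width = 400, height = 400)
  expect_identical(detectBaseline(sc$image), detectBaseline(sc$image))
})

test_that("watershed never splits isolated convex grains", {
  # many small seeded scenes; every zero-occlusion count must be exact
  for (s in 1:12) {
    n <- 10 + (s %% 5) * 4
    sc <- generateScene(n, occlusionMax = 0, seed = 200 + s,
                        width = 520, height = 560)
    expect_equal(nrow(detectBaseline(sc$image)), n)
  }
})

test_that("detected boxes align with the annotated truth", {
  sc <- generateScene(25, occlusionMax = 0, seed = 300,
                      width = 600, height = 600)
  boxes <- detectBaseline(sc$image)
  truth <- sceneBoxes(sc$annotation)
  expect_equal(averagePrecision(boxes, truth, 0.5), 1, tolerance = 1e-9)
})

test_that("nms retains exactly the non-suppressed boxes", {
  two <- cbind(x0 = c(0, 0), y0 = c(0, 0), x1 = c(10, 10), y1 = c(10, 10),
               score = c(0.9, 0.8))
  kept <- nms(two, 0.74)
  expect_equal(nrow(kept), 1L)
  expect_equal(unname(kept[1, "score"]), 0.9)
  disjoint <- cbind(x0 = c(0, 20, 40), y0 = 0, x1 = c(10, 30, 50), y1 = 10,
                    score = c(0.5, 0.9, 0.7))
  expect_equal(nrow(nms(disjoint, 0.74)), 3L)
})

test_that("nms matches the brute-force oracle on hand-placed boxes", {
  boxes <- cbind(x0 = c(0, 2, 20, 21, 40),
                 y0 = c(0, 1, 0, 0, 0),
                 x1 = c(10, 12, 30, 31, 50),
                 y1 = c(10, 11, 10, 10, 10),
                 score = c(0.9, 0.85, 0.7, 0.95, 0.6))
  for (thr in c(0.3, 0.5, 0.74)) {
    got <- nms(boxes, thr)
    want <- nmsBrute(boxes, thr)
    expect_equal(got[order(got[, "x0"]), ], want[order(want[, "x0"]), ])
  }
  # retained pairs never exceed the threshold
  got <- nms(boxes, 0.5)
  for (i in seq_len(nrow(got) - 1))
    for (j in (i + 1):nrow(got))
      expect_lte(boxIoU(got[i, ], got[j, ]), 0.5)
})

test_that("nms is invariant to input order up to score ties", {
  boxes <- cbind(x0 = c(0, 3, 30, 60, 61), y0 = c(0, 2, 0, 0, 1),
                 x1 = c(10, 13, 40, 70, 72), y1 = c(10, 12, 10, 10, 11),
                 score = c(0.9, 0.5, 0.8, 0.7, 0.95))
  ref <- nms(boxes, 0.4)
  for (s in 1:5) {
    p <- withr::with_seed(s, sample(nrow(boxes)))
    got <- nms(boxes[p, ], 0.4)
    expect_equal(got[order(got[, "score"]), ], ref[order(ref[, "score"]), ])
  }
})

test_that("countGrains is the number of detection boxes", {
  expect_equal(countGrains(NULL), 0L)
  m <- cbind(x0 = 1:109, y0 = 1, x1 = 2:110, y1 = 2, score = 0.9)
  expect_equal(countGrains(m), 109L)
  expect_equal(countGrains(m[0, , drop = FALSE]), 0L)
})

test_that("a generated panicle-sized scene is counted exactly", {
  sc <- generateScene(109, occlusionMax = 0, seed = 400)
  expect_equal(countGrains(detectBaseline(sc$image)), 109L)
})

test_that("detector configuration defaults match the published table", {
  d <- detectorDefaults()
  expect_equal(d$inputSize, c(1425, 1700))
  expect_equal(d$nmsIou, 0.74)
  expect_equal(d$rpnProposals, 4000)
  expect_equal(d$backboneDepth, 50)
  expect_equal(d$optimizer, "sgd")
  expect_equal(d$lr, 0.02)
  expect_equal(d$momentum, 0.9)
  expect_equal(d$weightDecay, 1e-4)
  expect_equal(d$batchSize, 1)
  expect_equal(d$maxEpochs, 100)
  expect_error(DetectorConfig(backboneDepth = 34))
})

test_that("the trainable detector overfits one small scene", {
  sc <- generateScene(4, mmPerPx = 0.45, width = 64, height = 64, seed = 9,
                      params = grainParams(
                        length = list(dist = "uniform", min = 5, max = 8),
                        width = list(dist = "uniform", min = 2, max = 3)))
  det <- buildDetector(DetectorConfig(anchorPx = 16, fpnChannels = 8),
                       seed = 1)
  batch <- list(list(image = sc$image, boxes = sceneBoxes(sc$annotation)))
  losses <- vapply(1:25, function(i) det$trainStep(batch), 0)
  expect_true(all(is.finite(losses)))
  expect_lt(losses[25], losses[1])
  pred <- det$predict(sc$image)
  expect_gte(nrow(pred), 1L)
})

test_that("both backbone depths build and train", {
  sc <- generateScene(3, mmPerPx = 0.5, width = 64, height = 64, seed = 10,
                      params = grainParams(
                        length = list(dist = "uniform", min = 5, max = 7),
                        width = list(dist = "uniform", min = 2, max = 3)))
  batch <- list(list(image = sc$image, boxes = sceneBoxes(sc$annotation)))
  for (depth in c(50, 101)) {
    det <- buildDetector(DetectorConfig(backboneDepth = depth,
                                        anchorPx = 16, fpnChannels = 8),
                         seed = 2)
    l <- det$trainStep(batch)
    expect_true(is.finite(l))
  }
})
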