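#' Detection model configuration
#'
#' Hyperparameters of the trainable grain detector. The defaults are the
#' published working point: 1425 x 1700 inputs, NMS threshold 0.74, 4000
#' region proposals, depth-50 backbone, SGD with learning rate 0.02,
#' momentum 0.9, weight decay 1e-4, batch size 1, 100 epochs. Anchor size
#' and feature width go beyond that table and follow the architecture
#' family's standard defaults, exposed here.
#'
#' @slot inputSize working input size `c(width, height)` in px.
#' @slot nmsIou non-maximum suppression IoU threshold.
#' @slot rpnProposals maximum region proposals retained.
#' @slot backboneDepth 50 or 101 (channel-width tag of the compact
#'   backbone).
#' @slot optimizer `"sgd"`.
#' @slot lr,momentum,weightDecay SGD parameters.
#' @slot batchSize images per step.
#' @slot maxEpochs full-scale epoch budget.
#' @slot anchorPx square anchor side at the fused feature stride.
#' @slot fpnChannels channels of the fused pyramid map.
#' @slot scoreThreshold objectness cutoff at prediction time.
#' @export
setClass("DetectorConfig",
  slots = c(inputSize = "numeric", nmsIou = "numeric",
            rpnProposals = "numeric", backboneDepth = "numeric",
            optimizer = "character", lr = "numeric", momentum = "numeric",
            weightDecay = "numeric", batchSize = "numeric",
            maxEpochs = "numeric", anchorPx = "numeric",
            fpnChannels = "numeric", scoreThreshold = "numeric"),
  prototype = list(inputSize = c(1425, 1700), nmsIou = 0.74,
                   rpnProposals = 4000, backboneDepth = 50,
                   optimizer = "sgd", lr = 0.02, momentum = 0.9,
                   weightDecay = 1e-4, batchSize = 1, maxEpochs = 100,
                   anchorPx = 32, fpnChannels = 16, scoreThreshold = 0.5))

setValidity("DetectorConfig", function(object) {
  if (!object@backboneDepth %in% c(50, 101))
    return("backboneDepth must be 50 or 101")
  if (object@nmsIou <= 0 || object@nmsIou >= 1)
    return("nmsIou must lie in (0, 1)")
  TRUE
})

#' @rdname DetectorConfig-class
#' @param ... slot values overriding the defaults.
#' @export
DetectorConfig <- function(...) new("DetectorConfig", ...)

setMethod("show", "DetectorConfig", function(object) {
  cat(sprintf(
    "DetectorConfig: %dx%d, NMS %.2f, %d proposals, depth %d, %s lr %g\n",
    object@inputSize[1L], object@inputSize[2L], object@nmsIou,
    object@rpnProposals, object@backboneDepth, object@optimizer, object@lr))
})

#' Core hyperparameters of a detector configuration
#'
#' @param config a [DetectorConfig-class].
#' @return named list of the published working-point values.
#' @export
detectorDefaults <- function(config = DetectorConfig()) {
  list(inputSize = config@inputSize, nmsIou = config@nmsIou,
       rpnProposals = config@rpnProposals,
       backboneDepth = config@backboneDepth, optimizer = config@optimizer,
       lr = config@lr, momentum = config@momentum,
       weightDecay = config@weightDecay, batchSize = config@batchSize,
       maxEpochs = config@maxEpochs)
}

detectorChannels <- function(depth) {
  if (depth == 101) c(12L, 24L, 48L) else c(8L, 16L, 32L)
}

#' Build the trainable two-stage grain detector
#'
#' A compact two-stage detector with multi-scale feature-pyramid fusion.
#' The backbone extracts features at strides 2, 4 and 8; lateral 1 x 1
#' convolutions project the stride-4 and stride-8 maps to a common width and
#' the upsampled deep map is added to the shallow one (the pyramid fusion
#' that preserves small, densely packed grains). A region-proposal head
#' predicts per-cell objectness and box deltas against square anchors; the
#' second stage re-scores each proposal from its pooled pyramid features.
#'
#' @param config a [DetectorConfig-class].
#' @param seed optional seed for weight initialization.
#' @return object of class `psDetector` with fields
#'   `trainStep(batch)` (one SGD step over a list of
#'   `list(image, boxes)` samples; returns the loss) and
#'   `predict(image)` (scored boxes after NMS). Both close over mutable
#'   state inside the object environment.
#' @export
buildDetector <- function(config = DetectorConfig(), seed = NULL) {
  validObject(config)
  env <- new.env(parent = emptyenv())
  withSeed(seed, {
    ch <- detectorChannels(config@backboneDepth)
    f <- as.integer(config@fpnChannels)
    env$layers <- list(
      conv1 = nnConv(3L, ch[1L], k = 3L, stride = 2L, pad = 1L, "lrelu"),
      conv2 = nnConv(ch[1L], ch[2L], k = 3L, stride = 2L, pad = 1L, "lrelu"),
      conv3 = nnConv(ch[2L], ch[3L], k = 3L, stride = 2L, pad = 1L, "lrelu"),
      lat2 = nnConv(ch[2L], f, k = 1L, stride = 1L, pad = 0L, "linear"),
      lat3 = nnConv(ch[3L], f, k = 1L, stride = 1L, pad = 0L, "linear"),
      fuse = nnConv(f, f, k = 3L, stride = 1L, pad = 1L, "lrelu"),
      obj = nnConv(f, 1L, k = 1L, stride = 1L, pad = 0L, "linear"),
      reg = nnConv(f, 4L, k = 1L, stride = 1L, pad = 0L, "linear"))
    env$roiW <- rnorm(f, 0, sqrt(1 / f))
    env$roiB <- 0
  })
  env$opt <- nnMakeOpt(env$layers, "sgd", lr = config@lr,
                       momentum = config@momentum,
                       weightDecay = config@weightDecay)
  env$roiM <- 0 * env$roiW; env$roiBM <- 0
  env$config <- config

  forward <- function(x, keepCache = FALSE) {
    L <- env$layers
    r1 <- nnConvForward(L$conv1, x)
    r2 <- nnConvForward(L$conv2, r1$out)
    r3 <- nnConvForward(L$conv3, r2$out)
    l2 <- nnConvForward(L$lat2, r2$out)
    l3 <- nnConvForward(L$lat3, r3$out)
    up <- upsample2ForwardCpp(l3$out)
    # crop in case of odd sizes
    dp <- dim(l2$out)
    p <- l2$out + up[, seq_len(dp[2L]), seq_len(dp[3L]), drop = FALSE]
    fu <- nnConvForward(L$fuse, p)
    ob <- nnConvForward(L$obj, fu$out)
    rg <- nnConvForward(L$reg, fu$out)
    list(obj = ob$out, reg = rg$out, feat = fu$out,
         cache = if (keepCache) list(r1 = r1, r2 = r2, r3 = r3, l2 = l2,
                                     l3 = l3, fu = fu, ob = ob, rg = rg,
                                     upDim = dim(up)) else NULL)
  }

  backward <- function(cache, gObj, gReg, gFeat) {
    L <- env$layers
    grads <- list()
    go <- nnConvBackward(L$obj, cache$ob$cache, gObj)
    gr <- nnConvBackward(L$reg, cache$rg$cache, gReg)
    grads$obj <- go[c("gw", "gb")]; grads$reg <- gr[c("gw", "gb")]
    gFuse <- go$gin + gr$gin + gFeat
    gf <- nnConvBackward(L$fuse, cache$fu$cache, gFuse)
    grads$fuse <- gf[c("gw", "gb")]
    gp <- gf$gin
    gl2 <- gp
    gUp <- array(0, cache$upDim)
    gUp[, seq_len(dim(gp)[2L]), seq_len(dim(gp)[3L])] <- gp
    gl3 <- upsample2BackwardCpp(gUp)
    g2l <- nnConvBackward(L$lat2, cache$l2$cache, gl2)
    g3l <- nnConvBackward(L$lat3, cache$l3$cache, gl3)
    grads$lat2 <- g2l[c("gw", "gb")]; grads$lat3 <- g3l[c("gw", "gb")]
    g3 <- nnConvBackward(L$conv3, cache$r3$cache, g3l$gin)
    grads$conv3 <- g3[c("gw", "gb")]
    g2 <- nnConvBackward(L$conv2, cache$r2$cache, g2l$gin + g3$gin)
    grads$conv2 <- g2[c("gw", "gb")]
    g1 <- nnConvBackward(L$conv1, cache$r1$cache, g2$gin)
    grads$conv1 <- g1[c("gw", "gb")]
    grads[names(env$layers)]
  }

  cellCenters <- function(dims) {
    nh <- dims[2L]; nw <- dims[3L]
    list(cx = matrix(rep((0:(nw - 1L)) * 4 + 1.5, each = nh), nh, nw),
         cy = matrix(rep((0:(nh - 1L)) * 4 + 1.5, nw), nh, nw))
  }

  boxesFromDeltas <- function(objP, reg, keepIdx) {
    cc <- cellCenters(dim(objP))
    A <- env$config@anchorPx
    out <- matrix(0, length(keepIdx), 5L,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1", "score")))
    for (r in seq_along(keepIdx)) {
      k <- keepIdx[r]
      i <- (k - 1L) %% dim(objP)[2L] + 1L
      j <- (k - 1L) %/% dim(objP)[2L] + 1L
      cx <- cc$cx[i, j] + reg[1L, i, j] * A
      cy <- cc$cy[i, j] + reg[2L, i, j] * A
      w <- A * exp(clamp(reg[3L, i, j], -3, 3))
      h <- A * exp(clamp(reg[4L, i, j], -3, 3))
      out[r, ] <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
                    objP[1L, i, j])
    }
    out
  }

  roiPool <- function(feat, box) {
    j0 <- clamp(floor(box[1L] / 4) + 1L, 1L, dim(feat)[3L])
    j1 <- clamp(ceiling(box[3L] / 4), j0, dim(feat)[3L])
    i0 <- clamp(floor(box[2L] / 4) + 1L, 1L, dim(feat)[2L])
    i1 <- clamp(ceiling(box[4L] / 4), i0, dim(feat)[2L])
    list(v = apply(feat[, i0:i1, j0:j1, drop = FALSE], 1L, mean),
         i0 = i0, i1 = i1, j0 = j0, j1 = j1)
  }

  env$trainStep <- function(batch) {
    totalLoss <- 0
    acc <- NULL
    roiGW <- 0 * env$roiW; roiGB <- 0
    for (sample in batch) {
      pix <- if (is(sample$image, "ScanImage")) sample$image@pixels
             else sample$image
      x <- imageToTensor(pix)
      fw <- forward(x, keepCache = TRUE)
      dims <- dim(fw$obj)
      cc <- cellCenters(dims)
      truth <- sample$boxes
      target <- matrix(0, dims[2L], dims[3L])
      matchIdx <- matrix(0L, dims[2L], dims[3L])
      for (b in seq_len(nrow(truth))) {
        sel <- cc$cx >= truth[b, 1L] & cc$cx < truth[b, 3L] &
               cc$cy >= truth[b, 2L] & cc$cy < truth[b, 4L]
        target[sel] <- 1
        matchIdx[sel] <- b
      }
      objP <- 1 / (1 + exp(-fw$obj))
      bce <- nnBCE(objP, array(target, dims))
      gObj <- array(bce$grad * objP * (1 - objP), dims)
      loss <- bce$loss
      # box regression on positive cells
      gReg <- array(0, dim(fw$reg))
      pos <- which(matchIdx > 0L)
      if (length(pos)) {
        A <- env$config@anchorPx
        for (k in pos) {
          i <- (k - 1L) %% dims[2L] + 1L
          j <- (k - 1L) %/% dims[2L] + 1L
          tb <- truth[matchIdx[i, j], ]
          tgt <- c(((tb[1L] + tb[3L]) / 2 - cc$cx[i, j]) / A,
                   ((tb[2L] + tb[4L]) / 2 - cc$cy[i, j]) / A,
                   log((tb[3L] - tb[1L]) / A), log((tb[4L] - tb[2L]) / A))
          dlt <- fw$reg[, i, j] - tgt
          loss <- loss + 0.5 * sum(dlt^2) / length(pos)
          gReg[, i, j] <- dlt / length(pos)
        }
      }
      # second stage: re-score pooled proposals
      nProp <- min(32L, length(fw$obj))
      propIdx <- order(-as.numeric(fw$obj))[seq_len(nProp)]
      props <- boxesFromDeltas(objP, fw$reg, propIdx)
      gFeat <- array(0, dim(fw$feat))
      for (r in seq_len(nrow(props))) {
        iou <- if (nrow(truth)) max(vapply(seq_len(nrow(truth)), function(b)
          boxIoU(props[r, ], truth[b, ]), 0)) else 0
        rp <- roiPool(fw$feat, props[r, ])
        z <- sum(rp$v * env$roiW) + env$roiB
        p <- 1 / (1 + exp(-z))
        t <- as.numeric(iou >= 0.5)
        p <- clamp(p, 1e-7, 1 - 1e-7)
        loss <- loss - (t * log(p) + (1 - t) * log(1 - p)) / nProp
        dz <- (p - t) / nProp
        roiGW <- roiGW + dz * rp$v
        roiGB <- roiGB + dz
        nCells <- (rp$i1 - rp$i0 + 1L) * (rp$j1 - rp$j0 + 1L)
        gFeat[, rp$i0:rp$i1, rp$j0:rp$j1] <-
          gFeat[, rp$i0:rp$i1, rp$j0:rp$j1] + dz * env$roiW / nCells
      }
      grads <- backward(fw$cache, gObj, gReg, gFeat)
      acc <- if (is.null(acc)) grads else
        mapply(function(a, b) list(gw = a$gw + b$gw, gb = a$gb + b$gb),
               acc, grads, SIMPLIFY = FALSE)
      totalLoss <- totalLoss + loss
    }
    if (!is.finite(totalLoss))
      psStop("divergence", "non-finite detector loss")
    # global gradient-norm clipping stabilizes the high published lr
    gnorm <- sqrt(sum(vapply(acc, function(g)
      sum(g$gw^2) + sum(g$gb^2), 0)) + sum(roiGW^2) + roiGB^2)
    maxNorm <- 1
    if (gnorm > maxNorm) {
      sc <- maxNorm / gnorm
      acc <- lapply(acc, function(g) list(gw = g$gw * sc, gb = g$gb * sc))
      roiGW <- roiGW * sc; roiGB <- roiGB * sc
    }
    r <- nnOptStep(env$opt, env$layers, acc)
    env$opt <- r$opt; env$layers <- r$layers
    env$roiM <- env$config@momentum * env$roiM + roiGW
    env$roiBM <- env$config@momentum * env$roiBM + roiGB
    env$roiW <- env$roiW - env$config@lr * env$roiM
    env$roiB <- env$roiB - env$config@lr * env$roiBM
    totalLoss / length(batch)
  }

  env$predict <- function(image) {
    pix <- if (is(image, "ScanImage")) image@pixels else image
    x <- imageToTensor(pix)
    fw <- forward(x, keepCache = FALSE)
    objP <- 1 / (1 + exp(-fw$obj))
    keep <- which(as.numeric(objP) > env$config@scoreThreshold)
    if (!length(keep))
      return(matrix(numeric(0), 0L, 5L,
                    dimnames = list(NULL,
                                    c("x0", "y0", "x1", "y1", "score"))))
    boxes <- boxesFromDeltas(objP, fw$reg, keep)
    for (r in seq_len(nrow(boxes))) {
      rp <- roiPool(fw$feat, boxes[r, ])
      p <- 1 / (1 + exp(-(sum(rp$v * env$roiW) + env$roiB)))
      boxes[r, "score"] <- sqrt(boxes[r, "score"] * p)
    }
    boxes[, c("x0", "x1")] <- clamp(boxes[, c("x0", "x1")], 0,
                                    dim(pix)[2L])
    boxes[, c("y0", "y1")] <- clamp(boxes[, c("y0", "y1")], 0,
                                    dim(pix)[1L])
    boxes <- boxes[boxes[, "x1"] > boxes[, "x0"] &
                   boxes[, "y1"] > boxes[, "y0"], , drop = FALSE]
    out <- nms(boxes, env$config@nmsIou)
    head(out, env$config@rpnProposals)
  }

  structure(list(trainStep = env$trainStep, predict = env$predict,
                 config = config, state = env), class = "psDetector")
}
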