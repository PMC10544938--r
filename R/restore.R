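#' Restoration model configuration
#'
#' Hyperparameters of the occlusion restoration model. The defaults are the
#' published working point of the full-scale model: 256 x 256 inputs,
#' batch 64, Adam with learning rate 2e-4, 500 epochs. `depth` and
#' `baseChannels` size the compact U-Net; `patchGrid = NA` lets the patch
#' discriminator output its natural score-map size (30 x 30 for 256 px
#' inputs under the standard 70 px receptive-field head), while an explicit
#' `N` pools the map to `N x N` (`N = 1` degenerates the patch head into a
#' second global head). `lossWeights` holds the adversarial and L1
#' reconstruction weights of the generator objective; `fusionWeights` the
#' global:patch mix of the fused discriminator (1:1 by default).
#'
#' @slot imageSize square input size, px.
#' @slot batchSize training batch size.
#' @slot optimizer `"adam"`.
#' @slot lr learning rate.
#' @slot maxEpochs full-scale epoch budget.
#' @slot depth number of encoder levels in the compact U-Net.
#' @slot baseChannels channels of the first encoder level.
#' @slot patchGrid patch-score grid `N`, or `NA` for the natural map.
#' @slot lossWeights named numeric `(adversarial, reconstruction)`.
#' @slot fusionWeights named numeric `(global, patch)`.
#' @export
setClass("RestorerConfig",
  slots = c(imageSize = "numeric", batchSize = "numeric",
            optimizer = "character", lr = "numeric", maxEpochs = "numeric",
            depth = "numeric", baseChannels = "numeric",
            patchGrid = "numeric", lossWeights = "numeric",
            fusionWeights = "numeric"),
  prototype = list(imageSize = 256, batchSize = 64, optimizer = "adam",
                   lr = 2e-4, maxEpochs = 500, depth = 4, baseChannels = 8,
                   patchGrid = NA_real_,
                   lossWeights = c(adversarial = 1, reconstruction = 100),
                   fusionWeights = c(global = 1, patch = 1)))

setValidity("RestorerConfig", function(object) {
  s <- object@imageSize
  if (s < 8 || bitwAnd(as.integer(s), as.integer(s) - 1L) != 0)
    return("imageSize must be a power of two >= 8")
  if (2^object@depth * 4 > s)
    return("imageSize must be a power-of-two multiple of the bottleneck")
  if (!object@optimizer %in% c("adam", "sgd")) return("unknown optimizer")
  TRUE
})

#' @rdname RestorerConfig-class
#' @param ... slot values overriding the defaults.
#' @export
RestorerConfig <- function(...) new("RestorerConfig", ...)

setMethod("show", "RestorerConfig", function(object) {
  cat(sprintf(
    "RestorerConfig: %dx%d, batch %d, %s lr %g, %d epochs, depth %d\n",
    object@imageSize, object@imageSize, object@batchSize, object@optimizer,
    object@lr, object@maxEpochs, object@depth))
})

#' Save and reload a restorer configuration
#'
#' JSON round trip of a [RestorerConfig-class]; `readRestorerConfig`
#' reconstructs an object equal to the one saved.
#'
#' @param config a `RestorerConfig`.
#' @param path JSON file path.
#' @export
writeRestorerConfig <- function(config, path) {
  sl <- slotNames(config)
  l <- lapply(sl, function(s) slot(config, s))
  names(l) <- sl
  jsonlite::write_json(l, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeRestorerConfig
#' @export
readRestorerConfig <- function(path) {
  l <- jsonlite::fromJSON(path)
  l$optimizer <- as.character(l$optimizer)
  for (nm in c("lossWeights", "fusionWeights")) l[[nm]] <- unlist(l[[nm]])
  if (is.null(l$patchGrid) || !length(l$patchGrid) ||
      is.na(l$patchGrid[1L])) l$patchGrid <- NA_real_
  names(l$lossWeights) <- c("adversarial", "reconstruction")
  names(l$fusionWeights) <- c("global", "patch")
  do.call(RestorerConfig, l)
}

generatorChannels <- function(config) {
  d <- config@depth
  pmin(config@baseChannels * 2^(seq_len(d) - 1L), 8L * config@baseChannels)
}

#' Build the U-Net restoration generator
#'
#' An encoder-decoder with skip connections: each encoder level halves the
#' spatial size with a stride-2 convolution; each decoder level doubles it
#' and concatenates the matching encoder feature map before convolving, so
#' low-level detail bypasses the bottleneck. The output has the input's
#' shape, with a sigmoid mapping to [0, 1] intensities.
#'
#' @param config a [RestorerConfig-class]; `imageSize` must be a power-of-two
#'   multiple of the bottleneck (`2^depth * 4`).
#' @param seed optional seed for weight initialization.
#' @return an object of class `psGenerator` with elements `layers` and
#'   `config`; apply it with [generatorForward()].
#' @export
buildGenerator <- function(config = RestorerConfig(), seed = NULL) {
  validObject(config)
  withSeed(seed, {
    d <- config@depth
    ch <- generatorChannels(config)
    enc <- vector("list", d)
    inC <- 3L
    for (i in seq_len(d)) {
      enc[[i]] <- nnConv(inC, ch[i], k = 4L, stride = 2L, pad = 1L, "lrelu")
      inC <- ch[i]
    }
    dec <- vector("list", max(d - 1L, 0L))
    for (i in seq_len(d - 1L)) {
      lvl <- d - i # decoder level produced by this conv
      dec[[i]] <- nnConv(ch[lvl + 1L] + ch[lvl], ch[lvl], k = 3L,
                         stride = 1L, pad = 1L, "lrelu")
    }
    final <- nnConv(ch[1L], 3L, k = 3L, stride = 1L, pad = 1L, "sigmoid")
    structure(list(layers = c(enc, dec, list(final)), depth = d,
                   channels = ch, config = config),
              class = "psGenerator")
  })
}

#' Feature-map ledger of the generator
#'
#' Spatial size and channel count of every stage, documenting the
#' halving-encoder / doubling-decoder schedule.
#'
#' @param config a [RestorerConfig-class].
#' @return data.frame with columns `stage`, `size`, `channels`.
#' @export
generatorLedger <- function(config = RestorerConfig()) {
  d <- config@depth; s <- config@imageSize
  ch <- generatorChannels(config)
  rows <- list(data.frame(stage = "input", size = s, channels = 3))
  for (i in seq_len(d))
    rows[[length(rows) + 1L]] <- data.frame(
      stage = sprintf("enc%d", i), size = s / 2^i, channels = ch[i])
  for (lvl in rev(seq_len(d - 1L)))
    rows[[length(rows) + 1L]] <- data.frame(
      stage = sprintf("dec%d", lvl), size = s / 2^lvl, channels = ch[lvl])
  rows[[length(rows) + 1L]] <- data.frame(stage = "output", size = s,
                                          channels = 3)
  do.call(rbind, rows)
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- a
  out[da[1L] + seq_len(db[1L]), , ] <- b
  out
}

#' Apply the generator
#'
#' @param gen a `psGenerator` from [buildGenerator()].
#' @param x input tensor `(3, S, S)` in `[0, 1]` (see `imageToTensor`).
#' @param keepCache keep layer caches for a backward pass.
#' @return `list(out, cache)`; `out` has the shape of `x`.
#' @export
generatorForward <- function(gen, x, keepCache = FALSE) {
  d <- gen$depth
  L <- gen$layers
  caches <- vector("list", length(L))
  encOut <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    r <- nnConvForward(L[[i]], h)
    caches[[i]] <- r$cache
    encOut[[i]] <- r$out
    h <- r$out
  }
  for (j in seq_len(d - 1L)) {
    lvl <- d - j
    up <- upsample2ForwardCpp(h)
    cat <- catChannels(up, encOut[[lvl]])
    r <- nnConvForward(L[[d + j]], cat)
    caches[[d + j]] <- r$cache
    h <- r$out
  }
  up <- upsample2ForwardCpp(h)
  r <- nnConvForward(L[[2L * d]], up)
  caches[[2L * d]] <- r$cache
  out <- r$out
  list(out = out,
       cache = if (keepCache) list(caches = caches, encOut = encOut) else NULL)
}

# Backward pass; returns per-layer grads and nothing for the input.
generatorBackward <- function(gen, cache, gout) {
  d <- gen$depth
  L <- gen$layers
  caches <- cache$caches
  grads <- vector("list", length(L))
  skipGrad <- vector("list", d)
  g <- nnConvBackward(L[[2L * d]], caches[[2L * d]], gout)
  grads[[2L * d]] <- g[c("gw", "gb")]
  h <- upsample2BackwardCpp(g$gin)
  for (j in rev(seq_len(d - 1L))) {
    lvl <- d - j
    g <- nnConvBackward(L[[d + j]], caches[[d + j]], h)
    grads[[d + j]] <- g[c("gw", "gb")]
    upC <- dim(g$gin)[1L] - gen$channels[lvl]
    gUp <- g$gin[seq_len(upC), , , drop = FALSE]
    skipGrad[[lvl]] <- g$gin[upC + seq_len(gen$channels[lvl]), , ,
                             drop = FALSE]
    h <- upsample2BackwardCpp(gUp)
  }
  for (i in rev(seq_len(d))) {
    if (!is.null(skipGrad[[i]])) h <- h + skipGrad[[i]]
    g <- nnConvBackward(L[[i]], caches[[i]], h)
    grads[[i]] <- g[c("gw", "gb")]
    h <- g$gin
  }
  grads
}

discriminatorSchedule <- function() {
  list(list(k = 4L, s = 2L, p = 1L), list(k = 4L, s = 2L, p = 1L),
       list(k = 4L, s = 2L, p = 1L), list(k = 4L, s = 1L, p = 1L),
       list(k = 4L, s = 1L, p = 1L))
}

#' Layer ledger of the patch discriminator head
#'
#' Output size after each convolution of the standard patch head (kernel 4;
#' strides 2, 2, 2, 1, 1) plus the receptive field of one output unit:
#' a 256 px input yields a 30 x 30 score map whose units each see a 70 x 70
#' patch.
#'
#' @param inputSize square input size, px.
#' @return list with `sizes` (per-layer outputs), `patchMap` (final map
#'   side), `receptiveField`.
#' @export
discriminatorLedger <- function(inputSize = 256L) {
  sch <- discriminatorSchedule()
  sizes <- convScheduleSizes(as.integer(inputSize), sch)
  list(sizes = sizes, patchMap = sizes[length(sizes)],
       receptiveField = convScheduleReceptiveField(sch))
}

#' Build the fused global/patch discriminator
#'
#' Both heads consume the same (condition, candidate) image pair,
#' concatenated to a 6-channel input, through a shared convolutional trunk.
#' The patch head scores every local patch, producing an `N x N` matrix of
#' probabilities (its natural size is 30 x 30 for 256 px inputs; an explicit
#' `patchGrid` pools it, and `patchGrid = 1` collapses it into a second
#' global score). The global head averages the trunk features and applies a
#' dense sigmoid unit, scoring the image as a whole. The fused adversarial
#' loss is the `fusionWeights`-weighted sum of both heads' losses.
#'
#' @param config a [RestorerConfig-class].
#' @param seed optional seed for weight initialization.
#' @return object of class `psDiscriminator`; apply with
#'   [discriminatorForward()].
#' @export
buildDiscriminator <- function(config = RestorerConfig(), seed = NULL) {
  withSeed(seed, {
    c0 <- max(4L, config@baseChannels %/% 2L)
    chs <- c(c0, 2L * c0, 4L * c0, 4L * c0)
    sch <- discriminatorSchedule()
    trunk <- vector("list", 4L)
    inC <- 6L
    for (i in 1:4) {
      s <- sch[[i]]
      trunk[[i]] <- nnConv(inC, chs[i], k = s$k, stride = s$s, pad = s$p,
                           "lrelu")
      inC <- chs[i]
    }
    patch <- nnConv(inC, 1L, k = 4L, stride = 1L, pad = 1L, "linear")
    gw <- rnorm(inC, 0, sqrt(1 / inC)); gb <- 0
    structure(list(trunk = trunk, patch = patch, gw = gw, gb = gb,
                   config = config), class = "psDiscriminator")
  })
}

poolToGrid <- function(z, N) {
  # average-pool an (1, H, W) logit map to (1, N, N)
  H <- dim(z)[2L]; W <- dim(z)[3L]
  ye <- round(seq(0, H, length.out = N + 1L))
  xe <- round(seq(0, W, length.out = N + 1L))
  out <- array(0, c(1L, N, N))
  for (i in seq_len(N)) for (j in seq_len(N))
    out[1L, i, j] <- mean(z[1L, (ye[i] + 1L):ye[i + 1L],
                            (xe[j] + 1L):xe[j + 1L]])
  list(out = out, ye = ye, xe = xe)
}

poolToGridBackward <- function(gout, ye, xe, H, W) {
  g <- array(0, c(1L, H, W))
  N <- dim(gout)[2L]
  for (i in seq_len(N)) for (j in seq_len(N)) {
    ys <- (ye[i] + 1L):ye[i + 1L]; xs <- (xe[j] + 1L):xe[j + 1L]
    g[1L, ys, xs] <- g[1L, ys, xs] + gout[1L, i, j] / (length(ys) * length(xs))
  }
  g
}

#' Apply the fused discriminator
#'
#' @param disc a `psDiscriminator`.
#' @param cond,cand condition and candidate tensors `(3, S, S)` in `[0, 1]`.
#' @param keepCache keep caches for a backward pass.
#' @return `list(global = scalar in (0,1), patch = N x N matrix in (0,1),
#'   cache)`.
#' @export
discriminatorForward <- function(disc, cond, cand, keepCache = FALSE) {
  x <- catChannels(cond, cand)
  caches <- vector("list", 5L)
  h <- x
  for (i in 1:4) {
    r <- nnConvForward(disc$trunk[[i]], h)
    caches[[i]] <- r$cache
    h <- r$out
  }
  trunkOut <- h
  r <- nnConvForward(disc$patch, h)
  caches[[5L]] <- r$cache
  z <- r$out # linear logits (1, n, n)
  N <- disc$config@patchGrid
  poolInfo <- NULL
  if (!is.na(N)) {
    p <- poolToGrid(z, as.integer(N))
    poolInfo <- p
    z <- p$out
  }
  patch <- 1 / (1 + exp(-z))
  feat <- apply(trunkOut, 1L, mean)
  gz <- sum(feat * disc$gw) + disc$gb
  glob <- 1 / (1 + exp(-gz))
  cache <- if (keepCache)
    list(caches = caches, trunkOut = trunkOut, zDim = dim(r$out),
         poolInfo = poolInfo, patch = patch, feat = feat, glob = glob)
    else NULL
  list(global = glob, patch = matrix(patch[1L, , ], dim(patch)[2L]),
       cache = cache)
}

# Backward pass for the fused adversarial loss with per-head targets.
# Returns gradients for all parameters and for the candidate input channels.
discriminatorBackward <- function(disc, cache, targetGlobal, targetPatch,
                                  wGlobal, wPatch) {
  patch <- cache$patch
  bcePatch <- nnBCE(patch, array(targetPatch, dim(patch)))
  gz <- array(wPatch * bcePatch$grad * patch * (1 - patch), dim(patch))
  if (!is.null(cache$poolInfo))
    gz <- poolToGridBackward(gz, cache$poolInfo$ye, cache$poolInfo$xe,
                             cache$zDim[2L], cache$zDim[3L])
  grads <- vector("list", 5L)
  g <- nnConvBackward(disc$patch, cache$caches[[5L]], gz)
  grads[[5L]] <- g[c("gw", "gb")]
  hGrad <- g$gin
  # global head
  glob <- cache$glob
  bceG <- nnBCE(glob, targetGlobal)
  dgz <- as.numeric(wGlobal * bceG$grad * glob * (1 - glob))
  ggw <- dgz * cache$feat
  ggb <- dgz
  perCell <- prod(dim(cache$trunkOut)[2:3])
  featGrad <- array(0, dim(cache$trunkOut))
  for (c in seq_along(disc$gw))
    featGrad[c, , ] <- dgz * disc$gw[c] / perCell
  hGrad <- hGrad + featGrad
  for (i in 4:1) {
    g <- nnConvBackward(disc$trunk[[i]], cache$caches[[i]], hGrad)
    grads[[i]] <- g[c("gw", "gb")]
    hGrad <- g$gin
  }
  gCand <- hGrad[4:6, , , drop = FALSE]
  loss <- wGlobal * bceG$loss + wPatch * bcePatch$loss
  list(loss = loss, grads = grads, ggw = ggw, ggb = ggb, gCand = gCand)
}

#' Train the restoration model
#'
#' Conditional-GAN training of the compact U-Net generator against the fused
#' global/patch discriminator: the generator minimizes the weighted sum of
#' the adversarial loss (being scored real by both heads) and an L1
#' reconstruction term; the discriminator maximizes real/fake separation on
#' (occluded, clean) versus (occluded, generated) pairs. Fully seeded and
#' deterministic for a fixed seed. Divergence (non-finite loss) raises an
#' error rather than being swallowed.
#'
#' @param pairs list of [PairedSample-class] training pairs (non-empty).
#' @param config a [RestorerConfig-class]; `imageSize` must match the pairs.
#' @param seed integer seed for initialization and batch order.
#' @param steps number of optimization steps (default: one pass per epoch
#'   budget is far beyond desk scale, so supply a small value; 100 covers
#'   the smoke contract).
#' @param checkpointEvery record the running reconstruction error every this
#'   many steps.
#' @return object of class `psRestorer`: `generator`, `discriminator`,
#'   `checkpoints` (data.frame step/reconLoss), and `restore(occluded)`
#'   mapping an 8-bit crop to its restored 8-bit crop.
#' @export
trainRestorer <- function(pairs, config = RestorerConfig(), seed = 0L,
                          steps = 100L, checkpointEvery = 25L) {
  if (length(pairs) == 0L) psStop("invalidArgument", "no training pairs")
  withSeed(seed, {
    gen <- buildGenerator(config)
    disc <- buildDiscriminator(config)
    wAdv <- config@lossWeights[["adversarial"]]
    wRec <- config@lossWeights[["reconstruction"]]
    fus <- config@fusionWeights / sum(config@fusionWeights)
    wG <- fus[["global"]]; wP <- fus[["patch"]]
    optG <- nnMakeOpt(gen$layers, config@optimizer, lr = config@lr)
    optD <- nnMakeOpt(c(disc$trunk, list(disc$patch)), config@optimizer,
                      lr = config@lr)
    gwM <- 0; gwV <- 0; gbM <- 0; gbV <- 0
    bs <- min(config@batchSize, length(pairs))
    tens <- lapply(pairs, function(p)
      list(occ = imageToTensor(p@occluded), clean = imageToTensor(p@clean)))
    ckSteps <- integer(0); ckLoss <- numeric(0)
    for (step in seq_len(steps)) {
      batch <- sample.int(length(tens), bs, replace = bs > length(tens))
      gGrads <- NULL; dGrads <- NULL
      dggw <- 0; dggb <- 0
      reconSum <- 0; lossSum <- 0
      for (ix in batch) {
        occ <- tens[[ix]]$occ; clean <- tens[[ix]]$clean
        gf <- generatorForward(gen, occ, keepCache = TRUE)
        fake <- gf$out
        # --- discriminator step contributions (real 1, fake 0) ---
        dr <- discriminatorForward(disc, occ, clean, keepCache = TRUE)
        br <- discriminatorBackward(disc, dr$cache, 1, 1, wG, wP)
        df <- discriminatorForward(disc, occ, fake, keepCache = TRUE)
        bf <- discriminatorBackward(disc, df$cache, 0, 0, wG, wP)
        stepD <- mapply(function(a, b) list(gw = a$gw + b$gw,
                                            gb = a$gb + b$gb),
                        br$grads, bf$grads, SIMPLIFY = FALSE)
        dGrads <- if (is.null(dGrads)) stepD else
          mapply(function(a, b) list(gw = a$gw + b$gw, gb = a$gb + b$gb),
                 dGrads, stepD, SIMPLIFY = FALSE)
        dggw <- dggw + br$ggw + bf$ggw; dggb <- dggb + br$ggb + bf$ggb
        # --- generator: adversarial (want fake scored 1) + L1 ---
        bg <- discriminatorBackward(disc, df$cache, 1, 1, wG, wP)
        recon <- mean(abs(fake - clean))
        gRecon <- array(sign(fake - clean) / length(fake), dim(fake))
        gOut <- wAdv * bg$gCand + wRec * gRecon
        gStep <- generatorBackward(gen, gf$cache, gOut)
        gGrads <- if (is.null(gGrads)) gStep else
          mapply(function(a, b) list(gw = a$gw + b$gw, gb = a$gb + b$gb),
                 gGrads, gStep, SIMPLIFY = FALSE)
        reconSum <- reconSum + recon
        lossSum <- lossSum + wAdv * bg$loss + wRec * recon
      }
      if (!is.finite(lossSum))
        psStop("divergence", "non-finite training loss at step %d", step)
      r <- nnOptStep(optG, gen$layers, gGrads)
      optG <- r$opt; gen$layers <- r$layers
      dl <- c(disc$trunk, list(disc$patch))
      r <- nnOptStep(optD, dl, dGrads)
      optD <- r$opt
      disc$trunk <- r$layers[1:4]; disc$patch <- r$layers[[5L]]
      # Adam on the global head's dense unit
      gwM <- 0.5 * gwM + 0.5 * dggw; gwV <- 0.999 * gwV + 0.001 * dggw^2
      gbM <- 0.5 * gbM + 0.5 * dggb; gbV <- 0.999 * gbV + 0.001 * dggb^2
      disc$gw <- disc$gw - config@lr * gwM / (sqrt(gwV) + 1e-8)
      disc$gb <- disc$gb - config@lr * gbM / (sqrt(gbV) + 1e-8)
      if (step %% checkpointEvery == 0L || step == 1L) {
        ckSteps <- c(ckSteps, step)
        ckLoss <- c(ckLoss, reconSum / bs)
      }
    }
    restorer <- list(generator = gen, discriminator = disc, config = config,
                     checkpoints = data.frame(step = ckSteps,
                                              reconLoss = ckLoss))
    restorer$restore <- function(occluded) {
      pix <- if (is(occluded, "PairedSample")) occluded@occluded else occluded
      out <- generatorForward(gen, imageToTensor(pix))$out
      tensorToImage(out)
    }
    class(restorer) <- "psRestorer"
    restorer
  })
}

#' Geometric occlusion restoration baseline
#'
#' Deterministic silhouette completion used for desk-scale pipeline runs:
#' the visible silhouette is segmented from the crop outside the known
#' occluder footprint, an ellipse is fitted by direct least squares to the
#' visible contour (excluding points bordering the occluder, which are
#' artifacts of the cut), and the hidden region is filled with grain
#' foreground wherever it falls inside the fitted ellipse. The restored
#' silhouette always contains the visible one.
#'
#' @param occluded `H x W x 3` 8-bit crop (or [PairedSample-class], whose
#'   occluded image and mask are used).
#' @param occluderMask logical matrix marking occluder pixels.
#' @param minVisibleFraction least visible fraction of the estimated full
#'   silhouette (fitted-ellipse area) required; below it restoration fails
#'   with an explicit `insufficientEvidence` error.
#' @return `list(pixels = restored 8-bit crop, mask = restored silhouette,
#'   visible = visible silhouette, ellipse = fit parameters)`.
#' @export
restoreBaseline <- function(occluded, occluderMask = NULL,
                            minVisibleFraction = 0.3) {
  if (is(occluded, "PairedSample")) {
    if (is.null(occluderMask)) occluderMask <- occluded@occluderMask
    occluded <- occluded@occluded
  }
  if (is.null(occluderMask))
    psStop("invalidArgument", "occluderMask is required")
  g <- redChannel(occluded)
  free <- !occluderMask
  if (sum(free) < 16L || length(unique(as.integer(g[free]))) < 2L)
    psStop("insufficientEvidence", "crop almost fully occluded")
  thr <- otsuThreshold(g[free])
  visAll <- (g > thr) & free
  if (!any(visAll))
    psStop("insufficientEvidence", "no visible grain silhouette")
  ct <- largestOuterContour(visAll)
  vis <- attr(ct, "mask")
  if (all(!occluderMask)) {
    return(list(pixels = occluded, mask = vis, visible = vis,
                ellipse = NULL))
  }
  # Drop contour points adjacent to the occluder (cut edges, not grain).
  dil <- ebToMat(EBImage::imageData(EBImage::dilate(
    matToEB(occluderMask),
    EBImage::makeBrush(5L, shape = "box")))) > 0
  pts <- unclass(ct)[, 1:2, drop = FALSE]
  px <- clamp(round(pts[, 1L]), 0, ncol(vis) - 1L)
  py <- clamp(round(pts[, 2L]), 0, nrow(vis) - 1L)
  onCut <- dil[cbind(py + 1L, px + 1L)]
  keepPts <- pts[!onCut, , drop = FALSE]
  if (nrow(keepPts) < 6L)
    psStop("insufficientEvidence", "too little unoccluded contour")
  e <- tryCatch(fitEllipse(keepPts), fitDegenerate = function(err)
    psStop("insufficientEvidence", "ellipse fit failed: %s",
           conditionMessage(err)))
  if (sum(vis) < minVisibleFraction * pi * e$a * e$b)
    psStop("insufficientEvidence",
           "visible silhouette below %.0f%% of the estimated grain",
           100 * minVisibleFraction)
  H <- nrow(vis); W <- ncol(vis)
  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), W), H, W)
  inside <- insideEllipse(X, Y, e)
  restoredMask <- vis | (inside & occluderMask)
  fillCol <- vapply(1:3, function(ch) median(occluded[, , ch][vis]), 0)
  bgCol <- vapply(1:3, function(ch) {
    sel <- !vis & free
    if (any(sel)) median(occluded[, , ch][sel]) else 0
  }, 0)
  out <- array(0, dim = dim(occluded))
  for (ch in 1:3) {
    plane <- as.numeric(occluded[, , ch])
    plane[occluderMask & restoredMask] <- fillCol[ch]
    plane[occluderMask & !restoredMask] <- bgCol[ch]
    out[, , ch] <- plane
  }
  list(pixels = quantize8(out), mask = restoredMask, visible = vis,
       ellipse = e)
}

#' Silhouette of a restored crop
#'
#' Post-threshold silhouette extraction for restored crops that guarantees
#' the restoration invariant: the returned mask is the union of the crop's
#' Otsu foreground with the visible silhouette it started from, so
#' restoration never shrinks visible evidence.
#'
#' @param restored 8-bit `H x W x 3` crop.
#' @param visibleMask logical matrix of the pre-restoration visible
#'   silhouette.
#' @return logical matrix.
#' @export
restoredSilhouette <- function(restored, visibleMask) {
  g <- redChannel(restored)
  thr <- tryCatch(otsuThreshold(g), degenerateImage = function(e) NULL)
  fg <- if (is.null(thr)) matrix(FALSE, nrow(g), ncol(g)) else g > thr
  fg | visibleMask
}
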