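checkPairs <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 1L)
    psStop("invalidArgument", "predicted and true must have equal length >= 1")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((pred - true)^2) / sum((true - mean(true))^2)`, the
#' agreement score used for predicted-vs-true trait comparisons. Equal to 1
#' for a perfect prediction, 0 for predicting the mean, and negative for
#' worse-than-mean predictions.
#'
#' @param predicted,true numeric vectors of equal length.
#' @return scalar score <= 1.
#' @examples
#' rSquared(c(1.1, 1.9, 3.2), c(1, 2, 3))
#' @export
rSquared <- function(predicted, true) {
  checkPairs(predicted, true)
  den <- sum((true - mean(true))^2)
  if (den == 0)
    psStop("degenerateInput", "true values are all identical")
  1 - sum((predicted - true)^2) / den
}

#' Mean absolute percentage error
#'
#' `MAPE = mean(|pred - true| / true) * 100`, in percent. Requires all true
#' values to be nonzero.
#'
#' @inheritParams rSquared
#' @return percentage >= 0.
#' @examples
#' mape(c(1, 5), c(2, 4)) # 37.5
#' @export
mape <- function(predicted, true) {
  checkPairs(predicted, true)
  if (any(true == 0))
    psStop("degenerateInput", "MAPE undefined for zero true values")
  mean(abs(predicted - true) / abs(true)) * 100
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((pred - true)^2))`, in the units of the trait.
#'
#' @inheritParams rSquared
#' @return error >= 0.
#' @export
rmse <- function(predicted, true) {
  checkPairs(predicted, true)
  sqrt(mean((predicted - true)^2))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(MAX_I^2 / MSE)` in dB, with `MAX_I = 255` for 8-bit
#' images. The MSE is the mean squared pixel difference; for multi-channel
#' images it is computed per channel and averaged. Identical images return
#' `Inf` (a legal comparison outcome, not an error).
#'
#' @param x,y equal-shape numeric arrays on the 0..255 scale.
#' @param maxI peak intensity (default 255).
#' @return PSNR in dB (possibly `Inf`).
#' @examples
#' a <- matrix(0, 4, 4); psnr(a, a + 16) # ~24.05 dB
#' @export
psnr <- function(x, y, maxI = 255) {
  if (!identical(dim(x), dim(y)))
    psStop("shapeMismatch", "images must have identical shape")
  mse <- mean((as.numeric(x) - as.numeric(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(maxI^2 / mse)
}

#' Structural similarity (global statistics)
#'
#' `SSIM = (2 mux muy + c1)(2 sxy + c2) /
#' ((mux^2 + muy^2 + c1)(sx^2 + sy^2 + c2))` computed from whole-image means,
#' variances and covariance (a single window), with the standard stabilizing
#' constants `c1 = (k1 maxI)^2`, `c2 = (k2 maxI)^2`. Symmetric in its
#' arguments and 1 exactly when the images are identical. A sliding-window
#' mean (`window` set to an odd size) is offered for comparability with
#' windowed SSIM implementations; the default is the global form.
#'
#' @param x,y equal-shape numeric arrays on the 0..255 scale.
#' @param k1,k2 stabilizing constants (defaults 0.01, 0.03).
#' @param maxI peak intensity (default 255).
#' @param window `NULL` for global statistics (default), or an odd window
#'   size for the mean of local SSIM values.
#' @return similarity in `[-1, 1]`.
#' @export
ssim <- function(x, y, k1 = 0.01, k2 = 0.03, maxI = 255, window = NULL) {
  if (!identical(dim(x), dim(y)))
    psStop("shapeMismatch", "images must have identical shape")
  c1 <- (k1 * maxI)^2; c2 <- (k2 * maxI)^2
  ssim1 <- function(a, b) {
    mx <- mean(a); my <- mean(b)
    vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
    cxy <- mean((a - mx) * (b - my))
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  xv <- as.numeric(x); yv <- as.numeric(y)
  if (is.null(window)) return(ssim1(xv, yv))
  if (window %% 2L != 1L) psStop("invalidArgument", "window must be odd")
  xm <- if (length(dim(x)) == 3L) apply(x, 1:2, mean) else as.matrix(x)
  ym <- if (length(dim(y)) == 3L) apply(y, 1:2, mean) else as.matrix(y)
  h <- (window - 1L) %/% 2L
  vals <- c()
  for (i in seq(1L + h, nrow(xm) - h, by = max(1L, h)))
    for (j in seq(1L + h, ncol(xm) - h, by = max(1L, h))) {
      wi <- (i - h):(i + h); wj <- (j - h):(j + h)
      vals <- c(vals, ssim1(as.numeric(xm[wi, wj]), as.numeric(ym[wi, wj])))
    }
  mean(vals)
}

#' Intersection over union of half-open boxes
#'
#' @param a,b numeric vectors `(x0, y0, x1, y1)`.
#' @return IoU in `[0, 1]`.
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
           (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Average precision of scored detections
#'
#' Greedy one-to-one matching: predictions are visited in descending score
#' order (ties by earlier index) and matched to the unmatched ground-truth
#' box of highest IoU, provided that IoU reaches the threshold. AP is the
#' area under the precision-recall curve with all-points interpolation
#' (precision replaced by its running maximum from the right).
#'
#' @param pred matrix with columns x0, y0, x1, y1, score.
#' @param truth matrix with columns x0, y0, x1, y1.
#' @param iouThr IoU threshold (e.g. 0.50, 0.75, 0.95).
#' @return AP in `[0, 1]`; 0 when there are no predictions, or no truths
#'   with nonempty predictions.
#' @export
averagePrecision <- function(pred, truth, iouThr = 0.5) {
  nT <- nrow(truth)
  nP <- if (is.null(pred)) 0L else nrow(pred)
  if (nP == 0L) return(0)
  if (nT == 0L) return(0)
  ord <- order(-pred[, "score"], seq_len(nP))
  matched <- logical(nT)
  tp <- numeric(nP); fp <- numeric(nP)
  for (k in seq_len(nP)) {
    p <- pred[ord[k], ]
    ious <- vapply(seq_len(nT), function(j)
      if (matched[j]) -1 else boxIoU(p, truth[j, ]), 0)
    j <- which.max(ious)
    if (ious[j] >= iouThr) {
      matched[j] <- TRUE; tp[k] <- 1
    } else fp[k] <- 1
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / nT
  precision <- ctp / (ctp + cfp)
  # all-points interpolation
  mpre <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  sum((r[-1L] - r[-length(r)]) * mpre)
}

#' @rdname averagePrecision
#' @param thresholds IoU thresholds to average over (defaults to the
#'   reporting set 0.50, 0.75, 0.95).
#' @return `meanAveragePrecision`: mean AP over the thresholds.
#' @export
meanAveragePrecision <- function(pred, truth,
                                 thresholds = c(0.50, 0.75, 0.95)) {
  mean(vapply(thresholds, function(t) averagePrecision(pred, truth, t), 0))
}

#' Bundle of evaluation metrics for predicted-vs-true comparisons
#'
#' @param predicted,true numeric vectors (trait comparison part); `NULL` to
#'   skip.
#' @param imagePairs optional list of `list(x, y)` image pairs for PSNR/SSIM
#'   (means over pairs; infinite PSNR values are dropped from the mean
#'   unless all are infinite).
#' @param pred,truth optional detection matrices for AP.
#' @return list of class `evalReport` with `r2`, `mape_pct`, `rmse`,
#'   `psnr_db`, `ssim`, `ap` (named by threshold), `map`.
#' @export
evalReport <- function(predicted = NULL, true = NULL, imagePairs = NULL,
                       pred = NULL, truth = NULL,
                       thresholds = c(0.50, 0.75, 0.95)) {
  rep <- list()
  if (!is.null(predicted)) {
    rep$r2 <- rSquared(predicted, true)
    rep$mape_pct <- mape(predicted, true)
    rep$rmse <- rmse(predicted, true)
  }
  if (!is.null(imagePairs)) {
    ps <- vapply(imagePairs, function(p) psnr(p$x, p$y), 0)
    finite <- ps[is.finite(ps)]
    rep$psnr_db <- if (length(finite)) mean(finite) else Inf
    rep$ssim <- mean(vapply(imagePairs, function(p) ssim(p$x, p$y), 0))
  }
  if (!is.null(pred)) {
    ap <- vapply(thresholds, function(t) averagePrecision(pred, truth, t), 0)
    names(ap) <- sprintf("%.2f", thresholds)
    rep$ap <- as.list(ap)
    rep$map <- mean(ap)
  }
  structure(rep, class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat("evalReport\n")
  for (n in setdiff(names(x), "ap"))
    cat(sprintf("  %-9s %s\n", n, format(x[[n]], digits = 4)))
  if (!is.null(x$ap))
    cat("  ap       ", paste(sprintf("%s: %.3f", names(x$ap),
                                     unlist(x$ap)), collapse = ", "), "\n")
  invisible(x)
}
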