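# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Otsu by direct evaluation of all 255 splits with plain means.
otsuBrute <- function(gray) {
  v <- as.integer(round(as.numeric(gray)))
  best <- -Inf; bestT <- NA_integer_
  n <- length(v)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; bestT <- t }
  }
  bestT
}

iouBrute <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# NMS by literal definition: repeatedly take the highest-scoring remaining
# box and delete every remaining box overlapping it above the threshold.
nmsBrute <- function(boxes, thr) {
  remaining <- seq_len(nrow(boxes))
  kept <- integer(0)
  while (length(remaining)) {
    sc <- boxes[remaining, "score"]
    top <- remaining[order(-sc, remaining)[1]]
    kept <- c(kept, top)
    remaining <- setdiff(remaining, top)
    drop <- remaining[vapply(remaining, function(j)
      iouBrute(boxes[top, ], boxes[j, ]) > thr, logical(1))]
    remaining <- setdiff(remaining, drop)
  }
  boxes[kept, , drop = FALSE]
}

# AP oracle: for every score cutoff compute the maximum bipartite matching
# (exhaustive over truth permutations, fine for <= 6 boxes), build the PR
# curve, integrate with the precision envelope.
apBrute <- function(pred, truth, thr) {
  nP <- nrow(pred); nT <- nrow(truth)
  if (nP == 0 || nT == 0) return(0)
  ord <- order(-pred[, "score"], seq_len(nP))
  feasible <- outer(seq_len(nP), seq_len(nT), Vectorize(function(i, j)
    iouBrute(pred[i, ], truth[j, ]) >= thr))
  # exhaustive maximum bipartite matching among the top-k predictions
  maxMatch <- function(k) {
    rec <- function(i, used) {
      if (i > k) return(0)
      best <- rec(i + 1, used) # leave prediction i unmatched
      for (j in setdiff(which(feasible[ord[i], ]), used))
        best <- max(best, 1 + rec(i + 1, c(used, j)))
      best
    }
    rec(1, integer(0))
  }
  tpk <- vapply(seq_len(nP), maxMatch, 0)
  recall <- tpk / nT
  precision <- tpk / seq_len(nP)
  mpre <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  sum((r[-1] - r[-length(r)]) * mpre)
}

# Flat test image with a bright axis-aligned rectangle.
rectImage <- function(H, W, y0, y1, x0, x1, fg = 200L, bg = 30L) {
  a <- array(bg, dim = c(H, W, 3L))
  a[(y0 + 1):(y1), (x0 + 1):(x1), ] <- fg
  storage.mode(a) <- "integer"
  a
}
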