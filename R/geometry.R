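# Low-level geometry used by the trait and restoration modules.
#
# Pixel (x, y) is 0-based and covers the square [x-0.5, x+0.5] x [y-0.5, y+0.5];
# boundary ("crack") polygons therefore have vertices at half-integer
# coordinates and their shoelace area equals the pixel count of the traced
# region (holes aside).

# Trace the crack boundary of the connected foreground region containing the
# top-most, then left-most, foreground pixel. `mask` is logical, rows = y.
# Returns an n x 2 matrix (x, y) of polygon vertices in order (closed
# implicitly; last vertex != first). Foreground is kept on the right of the
# walking direction, which yields a clockwise polygon in y-down coordinates.
traceCrackBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(x, y) x >= 0 && x < W && y >= 0 && y < H && mask[y + 1L, x + 1L]
  if (!any(mask)) psStop("emptyForeground", "mask has no foreground pixel")
  idx <- which(mask, arr.ind = TRUE)
  ymin <- min(idx[, 1L]) - 1L
  xmin <- min(idx[idx[, 1L] - 1L == ymin, 2L]) - 1L
  # Start at the pixel's top-left corner, walking east along its top edge.
  sx <- xmin - 0.5; sy <- ymin - 0.5
  dirs <- matrix(c(1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE) # E S W N
  d <- 1L
  px <- sx; py <- sy
  verts <- matrix(NA_real_, 4L * (sum(mask) + 4L), 2L)
  nv <- 0L
  repeat {
    nv <- nv + 1L
    verts[nv, ] <- c(px, py)
    nx <- px + dirs[d, 1L]; ny <- py + dirs[d, 2L]
    # Pixels ahead-left and ahead-right of the corner (nx, ny) w.r.t. d.
    dl <- dirs[(d + 2L) %% 4L + 1L, ] # left of d  (E -> N, S -> E, ...)
    dr <- dirs[d %% 4L + 1L, ]        # right of d (E -> S, S -> W, ...)
    # The two pixels adjacent to corner (nx, ny) that lie ahead:
    # front-left pixel center = corner + (d + left)/2, front-right likewise.
    fl <- fg(nx + (dirs[d, 1L] + dl[1L]) / 2, ny + (dirs[d, 2L] + dl[2L]) / 2)
    fr <- fg(nx + (dirs[d, 1L] + dr[1L]) / 2, ny + (dirs[d, 2L] + dr[2L]) / 2)
    if (fr && !fl) {
      # boundary continues straight
    } else if (!fr) {
      d <- d %% 4L + 1L              # turn right
    } else {
      d <- (d + 2L) %% 4L + 1L       # turn left (fl and fr both foreground)
    }
    px <- nx; py <- ny
    if (px == sx && py == sy && d == 1L) break
    if (nv > nrow(verts) - 2L) verts <- rbind(verts, verts) # safety growth
  }
  v <- verts[seq_len(nv), , drop = FALSE]
  colnames(v) <- c("x", "y")
  v
}

# Remove collinear runs from a closed polygon (keeps corners only).
dropCollinear <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(poly)
  prev <- poly[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- poly[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  cross <- (poly[, 1L] - prev[, 1L]) * (nxt[, 2L] - poly[, 2L]) -
           (poly[, 2L] - prev[, 2L]) * (nxt[, 1L] - poly[, 1L])
  keep <- abs(cross) > 1e-9
  if (!any(keep)) return(poly[1:2, , drop = FALSE])
  poly[keep, , drop = FALSE]
}

# Douglas-Peucker simplification of an open chain (keeps endpoints).
rdpChain <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    mid <- (i + 1L):(j - 1L)
    if (len < 1e-12) {
      d <- sqrt((pts[mid, 1L] - a[1L])^2 + (pts[mid, 2L] - a[2L])^2)
    } else {
      d <- abs((pts[mid, 1L] - a[1L]) * ab[2L] -
               (pts[mid, 2L] - a[2L]) * ab[1L]) / len
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- mid[k]; keep[m] <- TRUE
      stack <- c(stack, list(c(i, m)), list(c(m, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Douglas-Peucker on a closed polygon: split at the two mutually farthest
# vertices, simplify both chains, rejoin.
rdpClosed <- function(poly, eps) {
  n <- nrow(poly)
  if (n <= 4L) return(poly)
  ext <- farthestPair(poly)
  i <- min(ext$i, ext$j); j <- max(ext$i, ext$j)
  c1 <- poly[i:j, , drop = FALSE]
  c2 <- poly[c(j:n, 1L:i), , drop = FALSE]
  s1 <- rdpChain(c1, eps); s2 <- rdpChain(c2, eps)
  rbind(s1[-nrow(s1), , drop = FALSE], s2[-nrow(s2), , drop = FALSE])
}

# Maximum pairwise distance among points, exact, via convex hull then
# exhaustive pairs over hull vertices. Returns distance and achieving pair.
farthestPair <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(list(d = 0, i = 1L, j = 1L, p = pts[1L, ], q = pts[1L, ]))
  h <- if (n > 2L) grDevices::chull(pts[, 1L], pts[, 2L]) else seq_len(n)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  best <- c(-1, 1L, 1L)
  for (a in seq_len(m - 1L)) {
    dx <- hp[(a + 1L):m, 1L] - hp[a, 1L]
    dy <- hp[(a + 1L):m, 2L] - hp[a, 2L]
    d2 <- dx * dx + dy * dy
    k <- which.max(d2)
    if (d2[k] > best[1L]) best <- c(d2[k], a, a + k)
  }
  i <- h[best[2L]]; j <- h[best[3L]]
  list(d = sqrt(best[1L]), i = i, j = j, p = pts[i, ], q = pts[j, ])
}

shoelaceArea <- function(poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n - 1L) + 1L, 1L)
  abs(sum(poly[, 1L] * poly[nxt, 2L] - poly[nxt, 1L] * poly[, 2L])) / 2
}

polyArcLength <- function(poly, closed = TRUE) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  idx <- if (closed) c(seq_len(n - 1L) + 1L, 1L) else seq_len(n)[-1L]
  ref <- if (closed) seq_len(n) else seq_len(n - 1L)
  sum(sqrt((poly[idx, 1L] - poly[ref, 1L])^2 +
           (poly[idx, 2L] - poly[ref, 2L])^2))
}

# Analytic area of the superellipse |x/a|^n + |y/b|^n = 1.
superellipseArea <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# Analytic perimeter by numeric quadrature of the parametric boundary
# x = a cos(t)^(2/n), y = b sin(t)^(2/n), t in (0, pi/2), one quadrant.
superellipsePerimeter <- function(a, b, n) {
  f <- function(t) {
    ct <- cos(t); st <- sin(t)
    dx <- -a * (2 / n) * ct^(2 / n - 1) * st
    dy <- b * (2 / n) * st^(2 / n - 1) * ct
    sqrt(dx^2 + dy^2)
  }
  4 * integrate(f, 1e-9, pi / 2 - 1e-9, rel.tol = 1e-9)$value
}

# Direct least-squares ellipse fit (Fitzgibbon/Halir-Flusser) to 2-D points.
# Returns list(cx, cy, a, b, theta) with a >= b, or signals fitDegenerate.
fitEllipse <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  if (length(x) < 6L) psStop("fitDegenerate", "too few points for ellipse fit")
  mx <- mean(x); my <- mean(y); s <- max(stats::sd(x), stats::sd(y), 1e-9)
  x <- (x - mx) / s; y <- (y - my) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    psStop("fitDegenerate", "singular system in ellipse fit"))
  M <- S1 + S2 %*% T3
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1L, ]) * Re(ev$vectors[3L, ]) -
    Re(ev$vectors[2L, ])^2
  ok <- which(cond > 0)
  if (!length(ok)) psStop("fitDegenerate", "no elliptical solution")
  a1 <- Re(ev$vectors[, ok[1L]])
  coef <- c(a1, as.numeric(T3 %*% a1)) # A B C D E F in scaled frame
  A <- coef[1L]; B <- coef[2L]; C <- coef[3L]
  D <- coef[4L]; E <- coef[5L]; FF <- coef[6L]
  M33 <- matrix(c(A, B / 2, B / 2, C), 2L)
  Mfull <- matrix(c(A, B / 2, D / 2, B / 2, C, E / 2, D / 2, E / 2, FF), 3L)
  d33 <- det(M33)
  if (d33 <= 0) psStop("fitDegenerate", "not an ellipse")
  ctr <- solve(M33, -c(D / 2, E / 2))
  k <- -det(Mfull) / d33
  eg <- eigen(M33, symmetric = TRUE) # values decreasing
  if (any(k / eg$values <= 0))
    psStop("fitDegenerate", "degenerate ellipse axes")
  semis <- sqrt(k / eg$values)
  imaj <- which.max(semis)
  ax <- semis[imaj]; bx <- semis[-imaj]
  vmaj <- eg$vectors[, imaj]
  th <- atan2(vmaj[2L], vmaj[1L])
  list(cx = ctr[1L] * s + mx, cy = ctr[2L] * s + my,
       a = ax * s, b = bx * s, theta = th)
}

# Points strictly inside an ellipse, vectorized over (x, y).
insideEllipse <- function(x, y, e) {
  u <- (x - e$cx) * cos(e$theta) + (y - e$cy) * sin(e$theta)
  v <- -(x - e$cx) * sin(e$theta) + (y - e$cy) * cos(e$theta)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}
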