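# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. seed = NULL means "use the current RNG stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Quantize a numeric array in [0, 255] to 8-bit integers.
quantize8 <- function(x) {
  x <- clamp(round(x), 0, 255)
  storage.mode(x) <- "integer"
  x
}

# Structured error helper: all package errors carry a subclass so callers can
# distinguish degenerate inputs from programming errors.
psStop <- function(subclass, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(subclass, "panicleScanError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# H x W x 3 (rows = y) <-> EBImage Image (x, y, c)
asEBImage <- function(pixels) {
  EBImage::Image(aperm(pixels, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

fromEBImage <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  quantize8(aperm(a, c(2L, 1L, 3L)) * 255)
}

# Matrix (rows = y) <-> EBImage grayscale (x, y); values passed through.
matToEB <- function(m) EBImage::Image(t(m))
ebToMat <- function(img) t(EBImage::imageData(img))

isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
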