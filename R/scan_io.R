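#' Physical scale of a scan from its resolution
#'
#' Converts a scanner resolution in dots per inch to the side length of one
#' pixel in millimetres, `25.4 / dpi`. A 600 dpi scan resolves 0.0423 mm per
#' pixel, the working scale of panicle scanning.
#'
#' @param dpi resolution in dots per inch (> 0).
#' @return length of one pixel in mm.
#' @examples
#' mmPerPixel(600)   # 0.04233...
#' mmPerPixel(25.4)  # exactly 1 mm per pixel
#' @export
mmPerPixel <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0)
    psStop("invalidArgument", "dpi must be a single positive number, got %s",
           deparse(dpi))
  25.4 / dpi
}

#' Centered crop of a scan
#'
#' Crops the central `outW x outH` window of a scan, e.g. trimming a
#' 7200 x 10200 raster to the 5700 x 6800 region holding the panicle.
#' The resolution is preserved. Offsets are `floor((dim - out) / 2)`; they are
#' returned as an attribute so downstream coordinates can be mapped back.
#'
#' @param image a [ScanImage-class].
#' @param outW,outH crop width and height in px (each <= image dimension).
#' @return A [ScanImage-class] with attribute `offset = c(x0, y0)`.
#' @examples
#' img <- ScanImage(array(0L, dim = c(10, 10, 3)), 600)
#' dim(cropCenter(img, 4, 4))
#' @export
cropCenter <- function(image, outW, outH) {
  stopifnot(is(image, "ScanImage"))
  d <- dim(image@pixels)
  if (!isCount(outW) || !isCount(outH) || outW < 1 || outH < 1)
    psStop("invalidArgument", "crop dimensions must be positive integers")
  if (outW > d[2L] || outH > d[1L])
    psStop("invalidArgument",
           "requested crop %d x %d exceeds image %d x %d", outW, outH,
           d[2L], d[1L])
  x0 <- (d[2L] - outW) %/% 2L
  y0 <- (d[1L] - outH) %/% 2L
  out <- ScanImage(image@pixels[(y0 + 1L):(y0 + outH),
                                (x0 + 1L):(x0 + outW), , drop = FALSE],
                   image@dpi)
  attr(out, "offset") <- c(x0 = x0, y0 = y0)
  out
}

#' Seeded dataset split by ratio
#'
#' Randomly partitions items into parts proportional to `ratio` (for example
#' 2:1:1 into training/validation/test, or 8:2 into training/validation).
#' Items are shuffled with the given seed and then sliced; floor sizes are
#' used with the remainder given to the earliest parts, so 160 items at
#' (2, 1, 1) give 80/40/40 and 2000 at (8, 2) give 1600/400.
#'
#' @param items vector or list to partition (non-empty).
#' @param ratio integer vector of part weights (sum > 0).
#' @param seed integer seed controlling the shuffle.
#' @return List of partitions (same type as `items`), disjoint with union
#'   equal to the input; deterministic for a fixed seed.
#' @examples
#' lengths(splitDataset(1:160, c(2, 1, 1), seed = 1))
#' @export
splitDataset <- function(items, ratio, seed = 0L) {
  n <- length(items)
  if (n < 1L) psStop("invalidArgument", "items must be non-empty")
  if (any(ratio < 0) || sum(ratio) <= 0)
    psStop("invalidArgument", "ratio parts must be >= 0 and sum > 0")
  sizes <- floor(n * ratio / sum(ratio))
  rem <- n - sum(sizes)
  if (rem > 0) { # remainder to the earliest parts
    give <- seq_len(rem)
    sizes[give] <- sizes[give] + 1L
  }
  perm <- withSeed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ratio))
  for (i in seq_along(ratio)) {
    out[[i]] <- if (sizes[i] > 0) items[perm[starts[i]:ends[i]]] else items[0]
  }
  out
}

#' Read a scan image from disk
#'
#' Loads a PNG/TIFF/JPEG file as an 8-bit RGB [ScanImage-class]. Grayscale
#' files are expanded to three identical channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path image file path.
#' @param dpi scanner resolution of the file (dots per inch).
#' @return A [ScanImage-class].
#' @export
readScan <- function(path, dpi) {
  if (!file.exists(path))
    psStop("fileNotFound", "no such image file: %s", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3L] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  }
  ScanImage(quantize8(aperm(a, c(2L, 1L, 3L)) * 255), dpi)
}

#' Write a scan image to disk
#'
#' @param image a [ScanImage-class].
#' @param path output file path; format from the extension (.png/.tiff/.jpg).
#' @return `path`, invisibly.
#' @export
writeScan <- function(image, path) {
  stopifnot(is(image, "ScanImage"))
  EBImage::writeImage(asEBImage(image@pixels), path)
  invisible(path)
}

traitColumns <- c("grain_id", "panicle_id", "length_mm", "width_mm",
                  "area_mm2", "perimeter_mm", "lw_ratio", "ap_ratio",
                  "circularity", "eq_minor_mm")

#' Write and read per-grain trait tables
#'
#' Comma-separated, header row, UTF-8, '.' decimal; one row per grain. The
#' round trip preserves numeric fields to full double precision (values are
#' written with 15 significant digits).
#'
#' @param rows data.frame of per-grain traits.
#' @param path CSV path.
#' @return `writeTraits` returns `path` invisibly; `readTraits` returns the
#'   data.frame.
#' @export
writeTraits <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, logical(1))
  out <- rows
  out[num] <- lapply(rows[num], function(v) formatC(v, digits = 15,
                                                    format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTraits
#' @export
readTraits <- function(path) {
  if (!file.exists(path))
    psStop("fileNotFound", "no such trait table: %s", path)
  df <- tryCatch(read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) psStop("parseError",
                                            "cannot parse trait CSV %s: %s",
                                            path, conditionMessage(e)),
                 warning = function(w) psStop("parseError",
                                              "cannot parse trait CSV %s: %s",
                                              path, conditionMessage(w)))
  if (ncol(df) < 2L)
    psStop("parseError", "trait CSV %s does not look comma-separated", path)
  df
}

#' Read and write COCO-style detection annotations
#'
#' The interchange JSON holds `images` (id, file_name, width, height),
#' `annotations` (id, image_id, bbox as `[x, y, w, h]`, area, and optionally
#' score) and a single `grain` category. Internally boxes are half-open
#' corner matrices `(x0, y0, x1, y1)`; conversion is `x1 = x + w`,
#' `y1 = y + h`.
#'
#' @param path JSON file path.
#' @return `readCoco` returns `list(images = data.frame, boxes = named list
#'   of per-image box matrices)`; matrices gain a `score` column when the
#'   file carries scores.
#' @export
readCoco <- function(path) {
  if (!file.exists(path)) psStop("fileNotFound", "no such file: %s", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  imgs <- as.data.frame(j$images)
  ann <- as.data.frame(j$annotations)
  boxes <- list()
  for (i in seq_len(nrow(imgs))) {
    id <- imgs$id[i]
    rows <- ann[ann$image_id == id, , drop = FALSE]
    bb <- do.call(rbind, rows$bbox)
    if (is.null(bb)) bb <- matrix(numeric(0), 0, 4)
    m <- cbind(x0 = bb[, 1], y0 = bb[, 2],
               x1 = bb[, 1] + bb[, 3], y1 = bb[, 2] + bb[, 4])
    if (!is.null(rows$score)) m <- cbind(m, score = rows$score)
    boxes[[as.character(id)]] <- m
  }
  list(images = imgs, boxes = boxes)
}

#' @rdname readCoco
#' @param images data.frame with columns id, file_name, width, height.
#' @param boxes named list (by image id) of box matrices with columns
#'   x0, y0, x1, y1 and optionally score.
#' @export
writeCoco <- function(images, boxes, path) {
  anns <- list(); k <- 0L
  for (id in names(boxes)) {
    m <- boxes[[id]]
    for (r in seq_len(nrow(m))) {
      k <- k + 1L
      a <- list(id = k, image_id = as.numeric(id), category_id = 1L,
                bbox = c(m[r, "x0"], m[r, "y0"],
                         m[r, "x1"] - m[r, "x0"], m[r, "y1"] - m[r, "y0"]),
                area = (m[r, "x1"] - m[r, "x0"]) * (m[r, "y1"] - m[r, "y0"]))
      if ("score" %in% colnames(m)) a$score <- m[r, "score"]
      anns[[k]] <- a
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = list(list(id = 1L, name = "grain"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
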