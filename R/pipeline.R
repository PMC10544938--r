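#' Pipeline configuration
#'
#' Serializable configuration of the end-to-end run: scan resolution,
#' detector and restorer choice, SD convention for panicle aggregation,
#' thousand-grain sample size, ROI padding, and the master seed.
#'
#' @slot dpi scan resolution assumed for inputs without their own.
#' @slot detector `"baseline"` (Otsu + watershed) or `"frcnn"` (trainable
#'   contract; requires a trained model).
#' @slot restorer `"none"`, `"baseline"` (ellipse completion) or
#'   `"learned"`.
#' @slot sdType `"sample"` or `"population"`.
#' @slot thousandN thousand-grain sample size.
#' @slot roiPad padding added around detection boxes before measurement, px.
#' @slot seed master seed.
#' @export
setClass("PipelineConfig",
  slots = c(dpi = "numeric", detector = "character", restorer = "character",
            sdType = "character", thousandN = "numeric", roiPad = "numeric",
            seed = "numeric"),
  prototype = list(dpi = 150, detector = "baseline", restorer = "baseline",
                   sdType = "sample", thousandN = 1000, roiPad = 4,
                   seed = 0))

setValidity("PipelineConfig", function(object) {
  if (!object@detector %in% c("baseline", "frcnn"))
    return("detector must be 'baseline' or 'frcnn'")
  if (!object@restorer %in% c("none", "baseline", "learned"))
    return("restorer must be 'none', 'baseline' or 'learned'")
  if (!object@sdType %in% c("sample", "population"))
    return("sdType must be 'sample' or 'population'")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param ... slot values overriding the defaults.
#' @export
PipelineConfig <- function(...) new("PipelineConfig", ...)

#' Save and reload a pipeline configuration
#'
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
  sl <- slotNames(config)
  l <- lapply(sl, function(s) slot(config, s)); names(l) <- sl
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  l <- jsonlite::fromJSON(path)
  do.call(PipelineConfig, l)
}

cropRoi <- function(pix, box, pad) {
  H <- dim(pix)[1L]; W <- dim(pix)[2L]
  x0 <- max(0L, floor(box[1L]) - pad); x1 <- min(W, ceiling(box[2L]) + pad)
  y0 <- max(0L, floor(box[3L]) - pad); y1 <- min(H, ceiling(box[4L]) + pad)
  list(pix = pix[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE],
       x0 = x0, y0 = y0)
}

#' Run the full phenotyping cascade on panicle scans
#'
#' Executes scan -> detect -> (restore) -> measure -> aggregate for each
#' input scene. Each detected grain becomes one trait row; each scene
#' contributes one summary row carrying the 15 panicle traits. When a
#' restorer is enabled it is applied per ROI between detection and
#' measurement, with the footprint of neighbouring detections serving as the
#' occluder mask; without restoration the raw ROI is measured (the ablation
#' path). Per-grain failures are logged and skipped, not fatal.
#'
#' @param scans list of [ScanImage-class] objects (or image paths, read at
#'   `config@dpi`).
#' @param config a [PipelineConfig-class].
#' @param annotations optional list of [SceneAnnotation-class] truths, one
#'   per scan, enabling an evaluation report.
#' @param restorerModel trained `psRestorer` (required when
#'   `config@restorer == "learned"`).
#' @return list with `grains` (per-grain data.frame), `panicles` (one row of
#'   the 15 traits per scene), `log` (per-stage counts and timings), and
#'   `report` (an `evalReport` comparing counts and panicle means to truth,
#'   when annotations are given).
#' @export
runPipeline <- function(scans, config = PipelineConfig(),
                        annotations = NULL, restorerModel = NULL) {
  validObject(config)
  if (config@restorer == "learned" && is.null(restorerModel))
    psStop("invalidArgument", "learned restorer requires restorerModel")
  grains <- list(); panicles <- list(); log <- list()
  for (s in seq_along(scans)) {
    t0 <- proc.time()[["elapsed"]]
    scan <- scans[[s]]
    if (is.character(scan)) scan <- readScan(scan, config@dpi)
    mmpp <- mmPerPx(scan)
    det <- detectBaseline(scan, returnLabels = TRUE)
    boxes <- det$boxes
    nFail <- 0L
    rows <- list()
    for (g in seq_len(nrow(boxes))) {
      roi <- cropRoi(scan@pixels, boxes[g, c("x0", "x1", "y0", "y1")],
                     as.integer(config@roiPad))
      sub <- det$labels[(roi$y0 + 1L):(roi$y0 + dim(roi$pix)[1L]),
                        (roi$x0 + 1L):(roi$x0 + dim(roi$pix)[2L])]
      measured <- tryCatch({
        pix <- roi$pix
        if (config@restorer == "baseline") {
          occMask <- sub != 0L & sub != g
          if (any(occMask)) {
            occMask <- ebToMat(EBImage::imageData(EBImage::dilate(
              matToEB(occMask), EBImage::makeBrush(3L, "box")))) > 0
            res <- restoreBaseline(pix, occMask)
            pix <- res$pixels
          }
        } else if (config@restorer == "learned") {
          pix <- restorerModel$restore(fitToSquare(pix,
            restorerModel$config@imageSize))
        }
        extractGrainTraits(pix, mmpp)
      }, panicleScanError = function(e) NULL)
      if (is.null(measured)) { nFail <- nFail + 1L; next }
      measured$grain_id <- length(rows) + 1L
      measured$panicle_id <- s
      rows[[length(rows) + 1L]] <- measured
    }
    sceneGrains <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(sceneGrains)) {
      grains[[s]] <- sceneGrains[, c("grain_id", "panicle_id", "length_mm",
                                     "width_mm", "area_mm2", "perimeter_mm",
                                     "lw_ratio", "ap_ratio", "circularity",
                                     "eq_minor_mm")]
      panicles[[s]] <- cbind(panicle_id = s,
                             aggregatePanicle(sceneGrains, config@sdType))
    }
    log[[s]] <- list(scene = s, detected = nrow(boxes),
                     measured = if (is.null(sceneGrains)) 0L
                                else nrow(sceneGrains),
                     failed = nFail,
                     seconds = proc.time()[["elapsed"]] - t0)
  }
  out <- list(
    grains = if (length(grains)) do.call(rbind, grains) else
      data.frame(),
    panicles = if (length(panicles)) do.call(rbind, panicles) else
      data.frame(),
    log = log)
  if (!is.null(annotations) && length(annotations) == length(scans) &&
      nrow(out$panicles) > 0L) {
    predGN <- out$panicles$GN
    trueGN <- vapply(annotations[out$panicles$panicle_id], length, 0L)
    out$report <- evalReport(predicted = predGN, true = trueGN)
  }
  out
}

# Center an ROI crop on a square canvas of the restorer's input size,
# padding with the crop's corner background colour.
fitToSquare <- function(pix, size) {
  H <- dim(pix)[1L]; W <- dim(pix)[2L]
  if (H == size && W == size) return(pix)
  out <- array(0L, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- pix[1L, 1L, ch]
  y0 <- max(0L, (size - H) %/% 2L); x0 <- max(0L, (size - W) %/% 2L)
  hs <- min(H, size); ws <- min(W, size)
  out[y0 + seq_len(hs), x0 + seq_len(ws), ] <-
    pix[seq_len(hs), seq_len(ws), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Score the pipeline on simulated scenes
#'
#' Generates `nScenes` synthetic panicle scenes, runs the pipeline, and
#' compares predictions against the generator's exact truth: grain counts
#' (GN) and the panicle means of length, width, perimeter and projection
#' area. Deterministic for a fixed seed.
#'
#' @param config a [PipelineConfig-class].
#' @param nScenes number of simulated scenes.
#' @param seed integer seed.
#' @param grainRange min/max grains per scene (sampled uniformly).
#' @param occlusionMax occlusion ceiling passed to the generator.
#' @param width,height scene canvas, px.
#' @return list with `counts` (per-scene predicted/true GN),
#'   `traits` (per-scene predicted/true panicle means), and `report`
#'   (named list of `evalReport`s per quantity).
#' @export
benchmarkPipeline <- function(config = PipelineConfig(), nScenes = 20L,
                              seed = 0L, grainRange = c(45L, 250L),
                              occlusionMax = 0, width = 1425L,
                              height = 1700L) {
  mmpp <- mmPerPixel(config@dpi)
  counts <- data.frame(); traits <- data.frame()
  for (i in seq_len(nScenes)) {
    n <- withSeed(seed + 7919L * i,
                  sample(grainRange[1L]:grainRange[2L], 1L))
    sc <- generateScene(n, occlusionMax = occlusionMax, mmPerPx = mmpp,
                        width = width, height = height,
                        seed = seed + 104729L + i)
    run <- runPipeline(list(sc$image), config)
    tru <- sceneTruths(sc$annotation)
    if (nrow(run$panicles) == 0L) next
    counts <- rbind(counts, data.frame(scene = i, pred = run$panicles$GN,
                                       true = length(sc$annotation)))
    traits <- rbind(traits, data.frame(
      scene = i,
      mgl_pred = run$panicles$MGL, mgl_true = mean(tru$length_mm),
      mgw_pred = run$panicles$MGW, mgw_true = mean(tru$width_mm),
      mgp_pred = run$panicles$MGP, mgp_true = mean(tru$perimeter_mm),
      mgpa_pred = run$panicles$MGPA, mgpa_true = mean(tru$area_mm2)))
  }
  rep <- list(
    count = evalReport(predicted = counts$pred, true = counts$true),
    length = evalReport(predicted = traits$mgl_pred, true = traits$mgl_true),
    width = evalReport(predicted = traits$mgw_pred, true = traits$mgw_true),
    perimeter = evalReport(predicted = traits$mgp_pred,
                           true = traits$mgp_true),
    area = evalReport(predicted = traits$mgpa_pred, true = traits$mgpa_true))
  list(counts = counts, traits = traits, report = rep)
}
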