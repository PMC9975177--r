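#' Per-resolution anomaly map
#'
#' Scores every patch of the image at one resolution and paints each
#' patch's score onto all pixels of its tile, producing a full-resolution
#' map that is piecewise-constant on the size-s grid.
#'
#' @inheritParams scoreImagePatches
#' @return an [AnomalyMap-class] at the image resolution.
#' @export
resolutionMap <- function(image, encoder, db, kind = .similarityKinds,
                          d = NULL) {
  kind <- match.arg(kind)
  ps <- scoreImagePatches(image, encoder, db, kind, d)
  s <- patchSize(encoder)
  g <- nrow(image) %/% s
  grid <- matrix(0, g, g)
  grid[cbind(ps$gy + 1L, ps$gx + 1L)] <- ps$score
  new("AnomalyMap", map = kronecker(grid, matrix(1, s, s)),
      sizePx = as.integer(s), fused = FALSE)
}

#' Fit score calibration on validation normals
#'
#' Records, per patch size, the 1st and 99th percentiles of the patch
#' anomaly scores observed on normal validation images. These robust
#' bounds rescale raw per-resolution scores to a common [0, 1] range
#' before fusion, so that the fixed image-level threshold is comparable
#' across images (a per-image min-max rescaling would force every image's
#' maximum to 1 and make any fixed threshold vacuous).
#'
#' @param scoresBySize named list (per patch size) of numeric vectors of
#'   raw patch scores collected over normal validation images.
#' @param threshold image-level decision threshold in (0, 1); default 0.5.
#' @param epsilon floor applied to calibrated scores before multiplicative
#'   fusion; default 1e-6.
#' @param probs length-2 calibration quantiles; default `c(0.01, 0.99)`.
#' @return a [ScoreCalibration-class].
#' @export
fitCalibration <- function(scoresBySize, threshold = 0.5, epsilon = 1e-6,
                           probs = c(0.01, 0.99)) {
  .check(length(scoresBySize) >= 1L && !is.null(names(scoresBySize)),
         "scoresBySize must be a named list (names = patch sizes)")
  qs <- lapply(scoresBySize, function(s)
    stats::quantile(s, probs = probs, names = FALSE, type = 7))
  qLo <- vapply(qs, `[`, numeric(1), 1L)
  qHi <- vapply(qs, `[`, numeric(1), 2L)
  # guard degenerate (constant-score) calibration sets
  flat <- qHi <= qLo
  qHi[flat] <- qLo[flat] + 1e-12
  new("ScoreCalibration", qLo = qLo, qHi = qHi, threshold = threshold,
      epsilon = epsilon)
}

# internal: rescale one raw per-resolution map to [epsilon, 1]
.calibrateMap <- function(m, calibration, size) {
  key <- as.character(size)
  .check(key %in% names(calibration@qLo),
         "calibration has no quantiles for patch size ", size)
  x <- (m - calibration@qLo[[key]]) /
    (calibration@qHi[[key]] - calibration@qLo[[key]])
  pmin(pmax(x, calibration@epsilon), 1)
}

#' Fuse per-resolution anomaly maps
#'
#' Combines the per-resolution maps into the final anomaly map by
#' element-wise multiplication with per-resolution weights. Raw maps are
#' first rescaled to [epsilon, 1] by the calibration quantiles. Two weight
#' semantics are provided:
#'
#' * `"geometric"` (default): weights act as exponents and the product is
#'   renormalized by the weighted geometric mean,
#'   `A_final = exp( sum_i w_i log A_i / sum_i w_i )`. This keeps the map
#'   in [0, 1] without per-image rescaling, coincides with the plain
#'   k-th-root normalization when all weights are 1, and makes the weights
#'   ranking-relevant (scaling all weights by one constant changes
#'   nothing).
#' * `"literal"`: scalar weights multiply the maps,
#'   `A_final = ( prod_i w_i A_i )^(1/k)` clipped to [0, 1]. Under any
#'   scale normalization the product of the scalar weights is a global
#'   constant, so this mode leaves rankings insensitive to the weights; it
#'   is retained for fidelity experiments.
#'
#' Maps are fused in canonical (increasing patch size, fused-last) order,
#' so the result is bit-identical under any input ordering.
#'
#' @param maps list of per-resolution [AnomalyMap-class] objects (raw
#'   scores), all at the same pixel dimensions.
#' @param weights numeric vector of per-resolution weights, named by patch
#'   size or given in increasing-size order; all >= 0, at least one > 0.
#' @param calibration a [ScoreCalibration-class].
#' @param mode `"geometric"` or `"literal"`.
#' @return a fused [AnomalyMap-class] with entries in [0, 1].
#' @export
fuseMaps <- function(maps, weights, calibration,
                     mode = c("geometric", "literal")) {
  mode <- match.arg(mode)
  .check(length(maps) >= 1L, "no maps to fuse")
  sizes <- vapply(maps, patchSize, integer(1))
  .check(!anyNA(sizes), "fuse expects per-resolution (non-fused) maps")
  ord <- order(sizes)
  maps <- maps[ord]
  sizes <- sizes[ord]
  dims <- vapply(maps, function(m) dim(mapData(m)), integer(2))
  .check(all(dims == dims[, 1L]), "maps must share pixel dimensions")
  if (!is.null(names(weights))) {
    .check(all(as.character(sizes) %in% names(weights)),
           "weights must name every patch size being fused")
    w <- as.numeric(weights[as.character(sizes)])
  } else {
    .check(length(weights) == length(maps),
           "need one weight per map")
    w <- as.numeric(weights)[ord]
  }
  .check(all(w >= 0) && any(w > 0),
         "weights must be >= 0 with at least one > 0")
  cal <- lapply(seq_along(maps), function(i)
    .calibrateMap(mapData(maps[[i]]), calibration, sizes[i]))
  fusedData <- if (mode == "geometric") {
    acc <- 0
    for (i in seq_along(cal)) acc <- acc + w[i] * log(cal[[i]])
    exp(acc / sum(w))
  } else {
    acc <- 1
    for (i in seq_along(cal)) acc <- acc * (w[i] * cal[[i]])
    .clip01(acc^(1 / length(cal)))
  }
  new("AnomalyMap", map = fusedData, sizePx = NA_integer_, fused = TRUE)
}

#' Image-level anomaly score
#'
#' The score of an image is the maximum pixel of its fused, normalized
#' anomaly map.
#'
#' @param map a fused [AnomalyMap-class] (or any map with entries in
#'   [0, 1]).
#' @return scalar in [0, 1].
#' @export
imageScore <- function(map) {
  m <- if (is(map, "AnomalyMap")) mapData(map) else map
  max(m)
}

#' Binary normal/abnormal decision
#'
#' An image is called abnormal iff its score strictly exceeds the decision
#' threshold (default 0.5); a score exactly at the threshold is normal.
#'
#' @param score image-level score in [0, 1].
#' @param calibration a [ScoreCalibration-class], or a plain numeric
#'   threshold.
#' @return `"abnormal"` or `"normal"`.
#' @export
classifyScore <- function(score, calibration = 0.5) {
  thr <- if (is(calibration, "ScoreCalibration"))
    decisionThreshold(calibration) else as.numeric(calibration)
  .check(score >= 0 && score <= 1, "score must lie in [0, 1]")
  if (score > thr) "abnormal" else "normal"
}

#' Export an anomaly map
#'
#' `writeAnomalyHeatmap` writes the map as a 16-bit TIFF heatmap (values
#' clipped to [0, 1]); `writeMapArray` writes the raw float64 array
#' (little-endian, preceded by two int32 dimensions).
#'
#' @param map an [AnomalyMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnomalyHeatmap <- function(map, path) {
  writeImageGray(.clip01(mapData(map)), path)
}

#' @rdname writeAnomalyHeatmap
#' @export
writeMapArray <- function(map, path) {
  m <- mapData(map)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(dim(m)), con, size = 4L, endian = "little")
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}
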