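#' Phantom image configuration
#'
#' Parameters of the geometric "chest-like" phantom used to exercise the
#' detector without clinical data. A phantom is a square grayscale image
#' with a bright body ellipse on a dark background, two darker lung-field
#' ellipses inside the body, faint periodic rib bands across the lung
#' fields, per-image geometric jitter, and additive Gaussian pixel noise.
#' Intensities live in [0, 1]. The phantoms emulate only the gross
#' structure of a radiograph (bright mediastinum/soft tissue, darker
#' lungs, periodic ribs, patient-to-patient variation) — not radiographic
#' physics or pathology appearance.
#'
#' @param side image side in pixels; must be divisible by every configured
#'   patch size downstream.
#' @param background background intensity level.
#' @param bodyLevel intensity added inside the body ellipse.
#' @param lungDrop intensity subtracted inside each lung ellipse.
#' @param ribAmplitude amplitude of the sinusoidal rib bands (in the lungs).
#' @param ribPeriod rib band period in pixels.
#' @param jitter per-image uniform jitter of ellipse centres/semi-axes, as
#'   a fraction of `side`.
#' @param noiseSd standard deviation of the additive Gaussian pixel noise.
#' @param geometry named list `body`, `lungL`, `lungR` of ellipse
#'   parameters (row centre, col centre, row semi-axis, col semi-axis, as
#'   fractions of the side); defaults to the nominal chest-like layout.
#' @return validated list of class `"phantomConfig"`.
#' @export
phantomConfig <- function(side = 128L, background = 0.20, bodyLevel = 0.45,
                          lungDrop = 0.22, ribAmplitude = 0.05,
                          ribPeriod = 14, jitter = 0.02, noiseSd = 0.02,
                          geometry = .phantomGeometry) {
  .check(side >= 8, "side must be >= 8")
  .check(noiseSd >= 0, "noiseSd must be >= 0")
  .check(ribPeriod > 0, "ribPeriod must be > 0")
  .check(jitter >= 0 && jitter < 0.1, "jitter must lie in [0, 0.1)")
  .check(all(c("body", "lungL", "lungR") %in% names(geometry)),
         "geometry must define body, lungL and lungR ellipses")
  structure(list(side = as.integer(side), background = background,
                 bodyLevel = bodyLevel, lungDrop = lungDrop,
                 ribAmplitude = ribAmplitude, ribPeriod = ribPeriod,
                 jitter = jitter, noiseSd = noiseSd, geometry = geometry),
            class = "phantomConfig")
}

# nominal phantom geometry as fractions of the image side:
# (row centre, col centre, row semi-axis, col semi-axis)
.phantomGeometry <- list(
  body = c(0.52, 0.50, 0.44, 0.38),
  lungL = c(0.42, 0.33, 0.26, 0.14),
  lungR = c(0.42, 0.67, 0.26, 0.14))

.ellipseMask <- function(side, geo) {
  r <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((r - geo[1] * side) / (geo[3] * side))^2 +
    ((cc - geo[2] * side) / (geo[4] * side))^2 <= 1
}

#' Generate one normal phantom image
#'
#' Deterministic for a fixed seed (or for a fixed RNG state when
#' `seed = NULL`). The construction guarantees that the mean intensity
#' inside the lung fields is below the mean outside them.
#'
#' @param config a [phantomConfig()].
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return numeric `side` x `side` matrix in [0, 1].
#' @export
generateNormal <- function(config, seed = NULL) {
  .check(inherits(config, "phantomConfig"), "config must be a phantomConfig")
  if (!is.null(seed)) set.seed(seed)
  s <- config$side
  jit <- function() runif(4, -config$jitter, config$jitter)
  geo <- lapply(config$geometry, function(g) g + jit())
  # lungs must stay inside the body ellipse (fractional bounding check)
  for (lung in c("lungL", "lungR")) {
    g <- geo[[lung]]; b <- geo$body
    inside <- ((g[1] - b[1]) / b[3])^2 + ((g[2] - b[2]) / b[4])^2 < 1 &&
      g[3] < b[3] && g[4] < b[4]
    if (!inside)
      stop("invalid phantom geometry: lung field falls outside the body")
  }
  body <- .ellipseMask(s, geo$body)
  lungs <- .ellipseMask(s, geo$lungL) | .ellipseMask(s, geo$lungR)
  img <- matrix(config$background, s, s)
  img[body] <- img[body] + config$bodyLevel
  img[lungs] <- img[lungs] - config$lungDrop
  if (config$ribAmplitude > 0) {
    # the rib-band phase is part of the per-image geometric variation
    phase <- if (config$jitter > 0) runif(1, 0, 2 * pi) else 0
    ribs <- config$ribAmplitude *
      sin(2 * pi * matrix(seq_len(s), s, s) / config$ribPeriod + phase)
    img[lungs] <- img[lungs] + ribs[lungs]
  }
  if (config$noiseSd > 0)
    img <- img + matrix(rnorm(s * s, sd = config$noiseSd), s, s)
  .clip01(img)
}

#' Anomaly injection specification
#'
#' Controlled synthetic anomalies with smooth Gaussian-profile edges:
#' `bright-blob` and `dark-blob` add/subtract an intensity bump of
#' full-width-at-half-maximum equal to the sampled diameter; a
#' `shape-deformation` locally magnifies the image inside the same
#' Gaussian window (structural rather than intensity change). Diameters
#' and contrasts are sampled uniformly from their ranges per anomaly. The
#' default diameter range spans more than one patch resolution of the
#' desk-scale grid, so multiresolution behaviour is exercised.
#'
#' @param kinds subset of `c("bright-blob", "dark-blob",
#'   "shape-deformation")`; one is drawn per anomaly.
#' @param diameterRange anomaly FWHM range in pixels (min >= 2).
#' @param contrastRange absolute contrast range (0 excluded).
#' @param count anomalies per image.
#' @param centerRegion ellipse (row centre, col centre, row semi-axis, col
#'   semi-axis, as fractions of the side) within which anomaly centres are
#'   sampled; default: the nominal phantom body.
#' @return validated list of class `"anomalySpec"`.
#' @export
anomalySpec <- function(kinds = c("bright-blob", "dark-blob",
                                  "shape-deformation"),
                        diameterRange = c(8, 48),
                        contrastRange = c(0.15, 0.40), count = 1L,
                        centerRegion = c(0.52, 0.50, 0.36, 0.30)) {
  .check(all(kinds %in% c("bright-blob", "dark-blob", "shape-deformation")),
         "unknown anomaly kind")
  .check(diameterRange[1] >= 2, "minimum anomaly diameter is 2 px")
  .check(all(contrastRange > 0), "contrast must be non-zero (positive range)")
  .check(count >= 1, "count must be >= 1")
  structure(list(kinds = kinds, diameterRange = diameterRange,
                 contrastRange = contrastRange, count = as.integer(count),
                 centerRegion = centerRegion),
            class = "anomalySpec")
}

#' Inject synthetic anomalies into an image
#'
#' Alters the image with `spec$count` smooth-edged anomalies and returns
#' the modified image together with a binary ground-truth mask (pixels
#' within the half-maximum contour, i.e. within the nominal diameter).
#' Deterministic for a fixed seed.
#'
#' @param image square numeric matrix in [0, 1].
#' @param spec an [anomalySpec()].
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return list with `image` (modified matrix), `mask` (logical matrix),
#'   and `params` (data.frame: kind, row, col, diameter, contrast).
#' @export
injectAnomaly <- function(image, spec, seed = NULL) {
  .check(inherits(spec, "anomalySpec"), "spec must be an anomalySpec")
  if (!is.null(seed)) set.seed(seed)
  s <- nrow(image)
  reg <- spec$centerRegion
  maxDiam <- 2 * min(reg[3], reg[4]) * s
  out <- image
  mask <- matrix(FALSE, s, s)
  params <- vector("list", spec$count)
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  for (a in seq_len(spec$count)) {
    kind <- sample(spec$kinds, 1L)
    diam <- runif(1, spec$diameterRange[1], spec$diameterRange[2])
    if (diam > maxDiam)
      stop("anomaly larger than the body region: diameter ", round(diam),
           " px exceeds ", round(maxDiam), " px")
    contrast <- runif(1, spec$contrastRange[1], spec$contrastRange[2])
    # rejection-sample a centre such that the anomaly fits inside the region
    repeat {
      cr <- runif(1, reg[1] - reg[3], reg[1] + reg[3]) * s
      cc <- runif(1, reg[2] - reg[4], reg[2] + reg[4]) * s
      fit <- ((cr / s - reg[1]) / max(reg[3] - diam / (2 * s), 1e-6))^2 +
        ((cc / s - reg[2]) / max(reg[4] - diam / (2 * s), 1e-6))^2
      if (fit <= 1) break
    }
    sigma <- diam / (2 * sqrt(2 * log(2)))   # FWHM = diam
    r2 <- (rows - cr)^2 + (cols - cc)^2
    prof <- exp(-r2 / (2 * sigma^2))
    prof[prof < 1e-4] <- 0                   # compact support
    if (kind == "bright-blob") {
      out <- out + contrast * prof
    } else if (kind == "dark-blob") {
      out <- out - contrast * prof
    } else {
      # local magnification: sample the source image at contracted coords
      shrink <- 1 - 0.8 * contrast * prof
      srcR <- cr + (rows - cr) * shrink
      srcC <- cc + (cols - cc) * shrink
      out <- .bilinearSample(out, srcR, srcC)
    }
    mask <- mask | (prof >= 0.5)
    params[[a]] <- data.frame(kind = kind, row = cr, col = cc,
                              diameter = diam, contrast = contrast)
  }
  list(image = .clip01(out), mask = mask, params = do.call(rbind, params))
}

# internal: bilinear sampling of matrix m at fractional (r, c) coordinates
.bilinearSample <- function(m, r, c) {
  s1 <- nrow(m); s2 <- ncol(m)
  r <- pmin(pmax(r, 1), s1); c <- pmin(pmax(c, 1), s2)
  r0 <- pmin(floor(r), s1 - 1L); c0 <- pmin(floor(c), s2 - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i10 <- cbind(as.vector(r0 + 1), as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c0 + 1))
  i11 <- cbind(as.vector(r0 + 1), as.vector(c0 + 1))
  v <- m[i00] * as.vector((1 - fr) * (1 - fc)) +
    m[i10] * as.vector(fr * (1 - fc)) +
    m[i01] * as.vector((1 - fr) * fc) +
    m[i11] * as.vector(fr * fc)
  matrix(v, s1, s2)
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes a normal-only training set and balanced labeled validation and
#' test sets (equal normal/abnormal counts), mirroring a
#' train / validation / test screening-study layout. Images are 16-bit
#' TIFF; ground-truth anomaly masks are 8-bit PNG; a manifest CSV records
#' split, label, file paths, the per-image seeds, and the sampled anomaly
#' parameters, so the whole dataset can be regenerated bit-identically
#' from the manifest alone.
#'
#' @param dir output directory (created if needed).
#' @param nNormalTrain normal training images.
#' @param nValPairs,nTestPairs normal/abnormal image pairs in the
#'   validation and test splits.
#' @param phantom a [phantomConfig()].
#' @param anomaly an [anomalySpec()].
#' @param seed master seed; per-image seeds are drawn from it and recorded.
#' @return the manifest data.frame, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
makeDataset <- function(dir, nNormalTrain = 60L, nValPairs = 20L,
                        nTestPairs = 20L, phantom = phantomConfig(),
                        anomaly = anomalySpec(), seed = 1L) {
  .check(nNormalTrain >= 1 && nValPairs >= 1 && nTestPairs >= 1,
         "all counts must be >= 1")
  for (d in c(dir, file.path(dir, c("train", "val", "test", "masks"))))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  plan <- rbind(
    data.frame(split = "train", label = 0L, n = nNormalTrain),
    data.frame(split = "val", label = 0L, n = nValPairs),
    data.frame(split = "val", label = 1L, n = nValPairs),
    data.frame(split = "test", label = 0L, n = nTestPairs),
    data.frame(split = "test", label = 1L, n = nTestPairs))
  nTotal <- sum(plan$n)
  set.seed(seed)
  imgSeeds <- sample.int(.Machine$integer.max - 1L, 2L * nTotal)
  rows <- vector("list", nTotal)
  k <- 0L
  for (p in seq_len(nrow(plan))) {
    for (i in seq_len(plan$n[p])) {
      k <- k + 1L
      id <- sprintf("%s_%s_%03d", plan$split[p],
                    if (plan$label[p] == 1L) "abn" else "nrm", i)
      genSeed <- imgSeeds[2L * k - 1L]
      anoSeed <- imgSeeds[2L * k]
      img <- generateNormal(phantom, seed = genSeed)
      maskPath <- NA_character_
      anoStr <- ""
      if (plan$label[p] == 1L) {
        inj <- injectAnomaly(img, anomaly, seed = anoSeed)
        img <- inj$image
        maskPath <- file.path("masks", paste0(id, "_mask.png"))
        writeImageGray(inj$mask * 1, file.path(dir, maskPath))
        anoStr <- paste(sprintf("%s:%.1fpx:%+.3f", inj$params$kind,
                                inj$params$diameter,
                                ifelse(inj$params$kind == "dark-blob", -1, 1) *
                                  inj$params$contrast),
                        collapse = ";")
      }
      relPath <- file.path(plan$split[p], paste0(id, ".tif"))
      writeImageGray(img, file.path(dir, relPath))
      rows[[k]] <- data.frame(id = id, split = plan$split[p],
                              label = plan$label[p], path = relPath,
                              maskPath = maskPath, genSeed = genSeed,
                              anomalySeed = anoSeed, anomalies = anoStr,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# internal: load a dataset (directory with manifest.csv, or in-memory list)
.loadDataset <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$images) &&
      !is.null(dataset$manifest))
    return(dataset)
  .check(is.character(dataset) && dir.exists(dataset),
         "dataset must be a directory made by makeDataset() or a ",
         "list(images, manifest)")
  man <- read.csv(file.path(dataset, "manifest.csv"),
                  stringsAsFactors = FALSE)
  images <- lapply(file.path(dataset, man$path), readImageGray)
  names(images) <- man$id
  list(images = images, manifest = man, dir = dataset)
}

#' Read a dataset manifest
#'
#' @param dir dataset directory created by [makeDataset()].
#' @return the manifest data.frame.
#' @export
readDatasetManifest <- function(dir) {
  read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}
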