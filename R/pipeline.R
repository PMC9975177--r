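#' Pipeline configuration
#'
#' Assembles and validates the full detector configuration: the image
#' side, the patch-size set, per-size locality radii d, the similarity
#' kind, per-size fusion weights and fusion mode, the decision threshold,
#' the covariance shrinkage, and the SSL training settings.
#'
#' Two profiles are provided. `"desk"` (the default) is the CPU-scale
#' profile used throughout the tests: 128 px images, patch sizes
#' {16, 32, 64, 128}, locality d = (2, 1, 0, 0) from the smallest size up,
#' fusion weights (0.1, 1.2, 1.2, 1.0), Mahalanobis similarity, threshold
#' 0.5, and the built-in fully-connected backbone. `"paper"` records the
#' full-scale profile for fidelity: 1024 px images, sizes
#' {128, 256, 512, 1024} with the same d and weight assignments, a
#' ResNet-50 backbone with 2048-d features and a 128-d projection head,
#' LARS optimizer (lr 4.8, weight decay 1e-6), batch 256, 100 epochs.
#' Training the paper profile requires a GPU-scale backbone that this
#' build does not ship; the profile exists so the configuration is
#' preserved verbatim and exchangeable.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... named overrides of any configuration field.
#' @return validated list of class `"pipelineConfig"`.
#' @export
defaultPipelineConfig <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "desk") {
    list(profile = "desk", imageSide = 128L,
         patchSizes = c(16L, 32L, 64L, 128L),
         locality = c("16" = 2L, "32" = 1L, "64" = 0L, "128" = 0L),
         similarity = "mahalanobis",
         weights = c("16" = 0.1, "32" = 1.2, "64" = 1.2, "128" = 1.0),
         fusionMode = "geometric", threshold = 0.5, epsilon = 1e-6,
         shrinkage = 0.1,
         ssl = sslConfig())
  } else {
    list(profile = "paper", imageSide = 1024L,
         patchSizes = c(128L, 256L, 512L, 1024L),
         locality = c("128" = 2L, "256" = 1L, "512" = 0L, "1024" = 0L),
         similarity = "mahalanobis",
         weights = c("128" = 0.1, "256" = 1.2, "512" = 1.2, "1024" = 1.0),
         fusionMode = "geometric", threshold = 0.5, epsilon = 1e-6,
         shrinkage = 0.1,
         ssl = sslConfig(temperature = 0.5, batchPairs = 256L,
                         epochs = 100L, featureDim = 2048L,
                         projectionDim = 128L, inputSide = 1024L,
                         backbone = "resnet50"))
  }
  if (profile == "paper") {
    cfg$ssl$optimizer <- "lars"
    cfg$ssl$lr <- 4.8
    cfg$ssl$weightDecay <- 1e-6
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  validatePipelineConfig(cfg)
}

#' @rdname defaultPipelineConfig
#' @param config a pipeline configuration list to validate.
#' @export
validatePipelineConfig <- function(config) {
  .check(all(config$imageSide %% config$patchSizes == 0L),
         "field patchSizes: every patch size must divide imageSide (",
         config$imageSide, ")")
  key <- as.character(sort(config$patchSizes))
  .check(all(key %in% names(config$locality)),
         "field locality: must define a patch distance d for every size")
  .check(all(config$locality >= 0),
         "field locality: patch distances must be >= 0")
  .check(all(key %in% names(config$weights)),
         "field weights: must define a weight for every size")
  .check(all(config$weights >= 0) && any(config$weights > 0),
         "field weights: must be >= 0 with at least one > 0")
  .check(config$similarity %in% .similarityKinds,
         "field similarity: must be one of ",
         paste(.similarityKinds, collapse = ", "))
  .check(config$fusionMode %in% c("geometric", "literal"),
         "field fusionMode: must be 'geometric' or 'literal'")
  .check(config$threshold > 0 && config$threshold < 1,
         "field threshold: must lie in (0, 1)")
  structure(config, class = "pipelineConfig")
}

#' Load / save a pipeline configuration as YAML
#'
#' The YAML schema mirrors the fields of [defaultPipelineConfig()]
#' (`imageSide`, `patchSizes`, `locality`, `similarity`, `weights`,
#' `fusionMode`, `threshold`, `epsilon`, `shrinkage`, and an `ssl` block
#' with the [sslConfig()] fields). Round-trips exactly: a loaded config
#' re-serialized equals the original canonical form.
#'
#' @param path YAML file path.
#' @param config a `"pipelineConfig"` list.
#' @return `loadPipelineConfig` returns the validated config;
#'   `savePipelineConfig` returns `path` invisibly.
#' @export
loadPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  .check(is.list(raw), "config file is not a YAML mapping")
  base <- defaultPipelineConfig(raw$profile %||% "desk")
  for (nm in setdiff(names(raw), c("ssl", "profile"))) {
    v <- raw[[nm]]
    if (nm %in% c("patchSizes")) v <- as.integer(v)
    if (nm %in% c("locality")) v <- setNames(as.integer(unlist(v)), names(v))
    if (nm %in% c("weights")) v <- setNames(as.numeric(unlist(v)), names(v))
    base[[nm]] <- v
  }
  if (!is.null(raw$ssl)) {
    sslArgs <- unclass(base$ssl)
    sslArgs[names(raw$ssl)] <- raw$ssl
    base$ssl <- do.call(sslConfig,
                        sslArgs[names(formals(sslConfig))[
                          names(formals(sslConfig)) %in% names(sslArgs)]])
  }
  validatePipelineConfig(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname loadPipelineConfig
#' @export
savePipelineConfig <- function(config, path) {
  out <- unclass(config)
  out$ssl <- unclass(out$ssl)
  out$locality <- as.list(out$locality)
  out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Train the full multiresolution detector
#'
#' Runs the complete training phase on normal images only: per patch
#' size, tiles all training images and trains a contrastive encoder;
#' builds the reference database of normal-patch embeddings (with per-size
#' covariance models); then scores the validation normals to fit the
#' per-resolution score calibration for every similarity kind. All
#' randomness derives from `seed`.
#'
#' @param trainImages named list of normal training images (matrices) or
#'   character vector of paths.
#' @param valImages named list of normal validation images (for
#'   calibration), or paths.
#' @param config a `"pipelineConfig"` from [defaultPipelineConfig()].
#' @param seed integer seed controlling encoder training.
#' @param verbose print progress.
#' @return a [PipelineModel-class].
#' @export
trainPipeline <- function(trainImages, valImages, config, seed = 1L,
                          verbose = FALSE) {
  config <- validatePipelineConfig(config)
  trainImgs <- lapply(.loadImageList(trainImages), resizeImage,
                      targetSide = config$imageSide)
  valImgs <- lapply(.loadImageList(valImages), resizeImage,
                    targetSide = config$imageSide)
  .check(length(trainImgs) >= 2L, "need at least 2 training images")
  .check(length(valImgs) >= 1L, "need at least 1 validation image")

  sizes <- sort(config$patchSizes)
  encoders <- setNames(vector("list", length(sizes)), as.character(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    if (verbose) message("training encoder for ", s, " px patches")
    spec <- patchSpec(s, config$imageSide)
    patches <- unlist(lapply(trainImgs, tileImage, spec = spec),
                      recursive = FALSE)
    ssl <- config$ssl
    ssl$seed <- as.integer((seed * 131L + i * 7919L) %% .Machine$integer.max)
    encoders[[i]] <- trainEncoder(patches, ssl, verbose = verbose)
  }
  if (verbose) message("building reference database")
  db <- buildReferenceDB(trainImgs, encoders, sizes, config$locality,
                         shrinkage = config$shrinkage,
                         imageSideOverride = config$imageSide)
  if (verbose) message("fitting calibration on validation normals")
  calibrations <- .fitAllCalibrations(valImgs, encoders, db, config)
  new("PipelineModel", encoders = encoders, db = db,
      calibration = calibrations[[config$similarity]],
      calibrations = calibrations, config = unclass(config))
}

# internal: per-kind, per-size calibration quantiles from val normals
.fitAllCalibrations <- function(valImgs, encoders, db, config) {
  kinds <- .similarityKinds
  sizes <- sort(config$patchSizes)
  pool <- lapply(setNames(kinds, kinds), function(k)
    setNames(vector("list", length(sizes)), as.character(sizes)))
  for (img in valImgs) {
    for (s in sizes) {
      key <- as.character(s)
      emb <- .embedImagePatches(img, encoders[[key]])
      d <- db@locality[[key]]
      for (k in kinds) {
        sc <- .scoreEmbeddedPatches(emb, db, s, k, d)$score
        pool[[k]][[key]] <- c(pool[[k]][[key]], sc)
      }
    }
  }
  lapply(pool, fitCalibration, threshold = config$threshold,
         epsilon = config$epsilon)
}

# internal: per-image raw per-resolution maps for a set of images
.scoreDatasetMaps <- function(model, images, kind) {
  imgs <- lapply(.loadImageList(images), resizeImage,
                 targetSide = model@config$imageSide)
  sizes <- sort(model@db@patchSizes)
  maps <- lapply(imgs, function(img)
    lapply(setNames(as.character(sizes), as.character(sizes)), function(key)
      resolutionMap(img, model@encoders[[key]], model@db, kind = kind)))
  list(maps = maps, ids = names(imgs))
}

#' Score a set of images with a trained detector
#'
#' For every image: computes the per-resolution anomaly maps, fuses them
#' with the configured weights and calibration, takes the maximum fused
#' pixel as the image score, and applies the decision threshold. Per-size
#' single-resolution scores (maximum calibrated pixel of each size's map)
#' are reported alongside, which is what a single-resolution variant of
#' the detector would produce.
#'
#' @param model a [PipelineModel-class].
#' @param images named list of matrices or character vector of paths.
#' @param kind similarity kind (default: the model's configured kind).
#' @param weights fusion weights (default: the model's configured weights).
#' @param mapDir if non-NULL, per-resolution and fused heatmaps are
#'   written there as 16-bit TIFFs (k + 1 files per image).
#' @return data.frame with columns `imageId`, `score`, `decision`, and one
#'   `single_<size>` column per patch size.
#' @export
scoreDataset <- function(model, images, kind = NULL, weights = NULL,
                         mapDir = NULL) {
  kind <- kind %||% model@config$similarity
  weights <- weights %||% model@config$weights
  calibration <- model@calibrations[[kind]]
  .check(is(calibration, "ScoreCalibration"),
         "model holds no calibration for kind '", kind, "'")
  sm <- .scoreDatasetMaps(model, images, kind)
  sizes <- sort(model@db@patchSizes)
  if (!is.null(mapDir))
    dir.create(mapDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(sm$maps))
  for (i in seq_along(sm$maps)) {
    maps <- sm$maps[[i]]
    fused <- fuseMaps(maps, weights, calibration,
                      mode = model@config$fusionMode)
    sc <- imageScore(fused)
    singles <- vapply(as.character(sizes), function(key)
      max(.calibrateMap(mapData(maps[[key]]), calibration,
                        as.integer(key))), numeric(1))
    if (!is.null(mapDir)) {
      for (key in names(maps))
        writeAnomalyHeatmap(
          new("AnomalyMap",
              map = .calibrateMap(mapData(maps[[key]]), calibration,
                                  as.integer(key)),
              sizePx = as.integer(key), fused = FALSE),
          file.path(mapDir, sprintf("%s_s%s.tif", sm$ids[i], key)))
      writeAnomalyHeatmap(fused,
                          file.path(mapDir,
                                    sprintf("%s_fused.tif", sm$ids[i])))
    }
    row <- data.frame(imageId = sm$ids[i], score = sc,
                      decision = classifyScore(sc, calibration),
                      stringsAsFactors = FALSE)
    for (key in names(singles)) row[[paste0("single_", key)]] <- singles[[key]]
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Save / load a trained pipeline model
#'
#' @param model a [PipelineModel-class].
#' @param path file path for the serialized container.
#' @return `savePipelineModel` returns `path` invisibly;
#'   `loadPipelineModel` returns the [PipelineModel-class].
#' @export
savePipelineModel <- function(model, path) {
  saveRDS(list(format = "mrpad-model-v1", model = model), path)
  invisible(path)
}

#' @rdname savePipelineModel
#' @export
loadPipelineModel <- function(path) {
  obj <- readRDS(path)
  .check(identical(obj$format, "mrpad-model-v1"),
         "not an mrpad model container: ", path)
  obj$model
}
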