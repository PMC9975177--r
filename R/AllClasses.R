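#' @import methods
NULL

#' PatchSpec: a tiling resolution for square images
#'
#' Describes one patch resolution: the patch side length `sizePx` and the
#' (resized) image side `imageSidePx` it tiles. The grid dimension is
#' `imageSidePx / sizePx` and must be an exact integer, so every pixel
#' belongs to exactly one patch at this resolution.
#'
#' @slot sizePx integer(1), patch side length in pixels.
#' @slot imageSidePx integer(1), side of the square image being tiled.
#' @aliases PatchSpec-class
#' @exportClass PatchSpec
setClass("PatchSpec",
  representation(sizePx = "integer", imageSidePx = "integer"))

setValidity("PatchSpec", function(object) {
  msgs <- character()
  if (length(object@sizePx) != 1L || is.na(object@sizePx) || object@sizePx < 1L)
    msgs <- c(msgs, "sizePx must be a single positive integer")
  if (length(object@imageSidePx) != 1L || is.na(object@imageSidePx) ||
      object@imageSidePx < 1L)
    msgs <- c(msgs, "imageSidePx must be a single positive integer")
  if (length(msgs) == 0L && object@imageSidePx %% object@sizePx != 0L)
    msgs <- c(msgs, sprintf("sizePx (%d) must divide imageSidePx (%d) exactly",
                            object@sizePx, object@imageSidePx))
  if (length(msgs)) msgs else TRUE
})

#' PatchEncoder: a trained per-resolution feature extractor
#'
#' Holds the parameters of the self-supervised encoder for one patch size:
#' the backbone f(.) whose output h is the feature used for anomaly scoring,
#' and the projection head g(.) used only during contrastive training.
#' After training only the backbone is consulted; the head is retained for
#' inspection but never used by [embedPatch()].
#'
#' @slot patchSize integer(1), side of the patches this encoder accepts.
#' @slot inputSide integer(1), side to which patches are downsampled before
#'   the backbone (the backbone input is `inputSide^2` pixels).
#' @slot backbone character(1), backbone identifier (currently `"mlp"`).
#' @slot params list of numeric weight matrices/vectors for backbone and head.
#' @slot config list, the [sslConfig()] the encoder was trained with.
#' @slot lossCurve numeric, mean NT-Xent loss per epoch (empty if untrained).
#' @aliases PatchEncoder-class
#' @exportClass PatchEncoder
setClass("PatchEncoder",
  representation(patchSize = "integer", inputSide = "integer",
                 backbone = "character", params = "list",
                 config = "list", lossCurve = "numeric"))

setValidity("PatchEncoder", function(object) {
  if (length(object@patchSize) != 1L || object@patchSize < 1L)
    return("patchSize must be a single positive integer")
  if (!object@backbone %in% names(.backboneRegistry))
    return(sprintf("unknown backbone '%s'", object@backbone))
  TRUE
})

#' CovarianceModel: regularized feature covariance for Mahalanobis scoring
#'
#' The sample covariance S of the reference features of one patch size,
#' shrunk towards a scaled identity, `(1-lambda) S + lambda * vbar * I`
#' where `vbar` is the mean feature variance (floored at 1e-8 so the result
#' is positive definite even for degenerate inputs). The inverse is cached
#' through the upper Cholesky factor of the regularized matrix.
#'
#' @slot S matrix, raw sample covariance (denominator n-1).
#' @slot Sreg matrix, regularized covariance (symmetric positive definite).
#' @slot cholReg matrix, upper Cholesky factor U with t(U) %*% U = Sreg.
#' @slot lambda numeric(1), shrinkage coefficient in [0, 1].
#' @aliases CovarianceModel-class
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(S = "matrix", Sreg = "matrix", cholReg = "matrix",
                 lambda = "numeric"))

#' ReferenceDB: the normal-patch embedding database
#'
#' Per patch size, stores one embedding record per (training image, grid
#' cell): the feature vector h together with the patch size, grid
#' coordinates and source image id. Also carries the per-size covariance
#' models for Mahalanobis scoring, the per-size locality radii d, and
#' provenance (encoder checksums and build configuration) so that scoring
#' can refuse a database built by different encoders.
#'
#' @slot imageSide integer(1), side of the (resized) images the DB indexes.
#' @slot patchSizes integer, configured patch sizes.
#' @slot records named list (one entry per patch size, names like "16") of
#'   lists with elements `H` (n x featureDim matrix), `gx`, `gy` (integer),
#'   `imageId` (character).
#' @slot covariance named list of [CovarianceModel-class] (or NULL entries).
#' @slot locality named integer, Chebyshev patch-distance d per size.
#' @slot provenance list: encoder checksums, shrinkage, build metadata.
#' @aliases ReferenceDB-class
#' @exportClass ReferenceDB
setClass("ReferenceDB",
  representation(imageSide = "integer", patchSizes = "integer",
                 records = "list", covariance = "list",
                 locality = "integer", provenance = "list"))

setValidity("ReferenceDB", function(object) {
  key <- as.character(object@patchSizes)
  if (!all(key %in% names(object@records)))
    return("records must contain one entry per configured patch size")
  for (k in key) {
    rec <- object@records[[k]]
    g <- object@imageSide %/% as.integer(k)
    cells <- paste(rec$gx, rec$gy)
    want <- as.vector(outer(0:(g - 1L), 0:(g - 1L),
                            function(a, b) paste(a, b)))
    if (!all(want %in% cells))
      return(sprintf("size %s: some grid locations have no record", k))
  }
  TRUE
})

#' ScoreCalibration: reference scale for anomaly scores
#'
#' Per-resolution robust score range (1st and 99th percentiles of patch
#' anomaly scores over normal validation images) used to rescale raw patch
#' scores to [0, 1] before fusion, plus the image-level decision threshold.
#'
#' @slot qLo named numeric, lower calibration quantile per patch size.
#' @slot qHi named numeric, upper calibration quantile per patch size.
#' @slot threshold numeric(1) in (0, 1), image-level decision threshold.
#' @slot epsilon numeric(1), floor applied to calibrated scores before
#'   multiplicative fusion (prevents one perfectly-matched resolution from
#'   annihilating the fused product).
#' @aliases ScoreCalibration-class
#' @exportClass ScoreCalibration
setClass("ScoreCalibration",
  representation(qLo = "numeric", qHi = "numeric", threshold = "numeric",
                 epsilon = "numeric"))

setValidity("ScoreCalibration", function(object) {
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    return("threshold must lie strictly inside (0, 1)")
  if (any(object@qHi < object@qLo))
    return("qHi must be >= qLo for every patch size")
  TRUE
})

#' AnomalyMap: a per-pixel anomaly score image
#'
#' A full-resolution score array. Maps produced at one patch resolution are
#' piecewise-constant over that resolution's tiles; the fused map combines
#' all resolutions and is bounded in [0, 1].
#'
#' @slot map numeric matrix of per-pixel scores (finite, >= 0).
#' @slot sizePx integer(1), source patch size; `NA` for a fused map.
#' @slot fused logical(1).
#' @aliases AnomalyMap-class
#' @exportClass AnomalyMap
setClass("AnomalyMap",
  representation(map = "matrix", sizePx = "integer", fused = "logical"))

setValidity("AnomalyMap", function(object) {
  if (!all(is.finite(object@map)) || any(object@map < 0))
    return("map entries must be finite and non-negative")
  if (isTRUE(object@fused) && any(object@map > 1))
    return("fused map entries must lie in [0, 1]")
  TRUE
})

#' PipelineModel: trained artifacts of the full detector
#'
#' Bundles everything needed to score new images: one [PatchEncoder-class]
#' per patch size, the [ReferenceDB-class], the [ScoreCalibration-class]
#' fitted on validation normals, and the pipeline configuration.
#'
#' @slot encoders named list of [PatchEncoder-class], one per patch size.
#' @slot db [ReferenceDB-class].
#' @slot calibration [ScoreCalibration-class], fitted for the configured
#'   similarity kind.
#' @slot calibrations named list of [ScoreCalibration-class], one per
#'   similarity kind (fitted on the same validation normals, so sweeps
#'   across kinds stay on a comparable [0, 1] scale).
#' @slot config list, the pipeline configuration used at training time.
#' @aliases PipelineModel-class
#' @exportClass PipelineModel
setClass("PipelineModel",
  representation(encoders = "list", db = "ReferenceDB",
                 calibration = "ScoreCalibration", calibrations = "list",
                 config = "list"))

#' EvalReport: cross-validated screening performance
#'
#' @slot folds data.frame, one row per fold with accuracy, precision,
#'   sensitivity, specificity and AUROC (NA where a denominator is zero).
#' @slot means named numeric, across-fold arithmetic means.
#' @slot config list, experiment configuration (sizes, similarity, weights, d).
#' @aliases EvalReport-class
#' @exportClass EvalReport
setClass("EvalReport",
  representation(folds = "data.frame", means = "numeric", config = "list"))
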