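#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes, so user code never
#' reaches into slots directly.
#'
#' @param object an S4 object from this package.
#' @return The requested component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchSize", function(object) standardGeneric("patchSize"))

#' @rdname accessors
#' @export
setGeneric("imageSide", function(object) standardGeneric("imageSide"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("lossCurve", function(object) standardGeneric("lossCurve"))

#' @rdname accessors
#' @export
setGeneric("featureDim", function(object) standardGeneric("featureDim"))

#' @rdname accessors
#' @export
setGeneric("refRecords", function(object, size) standardGeneric("refRecords"))

#' @rdname accessors
#' @export
setGeneric("covarianceModel",
           function(object, size) standardGeneric("covarianceModel"))

#' @rdname accessors
#' @export
setGeneric("localityRadius",
           function(object, size) standardGeneric("localityRadius"))

#' @rdname accessors
#' @export
setGeneric("decisionThreshold",
           function(object) standardGeneric("decisionThreshold"))

#' @rdname accessors
#' @export
setGeneric("mapData", function(object) standardGeneric("mapData"))

#' @rdname accessors
#' @export
setGeneric("isFused", function(object) standardGeneric("isFused"))

setMethod("patchSize", "PatchSpec", function(object) object@sizePx)
setMethod("imageSide", "PatchSpec", function(object) object@imageSidePx)
setMethod("gridDim", "PatchSpec",
          function(object) object@imageSidePx %/% object@sizePx)

setMethod("patchSize", "PatchEncoder", function(object) object@patchSize)
setMethod("lossCurve", "PatchEncoder", function(object) object@lossCurve)
setMethod("featureDim", "PatchEncoder",
          function(object) object@config$featureDim)

setMethod("imageSide", "ReferenceDB", function(object) object@imageSide)
setMethod("refRecords", "ReferenceDB", function(object, size) {
  key <- as.character(size)
  if (!key %in% names(object@records))
    stop("no records for patch size ", size)
  object@records[[key]]
})
setMethod("covarianceModel", "ReferenceDB", function(object, size) {
  object@covariance[[as.character(size)]]
})
setMethod("localityRadius", "ReferenceDB", function(object, size) {
  d <- object@locality[[as.character(size)]]
  if (is.null(d)) stop("no locality radius configured for size ", size)
  d
})

setMethod("decisionThreshold", "ScoreCalibration",
          function(object) object@threshold)
setMethod("decisionThreshold", "PipelineModel",
          function(object) object@calibration@threshold)

setMethod("mapData", "AnomalyMap", function(object) object@map)
setMethod("patchSize", "AnomalyMap", function(object) object@sizePx)
setMethod("isFused", "AnomalyMap", function(object) object@fused)

setMethod("show", "PatchSpec", function(object) {
  cat(sprintf("PatchSpec: %d px patches on a %d px image (%d x %d grid)\n",
              object@sizePx, object@imageSidePx, gridDim(object),
              gridDim(object)))
})

setMethod("show", "PatchEncoder", function(object) {
  cat(sprintf(
    "PatchEncoder (backbone '%s') for %d px patches\n", object@backbone,
    object@patchSize))
  cat(sprintf("  input %d x %d -> features %d (projection %d, training only)\n",
              object@inputSide, object@inputSide, object@config$featureDim,
              object@config$projectionDim))
  if (length(object@lossCurve))
    cat(sprintf("  trained %d epochs; NT-Xent loss %.4f -> %.4f\n",
                length(object@lossCurve), object@lossCurve[1],
                tail(object@lossCurve, 1)))
  else cat("  untrained\n")
})

setMethod("show", "ReferenceDB", function(object) {
  n <- vapply(object@records, function(r) nrow(r$H), integer(1))
  cat(sprintf("ReferenceDB on %d px images\n", object@imageSide))
  for (k in as.character(object@patchSizes))
    cat(sprintf("  size %4s px: %6d records, d = %d, covariance %s\n",
                k, n[[k]], object@locality[[k]],
                if (is.null(object@covariance[[k]])) "absent" else "fitted"))
})

setMethod("show", "AnomalyMap", function(object) {
  cat(sprintf("AnomalyMap %d x %d (%s); score range [%.4g, %.4g]\n",
              nrow(object@map), ncol(object@map),
              if (object@fused) "fused" else paste0(object@sizePx, " px"),
              min(object@map), max(object@map)))
})

setMethod("show", "PipelineModel", function(object) {
  cat("PipelineModel\n  patch sizes:",
      paste(object@db@patchSizes, collapse = ", "), "\n")
  cat(sprintf("  similarity: %s; threshold %.2f\n",
              object@config$similarity, object@calibration@threshold))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d fold(s)\n", nrow(object@folds)))
  print(round(object@means, 4))
})
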