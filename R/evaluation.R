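#' Confusion-matrix metrics
#'
#' Closed-form screening metrics from confusion counts:
#' accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP). A metric whose denominator is zero
#' is undefined and reported as `NA` (never silently coerced to 0); the
#' names of undefined metrics are listed in the `"undefined"` attribute.
#'
#' @param tp,fp,tn,fn non-negative integer counts (total > 0).
#' @return named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `specificity` with attribute `"undefined"`.
#' @examples
#' confusionMetrics(3, 1, 4, 2)  # 0.7, 0.75, 0.6, 0.8
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  .check(all(counts >= 0) && all(counts == round(counts)),
         "counts must be non-negative integers")
  .check(sum(counts) > 0, "all counts are zero: nothing was evaluated")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(accuracy = ratio(tp + tn, sum(counts)),
           precision = ratio(tp, tp + fp),
           sensitivity = ratio(tp, tp + fn),
           specificity = ratio(tn, tn + fp))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Area under the ROC curve
#'
#' Rank-based AUROC via the Mann-Whitney statistic with midranks, so tied
#' scores contribute 1/2: the probability that a randomly chosen abnormal
#' image outscores a randomly chosen normal one.
#'
#' @param labels binary vector (1/TRUE = abnormal/positive).
#' @param scores numeric scores, higher = more anomalous.
#' @return scalar in [0, 1].
#' @examples
#' aurocScore(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))  # 0.75
#' @export
aurocScore <- function(labels, scores) {
  lab <- as.logical(labels)
  .check(length(lab) == length(scores), "labels and scores differ in length")
  .check(!anyNA(lab) && all(is.finite(scores)), "NA labels or scores")
  nPos <- sum(lab)
  nNeg <- sum(!lab)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# internal: confusion counts from labels and decisions
.confusionCounts <- function(labels, abnormal) {
  lab <- as.logical(labels)
  list(tp = sum(lab & abnormal), fp = sum(!lab & abnormal),
       tn = sum(!lab & !abnormal), fn = sum(lab & !abnormal))
}

# internal: one row of fold metrics from labels/scores/decisions
.foldMetrics <- function(labels, scores, abnormal) {
  cc <- .confusionCounts(labels, abnormal)
  cm <- confusionMetrics(cc$tp, cc$fp, cc$tn, cc$fn)
  c(cm, auroc = aurocScore(labels, scores))
}

#' Five-fold cross-validation of the full pipeline
#'
#' The detector trains on normal images only, so folding rotates the
#' normal pool: the pooled training + validation normals are partitioned
#' into `nFolds` near-equal folds (sizes differ by at most one); in fold f
#' the f-th part supplies the calibration (validation) normals and the
#' rest train the encoders and the reference database. Every fold is then
#' evaluated on the same fixed labeled test pool, and the report carries
#' per-fold metrics plus their arithmetic mean. Encoders are retrained
#' from scratch in every fold. Fully deterministic for a fixed `seed`.
#'
#' @param dataset a dataset as returned by [makeDataset()] (directory path
#'   or in-memory list with `images` and `manifest`).
#' @param config a pipeline configuration from [defaultPipelineConfig()].
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed for fold assignment and training.
#' @return an [EvalReport-class].
#' @export
crossValidate <- function(dataset, config, nFolds = 5L, seed = 1L) {
  ds <- .loadDataset(dataset)
  man <- ds$manifest
  normIds <- man$id[man$split %in% c("train", "val") & man$label == 0L]
  testIds <- man$id[man$split == "test"]
  .check(length(normIds) >= nFolds,
         sprintf("need at least %d normal images for %d folds",
                 nFolds, nFolds))
  .check(length(testIds) >= 2L &&
           length(unique(man$label[man$split == "test"])) == 2L,
         "test pool must contain both classes")
  set.seed(seed)
  fold <- sample(rep(seq_len(nFolds), length.out = length(normIds)))
  testImages <- ds$images[testIds]
  testLabels <- man$label[match(testIds, man$id)]

  rows <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    valIds <- normIds[fold == f]
    trainIds <- normIds[fold != f]
    model <- trainPipeline(ds$images[trainIds], ds$images[valIds], config,
                           seed = seed + f)
    res <- scoreDataset(model, testImages)
    rows[[f]] <- c(fold = f,
                   .foldMetrics(testLabels, res$score,
                                res$decision == "abnormal"))
  }
  folds <- as.data.frame(do.call(rbind, rows))
  means <- colMeans(folds[, setdiff(names(folds), "fold"), drop = FALSE])
  new("EvalReport", folds = folds, means = means,
      config = list(patchSizes = config$patchSizes,
                    similarity = config$similarity,
                    weights = config$weights, locality = config$locality,
                    nFolds = nFolds, seed = seed))
}

#' Experiment sweeps over resolutions and fusion weights
#'
#' `sweepSingleResolution` evaluates every (patch size, similarity kind)
#' combination as a single-resolution detector (one row each), reusing the
#' trained encoders and reference database of `model`; only scoring and
#' calibration differ per row. `sweepWeights` evaluates the
#' multiresolution detector under a list of fusion-weight vectors for one
#' or more similarity kinds. Both mirror the shape of a
#' resolution-versus-similarity results table on the synthetic fixture.
#'
#' @param model a trained [PipelineModel-class].
#' @param images named list of evaluation images (matrices) or paths.
#' @param labels binary labels for `images` (1 = abnormal).
#' @param kinds similarity kinds to sweep.
#' @param weightsList list of numeric weight vectors (one per row), for
#'   `sweepWeights`.
#' @return data.frame, one row per configuration with the five metrics.
#' @export
sweepSingleResolution <- function(model, images, labels,
                                  kinds = .similarityKinds) {
  sizes <- model@db@patchSizes
  rows <- list()
  for (kind in kinds) {
    res <- scoreDataset(model, images, kind = kind)
    for (s in sizes) {
      sc <- res[[paste0("single_", s)]]
      dec <- sc > decisionThreshold(model)
      m <- .foldMetrics(labels, sc, dec)
      rows[[length(rows) + 1L]] <-
        data.frame(similarity = kind, patchSize = s, t(m))
    }
  }
  do.call(rbind, rows)
}

#' @rdname sweepSingleResolution
#' @export
sweepWeights <- function(model, images, labels, weightsList,
                         kinds = "mahalanobis") {
  rows <- list()
  for (kind in kinds) {
    res0 <- .scoreDatasetMaps(model, images, kind)
    for (w in weightsList) {
      sc <- vapply(res0$maps, function(maps)
        imageScore(fuseMaps(maps, w, model@calibration,
                            mode = model@config$fusionMode)), numeric(1))
      dec <- sc > decisionThreshold(model)
      m <- .foldMetrics(labels, sc, dec)
      rows[[length(rows) + 1L]] <-
        data.frame(similarity = kind,
                   weights = paste(w, collapse = ","), t(m))
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation report
#'
#' Writes the per-fold table plus a mean row as CSV, and the full report
#' (folds, means, configuration) as JSON.
#'
#' @param report an [EvalReport-class].
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return invisible list of written paths.
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) {
    tab <- report@folds
    meanRow <- c(fold = NA, report@means)
    tab <- rbind(tab, meanRow)
    tab$fold <- c(as.character(report@folds$fold), "mean")
    write.csv(tab, csvPath, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(folds = report@folds,
                              means = as.list(report@means),
                              config = report@config),
                         jsonPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(list(csv = csvPath, json = jsonPath))
}
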