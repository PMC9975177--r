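.similarityKinds <- c("euclidean", "manhattan", "cosine", "mahalanobis")

#' Distance between two feature vectors
#'
#' The four similarity functions used for anomaly scoring, all oriented so
#' that larger values mean more anomalous:
#' Euclidean `sqrt(sum((x - y)^2))`; Manhattan `sum(|x - y|)`; cosine
#' dissimilarity `1 - cos(x, y)`; Mahalanobis
#' `sqrt((x - y)' Sreg^-1 (x - y))` with the regularized covariance of a
#' [CovarianceModel-class]. With an identity covariance the Mahalanobis
#' distance reduces to the Euclidean one.
#'
#' @param x,y numeric vectors of equal length.
#' @param kind one of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"mahalanobis"`.
#' @param cov a [CovarianceModel-class]; required iff `kind = "mahalanobis"`.
#' @return non-negative scalar.
#' @examples
#' featureDistance(c(0, 0), c(3, 4), "euclidean")  # 5
#' @export
featureDistance <- function(x, y, kind = .similarityKinds, cov = NULL) {
  kind <- match.arg(kind)
  .check(length(x) == length(y), "x and y must have equal length")
  .check(all(is.finite(x)) && all(is.finite(y)),
         "feature vectors must be finite")
  if (kind == "mahalanobis") {
    .check(is(cov, "CovarianceModel"),
           "mahalanobis distance requires a CovarianceModel")
  } else {
    .check(is.null(cov), "cov is only meaningful for kind = 'mahalanobis'")
  }
  switch(kind,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0)
        stop("cosine similarity undefined for a zero vector")
      max(0, 1 - sum(x * y) / (nx * ny))
    },
    mahalanobis = {
      d <- x - y
      # (x-y)' Sreg^-1 (x-y) via the cached Cholesky factor
      w <- backsolve(cov@cholReg, d, transpose = TRUE)
      sqrt(sum(w^2))
    })
}

# internal: distances from one query (row vector) to many reference rows
.batchDistances <- function(q, H, kind, cov = NULL) {
  if (nrow(H) == 0L) return(numeric(0))
  switch(kind,
    euclidean = sqrt(rowSums(sweep(H, 2, q)^2)),
    manhattan = rowSums(abs(sweep(H, 2, q))),
    cosine = {
      nq <- sqrt(sum(q^2)); nh <- sqrt(rowSums(H^2))
      if (nq == 0 || any(nh == 0))
        stop("cosine similarity undefined for a zero vector")
      pmax(0, 1 - as.numeric(H %*% q) / (nh * nq))
    },
    mahalanobis = {
      D <- sweep(H, 2, q)
      W <- t(backsolve(cov@cholReg, t(D), transpose = TRUE))
      sqrt(rowSums(W^2))
    })
}

#' Patch-wise anomaly score
#'
#' The anomaly score of a query patch feature is its distance to the
#' nearest reference embedding within the locality neighborhood of its grid
#' cell (Chebyshev radius d): the better the best match among nearby normal
#' patches, the lower the score. The identity of the best-matching
#' reference record is returned for provenance.
#'
#' @param q query feature vector.
#' @param size patch size in pixels.
#' @param gx,gy 0-based grid coordinates of the query patch.
#' @param db a [ReferenceDB-class].
#' @param kind similarity kind (see [featureDistance()]).
#' @param d Chebyshev patch distance; default: the DB's configured radius.
#' @return list with `score` (non-negative scalar), `bestIndex` (row into
#'   the size's record table), `bestImageId`, and the query location.
#'   Ties keep the first record in deterministic storage order.
#' @export
patchAnomalyScore <- function(q, size, gx, gy, db,
                              kind = .similarityKinds, d = NULL) {
  kind <- match.arg(kind)
  nb <- neighborhoodRecords(db, size, gx, gy, d)
  if (nrow(nb$H) == 0L)
    stop("empty neighborhood: reference database has no records near (",
         gx, ", ", gy, ") at size ", size)
  cov <- if (kind == "mahalanobis") {
    cm <- covarianceModel(db, size)
    .check(is(cm, "CovarianceModel"),
           "no covariance model fitted for size ", size)
    cm
  } else NULL
  dist <- .batchDistances(q, nb$H, kind, cov)
  best <- which.min(dist)
  list(score = dist[best], bestIndex = nb$index[best],
       bestImageId = nb$imageId[best], size = size, gx = gx, gy = gy)
}

#' Score every patch of an image at one resolution
#'
#' Tiles the image, embeds all patches with the size's encoder, and
#' computes the locality-restricted nearest-reference anomaly score for
#' every grid cell.
#'
#' @param image square numeric matrix (already at the DB's image side).
#' @param encoder the [PatchEncoder-class] for this size.
#' @param db a [ReferenceDB-class].
#' @param kind similarity kind.
#' @param d Chebyshev patch distance; default: the DB's configured radius.
#' @return data.frame with columns `size`, `gx`, `gy`, `score`,
#'   `bestImageId`, in row-major grid order.
#' @export
scoreImagePatches <- function(image, encoder, db, kind = .similarityKinds,
                              d = NULL) {
  kind <- match.arg(kind)
  size <- patchSize(encoder)
  .check(nrow(image) == imageSide(db),
         "image side does not match the reference database")
  if (is.null(d)) d <- localityRadius(db, size)
  emb <- .embedImagePatches(image, encoder)
  .scoreEmbeddedPatches(emb, db, size, kind, d)
}

# internal: score pre-embedded patches (lets callers embed once and score
# under several similarity kinds)
.scoreEmbeddedPatches <- function(emb, db, size, kind, d) {
  cov <- if (kind == "mahalanobis") covarianceModel(db, size) else NULL
  if (kind == "mahalanobis")
    .check(is(cov, "CovarianceModel"),
           "no covariance model fitted for size ", size)
  rec <- refRecords(db, size)
  n <- length(emb$gx)
  score <- numeric(n)
  bestId <- character(n)
  for (i in seq_len(n)) {
    sel <- which(pmax(abs(rec$gx - emb$gx[i]), abs(rec$gy - emb$gy[i])) <= d)
    if (length(sel) == 0L)
      stop("empty neighborhood at (", emb$gx[i], ", ", emb$gy[i], ")")
    dist <- .batchDistances(emb$H[i, ], rec$H[sel, , drop = FALSE],
                            kind, cov)
    j <- which.min(dist)
    score[i] <- dist[j]
    bestId[i] <- rec$imageId[sel[j]]
  }
  data.frame(size = size, gx = emb$gx, gy = emb$gy, score = score,
             bestImageId = bestId, stringsAsFactors = FALSE)
}
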