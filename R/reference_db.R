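#' Fit a regularized covariance model of reference features
#'
#' Computes the sample covariance (n-1 denominator) of a set of feature
#' vectors and shrinks it towards a scaled identity,
#' `Sreg = (1 - lambda) S + lambda * vbar * I`, where `vbar` is the mean
#' feature variance. When the feature dimension exceeds the number of
#' records the raw S is singular, so some shrinkage is required for the
#' Mahalanobis distance to be computable; `vbar` is floored at 1e-8 so Sreg
#' is positive definite even for degenerate (zero-variance) inputs.
#'
#' @param H n x p numeric matrix of feature vectors (rows), n >= 2.
#' @param lambda shrinkage coefficient in [0, 1] (default 0.1).
#' @return a [CovarianceModel-class].
#' @examples
#' H <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
#' fitCovariance(H, lambda = 0)@S  # diag(4/3, 4/3)
#' @export
fitCovariance <- function(H, lambda = 0.1) {
  H <- as.matrix(H)
  .check(nrow(H) >= 2L, "need at least 2 records to fit a covariance")
  .check(all(is.finite(H)), "non-finite feature values")
  .check(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  S <- stats::cov(H)
  vbar <- max(mean(diag(S)), 1e-8)
  Sreg <- (1 - lambda) * S + lambda * vbar * diag(ncol(H))
  U <- tryCatch(chol(Sreg), error = function(e)
    stop("regularized covariance is not positive definite; ",
         "increase lambda", call. = FALSE))
  new("CovarianceModel", S = S, Sreg = Sreg, cholReg = U, lambda = lambda)
}

#' Build the reference database of normal-patch embeddings
#'
#' For every normal training image, every configured patch size and every
#' grid cell, stores one embedding record (patch size, grid x, grid y,
#' image id, feature vector h) — the learned normal feature space that
#' query patches are compared against. A covariance model is fitted per
#' patch size over all that size's records for Mahalanobis scoring.
#'
#' @param normalImages named list of square numeric matrices (names become
#'   image ids), or a character vector of image paths.
#' @param encoders named list of trained [PatchEncoder-class] objects, one
#'   per configured patch size (names are the sizes).
#' @param patchSizes integer vector of patch sizes to index.
#' @param locality named integer vector: Chebyshev patch distance d per
#'   size (names matching `patchSizes`).
#' @param shrinkage covariance shrinkage lambda (see [fitCovariance()]).
#' @param imageSideOverride resize images to this side first (default: the
#'   side of the first image).
#' @return a [ReferenceDB-class].
#' @export
buildReferenceDB <- function(normalImages, encoders, patchSizes,
                             locality, shrinkage = 0.1,
                             imageSideOverride = NULL) {
  imgs <- .loadImageList(normalImages)
  .check(length(imgs) >= 1L, "empty image list: nothing to index")
  patchSizes <- sort(as.integer(patchSizes))
  key <- as.character(patchSizes)
  missing <- setdiff(key, names(encoders))
  if (length(missing))
    stop("missing encoder for configured patch size(s): ",
         paste(missing, collapse = ", "))
  locality <- .normalizeLocality(locality, patchSizes)
  side <- if (is.null(imageSideOverride)) nrow(imgs[[1L]])
          else as.integer(imageSideOverride)
  .check(all(side %% patchSizes == 0L),
         "every patch size must divide the image side")

  records <- setNames(vector("list", length(key)), key)
  for (k in key) {
    enc <- encoders[[k]]
    .check(patchSize(enc) == as.integer(k),
           sprintf("encoder registered under size %s has patchSize %d",
                   k, patchSize(enc)))
    Hs <- vector("list", length(imgs))
    gxs <- gys <- vector("list", length(imgs))
    ids <- vector("list", length(imgs))
    for (i in seq_along(imgs)) {
      img <- resizeImage(imgs[[i]], side)
      emb <- .embedImagePatches(img, enc)
      Hs[[i]] <- emb$H
      gxs[[i]] <- emb$gx
      gys[[i]] <- emb$gy
      ids[[i]] <- rep(names(imgs)[i], length(emb$gx))
    }
    records[[k]] <- list(H = do.call(rbind, Hs),
                         gx = unlist(gxs), gy = unlist(gys),
                         imageId = unlist(ids))
  }
  covariance <- lapply(records, function(r)
    if (nrow(r$H) >= 2L) fitCovariance(r$H, shrinkage) else NULL)
  prov <- list(
    encoderChecksums = vapply(encoders[key], function(e)
      .objectChecksum(e@params), character(1)),
    shrinkage = shrinkage, nImages = length(imgs),
    imageIds = names(imgs))
  new("ReferenceDB", imageSide = as.integer(side), patchSizes = patchSizes,
      records = records, covariance = covariance,
      locality = locality, provenance = prov)
}

# internal: accept list of matrices or vector of paths; ensure names
.loadImageList <- function(x) {
  if (is.character(x)) {
    imgs <- lapply(x, readImageGray)
    names(imgs) <- basename(x)
    return(imgs)
  }
  .check(is.list(x), "normalImages must be a list of matrices or paths")
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- sprintf("img%04d", seq_along(x))
  x
}

.normalizeLocality <- function(locality, patchSizes) {
  key <- as.character(patchSizes)
  loc <- as.integer(locality)
  names(loc) <- names(locality)
  .check(all(key %in% names(loc)),
         "locality must name a patch distance d for every patch size")
  .check(all(loc >= 0L), "patch distances d must be >= 0")
  loc[key]
}

#' Locality-restricted neighborhood query
#'
#' Returns all reference records of one patch size whose grid location lies
#' within Chebyshev distance d of (gx, gy):
#' `max(|gx - gx'|, |gy - gy'|) <= d`, clipped at the grid borders (no
#' wrap-around). `d = 0` returns only records at the query location itself;
#' `d >= gridDim - 1` returns every record of that size.
#'
#' @param db a [ReferenceDB-class].
#' @param size patch size in pixels.
#' @param gx,gy 0-based grid coordinates of the query cell.
#' @param d Chebyshev patch distance (default: the DB's configured radius
#'   for this size).
#' @return list with elements `H` (matrix of feature rows), `gx`, `gy`,
#'   `imageId`, `index` (row indices into the size's record table).
#' @export
neighborhoodRecords <- function(db, size, gx, gy, d = NULL) {
  rec <- refRecords(db, size)
  g <- imageSide(db) %/% as.integer(size)
  .check(gx >= 0L && gx < g && gy >= 0L && gy < g,
         sprintf("grid location (%d, %d) invalid for a %d x %d grid",
                 gx, gy, g, g))
  if (is.null(d)) d <- localityRadius(db, size)
  .check(d >= 0L, "patch distance d must be >= 0")
  sel <- which(pmax(abs(rec$gx - gx), abs(rec$gy - gy)) <= d)
  list(H = rec$H[sel, , drop = FALSE], gx = rec$gx[sel], gy = rec$gy[sel],
       imageId = rec$imageId[sel], index = sel)
}

#' Persist / restore a reference database
#'
#' The database is stored as one serialized binary container; a
#' human-readable JSON manifest (record counts, locality radii, provenance
#' checksums) is written alongside it.
#'
#' @param db a [ReferenceDB-class].
#' @param path container file path; the manifest is written to
#'   `paste0(path, ".manifest.json")`.
#' @return `saveReferenceDB` returns `path` invisibly; `loadReferenceDB`
#'   returns the [ReferenceDB-class].
#' @export
saveReferenceDB <- function(db, path) {
  saveRDS(list(format = "mrpad-refdb-v1", db = db), path)
  manifest <- list(
    format = "mrpad-refdb-v1",
    imageSide = imageSide(db),
    patchSizes = db@patchSizes,
    records = as.list(vapply(db@records, function(r) nrow(r$H), integer(1))),
    locality = as.list(db@locality),
    provenance = db@provenance)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveReferenceDB
#' @export
loadReferenceDB <- function(path) {
  obj <- readRDS(path)
  .check(identical(obj$format, "mrpad-refdb-v1"),
         "not an mrpad reference database: ", path)
  obj$db
}
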