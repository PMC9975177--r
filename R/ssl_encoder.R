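#' Configuration for self-supervised contrastive encoder training
#'
#' One encoder is trained per patch size with a SimCLR-style objective:
#' each patch yields two augmented views (random crop retaining
#' `cropFraction` of the area, resized back to patch size, then a rotation
#' uniform in +/- `rotationDeg` degrees), the backbone f maps each view to a
#' feature vector h, a projection head g maps h to z, and the NT-Xent loss
#' pulls the two views of a patch together against all other views in the
#' mini-batch. After training the head is discarded for inference: anomaly
#' scoring uses h only.
#'
#' @param temperature NT-Xent temperature tau (> 0). The source method does
#'   not pin this down; 0.5 is the common contrastive-learning default.
#' @param batchPairs N, patches per mini-batch (2N augmented views).
#' @param epochs training epochs.
#' @param cropFraction fraction of patch area retained by the random crop,
#'   in (0, 1]; the crop is resized back to the patch size.
#' @param rotationDeg maximum absolute rotation in degrees (>= 0).
#' @param featureDim dimension of the backbone feature h.
#' @param projectionDim dimension of the projection z.
#' @param hiddenDim hidden width of the default backbone.
#' @param inputSide side to which patches are bilinearly downsampled before
#'   the backbone.
#' @param lr base Adam learning rate (cosine-annealed to 0 over training).
#' @param seed RNG seed controlling initialization, shuffling, augmentation.
#' @param backbone backbone identifier; `"mlp"` is the built-in
#'   fully-connected backbone.
#' @return validated config list of class `"sslConfig"`.
#' @export
sslConfig <- function(temperature = 0.5, batchPairs = 32L, epochs = 8L,
                      cropFraction = 0.5, rotationDeg = 5, featureDim = 64L,
                      projectionDim = 32L, hiddenDim = 128L, inputSide = 16L,
                      lr = 1e-3, seed = 1L, backbone = "mlp") {
  .check(is.numeric(temperature) && temperature > 0,
         "temperature must be > 0")
  .check(batchPairs >= 1, "batchPairs must be >= 1")
  .check(cropFraction > 0 && cropFraction <= 1,
         "cropFraction must lie in (0, 1]")
  .check(rotationDeg >= 0, "rotationDeg must be >= 0")
  .check(epochs >= 1, "epochs must be >= 1")
  structure(list(temperature = temperature, batchPairs = as.integer(batchPairs),
                 epochs = as.integer(epochs), cropFraction = cropFraction,
                 rotationDeg = rotationDeg, featureDim = as.integer(featureDim),
                 projectionDim = as.integer(projectionDim),
                 hiddenDim = as.integer(hiddenDim),
                 inputSide = as.integer(inputSide), lr = lr,
                 seed = as.integer(seed), backbone = backbone),
            class = "sslConfig")
}

#' Generate two augmented views of a patch
#'
#' Each view is sampled independently: a square sub-window retaining
#' `cropFraction` of the patch area is taken at a uniform random position
#' and bilinearly resized back to the patch size, then rotated by an angle
#' uniform in +/- `rotationDeg` degrees (bilinear, about the centre; corners
#' exposed by the rotation are filled with 0). With `cropFraction = 1` and
#' `rotationDeg = 0` both views equal the patch exactly. Randomness comes
#' from the current R RNG stream, so seeding the stream makes the pair
#' reproducible.
#'
#' @param patch a patch from [tileImage()] (or any list with a `pixels`
#'   matrix).
#' @param config an [sslConfig()].
#' @return list of two matrices `viewA`, `viewB` at the patch size.
#' @export
augmentPair <- function(patch, config) {
  px <- patch$pixels
  .check(is.matrix(px) && length(px) > 0, "patch has no pixels")
  list(viewA = .augmentOnce(px, config), viewB = .augmentOnce(px, config))
}

.augmentOnce <- function(px, config) {
  s <- nrow(px)
  cropSide <- max(1L, as.integer(round(s * sqrt(config$cropFraction))))
  v <- px
  if (cropSide < s) {
    oy <- sample.int(s - cropSide + 1L, 1L) - 1L
    ox <- sample.int(s - cropSide + 1L, 1L) - 1L
    v <- px[(oy + 1L):(oy + cropSide), (ox + 1L):(ox + cropSide),
            drop = FALSE]
    v <- resizeImage(v, s)
  }
  if (config$rotationDeg > 0 && s > 1L) {
    ang <- runif(1, -config$rotationDeg, config$rotationDeg)
    v <- EBImage::imageData(EBImage::rotate(EBImage::Image(v), ang,
                                            output.dim = c(s, s)))
    v <- matrix(as.numeric(v), s, s)
  }
  v
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' The contrastive loss over a batch of 2N projection vectors: for an
#' anchor i with positive partner j,
#' `l(i,j) = -log( exp(sim(z_i,z_j)/tau) / sum_{k != i} exp(sim(z_i,z_k)/tau) )`
#' with `sim` the cosine similarity, and the batch loss is the mean of
#' l over all 2N ordered anchor-positive terms.
#'
#' @param projections 2N x m numeric matrix, one projection vector per row.
#' @param pairing integer vector of length 2N; `pairing[i]` is the row index
#'   of i's positive partner (a perfect matching: `pairing[pairing[i]] == i`
#'   and `pairing[i] != i`).
#' @param temperature tau > 0.
#' @param gradient if TRUE, also return the exact gradient of the loss with
#'   respect to `projections`.
#' @return the scalar loss, or (with `gradient = TRUE`) a list with elements
#'   `loss` and `grad`.
#' @examples
#' z <- matrix(rnorm(8 * 3), 8, 3)
#' ntXentLoss(z, c(2, 1, 4, 3, 6, 5, 8, 7), temperature = 0.5)
#' @export
ntXentLoss <- function(projections, pairing, temperature, gradient = FALSE) {
  Z <- as.matrix(projections)
  n <- nrow(Z)
  .check(is.numeric(temperature) && length(temperature) == 1L &&
           temperature > 0, "temperature must be a single value > 0")
  .check(n >= 2L && n %% 2L == 0L, "need an even number (2N) of projections")
  pairing <- as.integer(pairing)
  .check(length(pairing) == n && all(pairing >= 1L & pairing <= n) &&
           all(pairing != seq_len(n)) &&
           all(pairing[pairing] == seq_len(n)),
         "pairing must be a perfect matching of the 2N rows")
  .check(all(is.finite(Z)), "projections must be finite")
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0))
    stop("zero-norm projection vector: cosine similarity undefined")
  U <- Z / norms
  S <- tcrossprod(U) / temperature          # s_ik = cos(z_i, z_k)/tau
  diag(S) <- -Inf                           # k != i excluded from the sum
  rowMax <- apply(S, 1, max)
  E <- exp(S - rowMax)                      # stable log-sum-exp
  rowSumE <- rowSums(E)
  lse <- rowMax + log(rowSumE)
  pos <- S[cbind(seq_len(n), pairing)]
  loss <- mean(lse - pos)
  if (!gradient) return(loss)
  # dLoss/dS[i,k] for k != i: (softmax_ik - 1[k = pairing[i]]) / n
  P <- E / rowSumE
  G <- P
  G[cbind(seq_len(n), pairing)] <- G[cbind(seq_len(n), pairing)] - 1
  G <- G / n
  diag(G) <- 0
  # dLoss/dU = (G + t(G)) %*% U / tau ; then through the row normalization
  dU <- (G + t(G)) %*% U / temperature
  dZ <- (dU - U * rowSums(dU * U)) / norms
  list(loss = loss, grad = dZ)
}

# internal: flatten a stack of views into the backbone input matrix.
# Patches larger than the backbone input are reduced by exact block
# averaging (area pooling) when the sides divide, so that small
# high-contrast structure contributes in proportion to its area instead of
# being aliased away by point-sampled decimation; bilinear resampling is
# the fallback for non-divisible sides.
.encoderInputs <- function(views, inputSide) {
  s <- nrow(views[[1L]])
  A <- if (s != inputSide && s %% inputSide == 0L) {
    f <- s %/% inputSide
    kronecker(diag(inputSide), matrix(1 / f, 1, f))   # inputSide x s
  } else NULL
  t(vapply(views, function(v) {
    if (nrow(v) != inputSide) {
      v <- if (!is.null(A) && nrow(v) == s) A %*% v %*% t(A)
           else resizeImage(v, inputSide)
    }
    as.numeric(v)
  }, numeric(inputSide * inputSide)))
}

#' Train a contrastive patch encoder
#'
#' Runs SimCLR-style training on a collection of same-size patches: per
#' mini-batch of N patches, two augmented views each are embedded by the
#' backbone, projected by the head, and the NT-Xent loss is minimized with
#' Adam under a cosine learning-rate schedule. Fully deterministic for a
#' fixed `config$seed`.
#'
#' @param patches list of patches from [tileImage()], all of one size.
#' @param config an [sslConfig()].
#' @param verbose print per-epoch losses.
#' @return a trained [PatchEncoder-class] (with the projection head retained
#'   in `params` for inspection; inference uses the backbone only).
#' @export
trainEncoder <- function(patches, config, verbose = FALSE) {
  .check(inherits(config, "sslConfig"), "config must come from sslConfig()")
  .check(length(patches) >= 1L, "no patches to train on")
  sizes <- unique(vapply(patches, function(p) nrow(p$pixels), integer(1)))
  .check(length(sizes) == 1L, "patches must all share one size")
  s <- sizes[[1L]]
  inputSide <- min(config$inputSide, s)
  inputDim <- inputSide^2
  bb <- .backboneRegistry[[config$backbone]]
  if (is.null(bb))
    stop(sprintf("backbone '%s' is not available in this build",
                 config$backbone))

  set.seed(config$seed)
  params <- c(bb$init(inputDim, config), .headInit(config))
  opt <- .adamInit(params)
  nP <- length(patches)
  batches <- max(1L, ceiling(nP / config$batchPairs))
  totalSteps <- batches * config$epochs
  lossCurve <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nP)
    epochLoss <- numeric(0)
    for (b in seq_len(batches)) {
      idx <- ord[(((b - 1L) * config$batchPairs) + 1L):
                   min(b * config$batchPairs, nP)]
      N <- length(idx)
      views <- vector("list", 2L * N)
      for (i in seq_len(N)) {
        pr <- augmentPair(patches[[idx[i]]], config)
        views[[i]] <- pr$viewA
        views[[N + i]] <- pr$viewB
      }
      X <- .encoderInputs(views, inputSide)
      pairing <- c((N + 1L):(2L * N), 1L:N)
      fb <- bb$forward(X, params)
      fh <- .headForward(fb$out, params)
      lg <- ntXentLoss(fh$out, pairing, config$temperature, gradient = TRUE)
      epochLoss <- c(epochLoss, lg$loss)
      if (N > 1L) {
        hb <- .headBackward(lg$grad, fh$cache, params)
        gradsBB <- bb$backward(hb$dH, fb$cache, params)
        step <- (epoch - 1L) * batches + b
        lr <- .cosineLr(config$lr, step, totalSteps)
        upd <- .adamStep(params, c(gradsBB, hb$grads), opt, lr)
        params <- upd$params
        opt <- upd$state
      }
    }
    lossCurve[epoch] <- mean(epochLoss)
    if (verbose)
      message(sprintf("epoch %d/%d: NT-Xent %.4f", epoch, config$epochs,
                      lossCurve[epoch]))
  }
  new("PatchEncoder", patchSize = as.integer(s),
      inputSide = as.integer(inputSide), backbone = config$backbone,
      params = params, config = unclass(config), lossCurve = lossCurve)
}

#' Embed a patch with a trained encoder
#'
#' Inference-mode feature extraction: the patch is downsampled to the
#' encoder's input side and passed through the backbone f only (the
#' projection head plays no part). Deterministic: the same patch always
#' yields the same feature vector.
#'
#' @param patch a patch from [tileImage()] (size must match the encoder).
#' @param encoder a trained [PatchEncoder-class].
#' @return numeric feature vector of length `featureDim(encoder)`.
#' @export
embedPatch <- function(patch, encoder) {
  .check(nrow(patch$pixels) == patchSize(encoder),
         sprintf("patch size %d does not match encoder size %d",
                 nrow(patch$pixels), patchSize(encoder)))
  drop(.embedMatrix(.encoderInputs(list(patch$pixels), encoder@inputSide),
                    encoder))
}

# internal: batch embedding of pre-flattened inputs (rows)
.embedMatrix <- function(X, encoder) {
  bb <- .backboneRegistry[[encoder@backbone]]
  bb$forward(X, encoder@params)$out
}

# internal: embed every tile of an image at one size; returns list(H, gx, gy)
.embedImagePatches <- function(image, encoder) {
  spec <- patchSpec(patchSize(encoder), nrow(image))
  patches <- tileImage(image, spec)
  X <- .encoderInputs(lapply(patches, `[[`, "pixels"), encoder@inputSide)
  list(H = .embedMatrix(X, encoder),
       gx = vapply(patches, `[[`, integer(1), "gx"),
       gy = vapply(patches, `[[`, integer(1), "gy"))
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints are a versioned serialized container embedding the full
#' training configuration, so a loaded encoder reproduces embeddings
#' bit-exactly.
#'
#' @param encoder a [PatchEncoder-class].
#' @param path checkpoint file path.
#' @return `saveEncoder` returns `path` invisibly; `loadEncoder` returns the
#'   [PatchEncoder-class].
#' @export
saveEncoder <- function(encoder, path) {
  saveRDS(list(format = "mrpad-encoder-v1", encoder = encoder), path)
  invisible(path)
}

#' @rdname saveEncoder
#' @export
loadEncoder <- function(path) {
  obj <- readRDS(path)
  .check(identical(obj$format, "mrpad-encoder-v1"),
         "not an mrpad encoder checkpoint: ", path)
  obj$encoder
}

#' Export a training loss curve as CSV
#'
#' @param encoder a trained [PatchEncoder-class].
#' @param path output CSV path (columns `epoch`, `mean_loss`).
#' @return `path`, invisibly.
#' @export
writeLossCurve <- function(encoder, path) {
  write.csv(data.frame(epoch = seq_along(lossCurve(encoder)),
                       mean_loss = lossCurve(encoder)),
            path, row.names = FALSE)
  invisible(path)
}
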