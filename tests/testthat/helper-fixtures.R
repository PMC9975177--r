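# Shared fixtures for the test suite. Everything is generated in code; no
# binary fixtures on disk.

# a quick training configuration for module tests (not the study fixture)
quickSSL <- function(epochs = 2L, seed = 1L, batchPairs = 8L, ...) {
  sslConfig(epochs = epochs, seed = seed, batchPairs = batchPairs,
            inputSide = 8L, hiddenDim = 16L, featureDim = 8L,
            projectionDim = 4L, ...)
}

# hand-build a ReferenceDB with given per-size record tables; used by
# neighborhood / scoring tests so expected values can be enumerated
handDB <- function(imageSide, recordsBySize, locality, shrinkage = 0.1) {
  sizes <- sort(as.integer(names(recordsBySize)))
  covariance <- lapply(recordsBySize, function(r)
    if (nrow(r$H) >= 2L) fitCovariance(r$H, shrinkage) else NULL)
  new("ReferenceDB", imageSide = as.integer(imageSide), patchSizes = sizes,
      records = recordsBySize[as.character(sizes)],
      covariance = covariance[as.character(sizes)],
      locality = setNames(as.integer(locality[as.character(sizes)]),
                          as.character(sizes)),
      provenance = list())
}

# records for a full g x g grid at one size: nPerCell random feature rows
# per grid cell, deterministic under the current RNG stream
gridRecords <- function(g, dim, nPerCell = 2L) {
  cells <- expand.grid(gx = 0:(g - 1L), gy = 0:(g - 1L))
  idx <- rep(seq_len(nrow(cells)), each = nPerCell)
  list(H = matrix(rnorm(length(idx) * dim), ncol = dim),
       gx = cells$gx[idx], gy = cells$gy[idx],
       imageId = sprintf("img%03d", seq_along(idx)))
}

# brute-force NT-Xent: direct term-by-term evaluation of the loss,
# independent of the vectorized implementation
bruteNTXent <- function(Z, pairing, tau) {
  n <- nrow(Z)
  cosSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  total <- 0
  for (i in seq_len(n)) {
    j <- pairing[i]
    num <- exp(cosSim(Z[i, ], Z[j, ]) / tau)
    den <- 0
    for (k in seq_len(n)) if (k != i) den <- den + exp(cosSim(Z[i, ], Z[k, ]) / tau)
    total <- total - log(num / den)
  }
  total / n
}

# brute-force AUROC by positive-negative pair counting (ties count 1/2)
bruteAUROC <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# naive per-element distance computations (independent oracles)
naiveDistance <- function(x, y, kind, Sreg = NULL) {
  n <- length(x)
  if (kind == "euclidean") {
    acc <- 0; for (i in 1:n) acc <- acc + (x[i] - y[i])^2; sqrt(acc)
  } else if (kind == "manhattan") {
    acc <- 0; for (i in 1:n) acc <- acc + abs(x[i] - y[i]); acc
  } else if (kind == "cosine") {
    num <- 0; nx <- 0; ny <- 0
    for (i in 1:n) { num <- num + x[i] * y[i]; nx <- nx + x[i]^2; ny <- ny + y[i]^2 }
    1 - num / sqrt(nx * ny)
  } else {
    d <- x - y
    sqrt(drop(t(d) %*% solve(Sreg) %*% d))
  }
}

# a small in-memory phantom dataset for pipeline-level tests
tinyDataset <- function(seed = 7L, side = 32L, nTrain = 8L, nVal = 3L,
                        nTest = 3L) {
  dir <- file.path(tempdir(), sprintf("tinyds_%d_%d", seed, side))
  if (!dir.exists(dir))
    makeDataset(dir, nNormalTrain = nTrain, nValPairs = nVal,
                nTestPairs = nTest, phantom = phantomConfig(side = side),
                anomaly = anomalySpec(diameterRange = c(4, 12)), seed = seed)
  dir
}

tinyConfig <- function(...) {
  defaultPipelineConfig("desk", imageSide = 32L, patchSizes = c(8L, 16L, 32L),
                        locality = c("8" = 1L, "16" = 1L, "32" = 0L),
                        weights = c("8" = 0.5, "16" = 1, "32" = 1),
                        ssl = quickSSL(), ...)
}
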