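# Internal minimal neural-net machinery for contrastive encoder training.
# Vectorized base-R matrix ops; gradients are exact (checked against finite
# differences in the test suite). Backbones are pluggable: an entry in
# .backboneRegistry provides init / forward / backward with the signatures
# used below, so a different architecture can be swapped in without touching
# the training loop.

.heInit <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# --- backbone: two-layer fully-connected net on downsampled patch pixels ---
# input (B x inputDim) -> ReLU(X W1 + b1) -> H1 W2 + b2 = features h

.mlpInit <- function(inputDim, cfg) {
  list(W1 = .heInit(inputDim, cfg$hiddenDim),
       b1 = numeric(cfg$hiddenDim),
       W2 = .heInit(cfg$hiddenDim, cfg$featureDim),
       b2 = numeric(cfg$featureDim))
}

.mlpForward <- function(X, params) {
  A1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(A1, 0)
  H <- sweep(H1 %*% params$W2, 2, params$b2, "+")
  list(out = H, cache = list(X = X, A1 = A1, H1 = H1))
}

.mlpBackward <- function(dH, cache, params) {
  dW2 <- crossprod(cache$H1, dH)
  db2 <- colSums(dH)
  dH1 <- dH %*% t(params$W2)
  dA1 <- dH1 * (cache$A1 > 0)
  dW1 <- crossprod(cache$X, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

.backboneRegistry <- list(
  mlp = list(init = .mlpInit, forward = .mlpForward, backward = .mlpBackward)
)

# --- projection head: h -> ReLU(h W3 + b3) W4 + b4 = z (training only) ---

.headInit <- function(cfg) {
  list(W3 = .heInit(cfg$featureDim, cfg$featureDim),
       b3 = numeric(cfg$featureDim),
       W4 = .heInit(cfg$featureDim, cfg$projectionDim),
       b4 = numeric(cfg$projectionDim))
}

.headForward <- function(H, params) {
  A3 <- sweep(H %*% params$W3, 2, params$b3, "+")
  H3 <- pmax(A3, 0)
  Z <- sweep(H3 %*% params$W4, 2, params$b4, "+")
  list(out = Z, cache = list(H = H, A3 = A3, H3 = H3))
}

.headBackward <- function(dZ, cache, params) {
  dW4 <- crossprod(cache$H3, dZ)
  db4 <- colSums(dZ)
  dH3 <- dZ %*% t(params$W4)
  dA3 <- dH3 * (cache$A3 > 0)
  dW3 <- crossprod(cache$H, dA3)
  db3 <- colSums(dA3)
  dH <- dA3 %*% t(params$W3)
  list(grads = list(W3 = dW3, b3 = db3, W4 = dW4, b4 = db4), dH = dH)
}

# --- Adam with cosine-annealed learning rate ---

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.cosineLr <- function(lr0, step, totalSteps) {
  if (totalSteps <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (step - 1L) / (totalSteps - 1L)))
}
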