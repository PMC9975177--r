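test_that("NT-Xent matches the brute-force oracle on random batches", {
  set.seed(101)
  for (N in c(2, 4, 8)) {
    for (rep in 1:5) {
      Z <- matrix(rnorm(2 * N * 5), 2 * N, 5)
      pairing <- c((N + 1):(2 * N), 1:N)
      tau <- runif(1, 0.2, 2)
      expect_equal(ntXentLoss(Z, pairing, tau),
                   bruteNTXent(Z, pairing, tau), tolerance = 1e-6)
    }
  }
})

test_that("NT-Xent limiting cases behave as the loss structure dictates", {
  set.seed(5)
  # one pair, no negatives: the denominator holds only the positive term
  Z <- matrix(rnorm(2 * 3), 2, 3)
  expect_equal(ntXentLoss(Z, c(2, 1), 0.5), 0)
  expect_equal(ntXentLoss(Z, c(2, 1), 7), 0)
  # flat-logit limit: loss -> log(2N - 1)
  Z <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(ntXentLoss(Z, c(5:8, 1:4), 1e6), log(7), tolerance = 1e-3)
})

test_that("NT-Xent is scale-free and monotone in the positive similarity", {
  set.seed(6)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  pairing <- c(4:6, 1:3)
  expect_equal(ntXentLoss(Z, pairing, 0.5),
               ntXentLoss(3.7 * Z, pairing, 0.5), tolerance = 1e-12)

  # pulling a positive pair together (negatives fixed) lowers the loss
  base <- matrix(rnorm(4 * 3), 4, 3)
  pairing <- c(2, 1, 4, 3)
  closer <- base
  closer[2, ] <- 0.2 * base[2, ] + 0.8 * base[1, ]
  expect_lt(ntXentLoss(closer, pairing, 0.5),
            ntXentLoss(base, pairing, 0.5))
})

test_that("NT-Xent rejects invalid input", {
  Z <- matrix(rnorm(4 * 3), 4, 3)
  expect_error(ntXentLoss(Z, c(2, 1, 4, 3), -1), "temperature")
  expect_error(ntXentLoss(Z, c(2, 1, 4, 3), 0), "temperature")
  expect_error(ntXentLoss(Z, c(1, 2, 3, 4), 0.5), "matching")
  Z[1, ] <- 0
  expect_error(ntXentLoss(Z, c(2, 1, 4, 3), 0.5), "zero-norm")
})

test_that("analytic NT-Xent gradient matches finite differences", {
  set.seed(11)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  pairing <- c(4:6, 1:3)
  g <- ntXentLoss(Z, pairing, 0.7, gradient = TRUE)
  eps <- 1e-6
  num <- Z * 0
  for (i in seq_along(Z)) {
    Zp <- Z; Zp[i] <- Zp[i] + eps
    Zm <- Z; Zm[i] <- Zm[i] - eps
    num[i] <- (ntXentLoss(Zp, pairing, 0.7) -
                 ntXentLoss(Zm, pairing, 0.7)) / (2 * eps)
  }
  expect_lt(max(abs(num - g$grad)), 1e-7)
})

test_that("augmentation produces identity views when disabled and is seeded", {
  img <- matrix(runif(32 * 32), 32, 32)
  p <- tileImage(img, patchSpec(16, 32))[[2]]

  idCfg <- sslConfig(cropFraction = 1, rotationDeg = 0)
  v <- augmentPair(p, idCfg)
  expect_identical(v$viewA, p$pixels)
  expect_identical(v$viewB, p$pixels)

  cfg <- sslConfig(cropFraction = 0.5, rotationDeg = 5)
  set.seed(99); v1 <- augmentPair(p, cfg)
  set.seed(99); v2 <- augmentPair(p, cfg)
  expect_identical(v1, v2)
  set.seed(100); v3 <- augmentPair(p, cfg)
  expect_false(identical(v1$viewA, v3$viewA))
  expect_equal(dim(v1$viewA), dim(p$pixels))
  expect_false(identical(v1$viewA, v1$viewB))  # independent views
})

test_that("encoder training lowers the contrastive loss and is reproducible", {
  set.seed(21)
  imgs <- lapply(1:6, function(i) generateNormal(phantomConfig(side = 32),
                                                 seed = i))
  patches <- unlist(lapply(imgs, tileImage, spec = patchSpec(8, 32)),
                    recursive = FALSE)
  cfg <- quickSSL(epochs = 4L, seed = 3L)
  enc <- trainEncoder(patches, cfg)
  curve <- lossCurve(enc)
  expect_length(curve, 4L)
  expect_lte(curve[4], curve[1])
  expect_identical(lossCurve(trainEncoder(patches, cfg)), curve)
})

test_that("a single-patch dataset trains with identically zero loss", {
  img <- matrix(runif(8 * 8), 8, 8)
  p <- tileImage(img, patchSpec(8, 8))
  enc <- trainEncoder(p, quickSSL(epochs = 3L, batchPairs = 1L))
  expect_equal(unname(lossCurve(enc)), c(0, 0, 0))
})

test_that("embedding is deterministic, sized, and guards patch size", {
  set.seed(31)
  img <- matrix(runif(32 * 32), 32, 32)
  patches <- tileImage(img, patchSpec(8, 32))
  enc <- trainEncoder(patches, quickSSL(seed = 2L))
  h <- embedPatch(patches[[5]], enc)
  expect_length(h, 8L)                     # featureDim of quickSSL
  expect_identical(h, embedPatch(patches[[5]], enc))
  big <- tileImage(img, patchSpec(16, 32))[[1]]
  expect_error(embedPatch(big, enc), "does not match")
})

test_that("encoder checkpoints round-trip with embedded config", {
  set.seed(41)
  img <- matrix(runif(16 * 16), 16, 16)
  patches <- tileImage(img, patchSpec(8, 16))
  enc <- trainEncoder(patches, quickSSL())
  f <- tempfile(fileext = ".rds")
  saveEncoder(enc, f)
  enc2 <- loadEncoder(f)
  expect_identical(enc2@params, enc@params)
  expect_identical(embedPatch(patches[[1]], enc2),
                   embedPatch(patches[[1]], enc))
  # loss curve CSV export
  csv <- tempfile(fileext = ".csv")
  writeLossCurve(enc, csv)
  tab <- read.csv(csv)
  expect_equal(names(tab), c("epoch", "mean_loss"))
  expect_equal(tab$mean_loss, unname(lossCurve(enc)))
})

test_that("the paper-scale profile records its settings but cannot train here", {
  cfg <- defaultPipelineConfig("paper")
  expect_equal(cfg$patchSizes, c(128L, 256L, 512L, 1024L))
  expect_equal(unname(cfg$locality), c(2L, 1L, 0L, 0L))
  expect_equal(unname(cfg$weights), c(0.1, 1.2, 1.2, 1.0))
  expect_equal(cfg$ssl$featureDim, 2048L)
  expect_equal(cfg$ssl$projectionDim, 128L)
  expect_equal(cfg$ssl$batchPairs, 256L)
  expect_equal(cfg$ssl$epochs, 100L)
  expect_equal(cfg$ssl$optimizer, "lars")
  expect_equal(cfg$ssl$lr, 4.8)
  expect_equal(cfg$ssl$weightDecay, 1e-6)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_error(trainEncoder(tileImage(img, patchSpec(8, 16)), cfg$ssl),
               "backbone")
})
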