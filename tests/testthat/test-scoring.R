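covFromSreg <- function(Sreg) {
  new("CovarianceModel", S = Sreg, Sreg = Sreg, cholReg = chol(Sreg),
      lambda = 0)
}

test_that("distance kinds reproduce hand-computed values", {
  expect_equal(featureDistance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(featureDistance(c(1, 2), c(4, 6), "manhattan"), 7)
  expect_equal(featureDistance(c(2, 0), c(5, 0), "cosine"), 0)

  # Mahalanobis with identity covariance is exactly Euclidean
  id <- covFromSreg(diag(2))
  x <- c(1.3, -2); y <- c(0.4, 5)
  expect_identical(featureDistance(x, y, "mahalanobis", id),
                   featureDistance(x, y, "euclidean"))

  # direct evaluation with an anisotropic covariance
  cm <- covFromSreg(diag(c(4, 1)))
  expect_equal(featureDistance(c(1, 0), c(0, 1), "mahalanobis", cm),
               sqrt(1 / 4 + 1))
})

test_that("distances agree with naive loops, vanish at identity, symmetric", {
  set.seed(81)
  for (rep in 1:50) {
    n <- sample(2:32, 1)
    x <- rnorm(n); y <- rnorm(n)
    A <- matrix(rnorm(n * (n + 2)), n + 2, n)
    Sreg <- crossprod(A) / (n + 2) + 0.1 * diag(n)
    cm <- covFromSreg(Sreg)
    for (kind in c("euclidean", "manhattan", "cosine", "mahalanobis")) {
      cov <- if (kind == "mahalanobis") cm else NULL
      d <- featureDistance(x, y, kind, cov)
      expect_equal(d, naiveDistance(x, y, kind, Sreg), tolerance = 1e-9)
      expect_equal(featureDistance(y, x, kind, cov), d, tolerance = 1e-12)
      expect_equal(featureDistance(x, x, kind, cov), 0, tolerance = 1e-9)
    }
  }
})

test_that("distance input validation catches the degenerate cases", {
  expect_error(featureDistance(1:3, 1:4, "euclidean"), "equal length")
  expect_error(featureDistance(c(0, 0), c(1, 1), "cosine"), "zero vector")
  expect_error(featureDistance(c(1, 2), c(3, 4), "mahalanobis"),
               "CovarianceModel")
  expect_error(featureDistance(c(1, 2), c(3, 4), "euclidean",
                               cov = covFromSreg(diag(2))),
               "only meaningful")
})

test_that("patch anomaly score is the neighborhood minimum distance", {
  # three hand-placed references in one cell; brute force over all of them
  rec <- list(H = rbind(c(1, 0), c(0, 2), c(3, 3)),
              gx = c(0L, 0L, 0L), gy = c(0L, 0L, 0L),
              imageId = c("a", "b", "c"))
  db <- handDB(16L, list("16" = rec), c("16" = 0L))
  ps <- patchAnomalyScore(c(0, 0), 16, 0, 0, db, "euclidean")
  expect_equal(ps$score, min(sqrt(rowSums(rec$H^2))))
  expect_equal(ps$bestImageId, "a")

  # a query equal to a stored reference scores exactly zero
  self <- patchAnomalyScore(c(0, 2), 16, 0, 0, db, "euclidean")
  expect_equal(self$score, 0)
  expect_equal(self$bestImageId, "b")
})

test_that("widening the locality radius never raises the score and reaches the global minimum", {
  set.seed(91)
  for (rep in 1:100) {
    g <- sample(2:5, 1)
    dim <- sample(2:6, 1)
    rec <- gridRecords(g, dim, nPerCell = sample(1:3, 1))
    db <- handDB(g * 16L, list("16" = rec), c("16" = 0L))
    q <- rnorm(dim)
    gx <- sample(0:(g - 1L), 1); gy <- sample(0:(g - 1L), 1)
    kind <- sample(c("euclidean", "manhattan", "cosine"), 1)
    scores <- vapply(0:(g - 1L), function(d)
      patchAnomalyScore(q, 16, gx, gy, db, kind, d = d)$score, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
    # exhaustive global search oracle at d >= gridDim - 1
    glob <- min(vapply(seq_len(nrow(rec$H)), function(i)
      featureDistance(q, rec$H[i, ], kind), numeric(1)))
    expect_equal(scores[g], glob, tolerance = 1e-12)
  }
})

test_that("batch image scoring matches per-patch scoring", {
  set.seed(95)
  img <- generateNormal(phantomConfig(side = 32), seed = 4)
  enc <- trainEncoder(tileImage(img, patchSpec(8, 32)), quickSSL())
  db <- buildReferenceDB(list(a = img), list("8" = enc), 8L, c("8" = 1L))
  tab <- scoreImagePatches(img, enc, db, kind = "euclidean")
  expect_equal(nrow(tab), 16L)
  # every patch of the indexed image self-matches
  expect_true(all(tab$score < 1e-8))
  # spot-check against the single-patch entry point
  q <- embedPatch(tileImage(img, patchSpec(8, 32))[[2]], enc)
  one <- patchAnomalyScore(q, 8, 1, 0, db, "euclidean")
  expect_equal(tab$score[tab$gx == 1 & tab$gy == 0], one$score)
})
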