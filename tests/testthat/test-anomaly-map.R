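# calibration with known quantile bounds for algebra tests
flatCal <- function(sizes, lo = 0, hi = 1) {
  key <- as.character(sizes)
  new("ScoreCalibration", qLo = setNames(rep(lo, length(sizes)), key),
      qHi = setNames(rep(hi, length(sizes)), key), threshold = 0.5,
      epsilon = 1e-6)
}

rawMap <- function(m, size) new("AnomalyMap", map = m,
                                sizePx = as.integer(size), fused = FALSE)

test_that("resolution maps are piecewise-constant and localize a perturbed tile", {
  set.seed(105)
  img <- generateNormal(phantomConfig(side = 32), seed = 9)
  enc <- trainEncoder(tileImage(img, patchSpec(16, 32)), quickSSL())
  db <- buildReferenceDB(list(a = img), list("16" = enc), 16L, c("16" = 1L))

  # the indexed image itself: every patch self-matches, map is all zero
  m0 <- resolutionMap(img, enc, db, kind = "euclidean")
  expect_true(all(mapData(m0) < 1e-8))
  expect_equal(dim(mapData(m0)), c(32L, 32L))

  # a 2x2 grid map holds at most 4 distinct values
  expect_lte(length(unique(as.vector(mapData(m0)))), 4L)

  # perturbing exactly one tile puts the map maximum on that tile's block
  img2 <- img
  img2[17:32, 1:16] <- img2[17:32, 1:16] + 0.5   # tile gx = 0, gy = 1
  m1 <- mapData(resolutionMap(img2, enc, db, kind = "euclidean"))
  block <- m1[17:32, 1:16]
  expect_true(all(block == max(m1)))
  expect_true(all(m1[1:16, ] < max(m1)))
})

test_that("single-map fusion is the calibrated map itself", {
  set.seed(110)
  A <- matrix(runif(64, 0.2, 0.8), 8, 8)
  cal <- flatCal(8)
  fused <- fuseMaps(list(rawMap(A, 8)), c("8" = 1), cal)
  expect_true(isFused(fused))
  expect_equal(mapData(fused), pmin(pmax(A, 1e-6), 1), tolerance = 1e-12)
})

test_that("fusion is order-invariant and weight-scale invariant", {
  set.seed(111)
  maps <- list(rawMap(matrix(runif(64), 8, 8), 2),
               rawMap(matrix(runif(64), 8, 8), 4),
               rawMap(matrix(runif(64), 8, 8), 8))
  cal <- flatCal(c(2, 4, 8))
  w <- c("2" = 0.1, "4" = 1.2, "8" = 1.0)
  f1 <- fuseMaps(maps, w, cal)
  f2 <- fuseMaps(rev(maps), w, cal)
  expect_identical(mapData(f1), mapData(f2))      # bit-exact

  # doubling every weight: identical fused map (power-of-two scaling)
  f3 <- fuseMaps(maps, 2 * w, cal)
  expect_identical(mapData(f3), mapData(f1))
  # non-dyadic scaling: equal to numerical precision
  f4 <- fuseMaps(maps, 3 * w, cal)
  expect_equal(mapData(f4), mapData(f1), tolerance = 1e-12)
})

test_that("geometric and literal modes coincide at unit weights", {
  set.seed(112)
  maps <- list(rawMap(matrix(runif(16), 4, 4), 2),
               rawMap(matrix(runif(16), 4, 4), 4))
  cal <- flatCal(c(2, 4))
  g <- fuseMaps(maps, c("2" = 1, "4" = 1), cal, mode = "geometric")
  l <- fuseMaps(maps, c("2" = 1, "4" = 1), cal, mode = "literal")
  expect_equal(mapData(g), mapData(l), tolerance = 1e-12)
})

test_that("fused maps stay in [0, 1] and respond monotonically", {
  set.seed(113)
  A <- matrix(runif(64), 8, 8); B <- matrix(runif(64), 8, 8)
  cal <- flatCal(c(2, 4))
  w <- c("2" = 1, "4" = 2)
  f <- fuseMaps(list(rawMap(A, 2), rawMap(B, 4)), w, cal)
  expect_true(all(mapData(f) >= 0 & mapData(f) <= 1))

  # raising one resolution's score at a pixel never lowers the fused value
  A2 <- A; A2[3, 3] <- min(A[3, 3] + 0.2, 1)
  f2 <- fuseMaps(list(rawMap(A2, 2), rawMap(B, 4)), w, cal)
  expect_gte(mapData(f2)[3, 3], mapData(f)[3, 3])
  # zero-score pixels are floored, not annihilating
  A3 <- A; A3[5, 5] <- 0
  f3 <- fuseMaps(list(rawMap(A3, 2), rawMap(B, 4)), w, cal)
  expect_gt(mapData(f3)[5, 5], 0)
})

test_that("fusion validates weights and dimensions", {
  cal <- flatCal(c(2, 4))
  maps <- list(rawMap(matrix(0.5, 4, 4), 2), rawMap(matrix(0.5, 4, 4), 4))
  expect_error(fuseMaps(maps, c("2" = 0, "4" = 0), cal), "at least one")
  bad <- list(rawMap(matrix(0.5, 4, 4), 2), rawMap(matrix(0.5, 8, 8), 4))
  expect_error(fuseMaps(bad, c("2" = 1, "4" = 1), cal), "dimensions")
})

test_that("image score is the exhaustive pixel maximum", {
  set.seed(114)
  m <- matrix(runif(100), 10, 10)
  fused <- new("AnomalyMap", map = m, sizePx = NA_integer_, fused = TRUE)
  mx <- -Inf
  for (i in 1:10) for (j in 1:10) mx <- max(mx, m[i, j])
  expect_equal(imageScore(fused), mx)
  expect_equal(imageScore(new("AnomalyMap", map = matrix(0, 4, 4),
                              sizePx = NA_integer_, fused = TRUE)), 0)
})

test_that("the decision threshold is strict", {
  expect_equal(classifyScore(0.51, 0.5), "abnormal")
  expect_equal(classifyScore(0.5, 0.5), "normal")
  expect_equal(classifyScore(0, 0.5), "normal")
  cal <- flatCal(8)
  expect_equal(classifyScore(0.9, cal), "abnormal")
  expect_error(classifyScore(1.2, cal), "0, 1")
})

test_that("calibration quantiles rescale validation scores robustly", {
  set.seed(115)
  scores <- list("8" = runif(500, 2, 6), "16" = runif(500, 1, 3))
  cal <- fitCalibration(scores)
  expect_equal(unname(cal@qLo[["8"]]),
               unname(quantile(scores[["8"]], 0.01)), tolerance = 1e-12)
  m <- mrpad:::.calibrateMap(matrix(c(0, 10), 1, 2), cal, 8)
  expect_equal(m[1, 1], 1e-6)  # below range floors at epsilon
  expect_equal(m[1, 2], 1)     # above range clips at 1
  # degenerate constant scores do not divide by zero
  calFlat <- fitCalibration(list("8" = rep(2, 50)))
  expect_true(is.finite(mrpad:::.calibrateMap(matrix(2, 1, 1), calFlat, 8)))
})

test_that("heatmap and raw-array exports round-trip", {
  set.seed(116)
  m <- matrix(runif(64), 8, 8)
  am <- new("AnomalyMap", map = m, sizePx = NA_integer_, fused = TRUE)
  f <- tempfile(fileext = ".tif")
  writeAnomalyHeatmap(am, f)
  expect_lt(max(abs(readImageGray(f) - m)), 2 / 65535)
  fb <- tempfile(fileext = ".bin")
  writeMapArray(am, fb)
  con <- file(fb, "rb")
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  vals <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  close(con)
  expect_identical(matrix(vals, dims[1], dims[2]), m)
})
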