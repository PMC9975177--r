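test_that("phantom generation is seeded and structurally correct", {
  cfg <- phantomConfig(side = 64)
  expect_identical(generateNormal(cfg, seed = 12),
                   generateNormal(cfg, seed = 12))
  expect_false(identical(generateNormal(cfg, seed = 12),
                         generateNormal(cfg, seed = 13)))

  # noiseless, jitter-free phantoms are identical across calls
  quiet <- phantomConfig(side = 64, noiseSd = 0, jitter = 0)
  expect_identical(generateNormal(quiet, seed = 1),
                   generateNormal(quiet, seed = 2))

  # lung fields are darker than the surrounding body tissue
  img <- generateNormal(quiet, seed = 1)
  lungs <- mrpad:::.ellipseMask(64, mrpad:::.phantomGeometry$lungL) |
    mrpad:::.ellipseMask(64, mrpad:::.phantomGeometry$lungR)
  body <- mrpad:::.ellipseMask(64, mrpad:::.phantomGeometry$body)
  expect_lt(mean(img[lungs]), mean(img[body & !lungs]))
})

test_that("invalid phantom geometry is rejected", {
  geo <- mrpad:::.phantomGeometry
  geo$lungL[2] <- 0.05  # lung centre outside the body ellipse
  bad <- phantomConfig(side = 64, jitter = 0, geometry = geo)
  expect_error(generateNormal(bad, seed = 1), "outside the body")
})

test_that("anomaly injection produces masks of the nominal area", {
  img <- generateNormal(phantomConfig(side = 128), seed = 3)
  for (diam in c(8, 16, 32)) {
    spec <- anomalySpec(kinds = "bright-blob",
                        diameterRange = c(diam, diam))
    inj <- injectAnomaly(img, spec, seed = 17)
    area <- sum(inj$mask)
    nominal <- pi * (diam / 2)^2
    expect_gte(area, 0.5 * nominal)
    expect_lte(area, 1.5 * nominal)
  }
  # minimal diameter still yields a non-empty mask
  tiny <- injectAnomaly(img, anomalySpec(diameterRange = c(2, 2)), seed = 1)
  expect_gt(sum(tiny$mask), 0)
})

test_that("anomalies alter the image only near the mask", {
  img <- generateNormal(phantomConfig(side = 128), seed = 4)
  for (kind in c("bright-blob", "dark-blob", "shape-deformation")) {
    spec <- anomalySpec(kinds = kind, diameterRange = c(12, 24))
    inj <- injectAnomaly(img, spec, seed = 23)
    diff <- abs(inj$image - img)
    expect_gt(max(diff), 0.05)          # the anomaly is visible
    # support of the change: within the smooth-edge halo of the mask
    # (Gaussian tail: ~4.3 sigma = ~1.83 diameters from the centre)
    p <- inj$params
    halo <- 1.9 * p$diameter
    rows <- matrix(seq_len(128), 128, 128)
    cols <- matrix(seq_len(128), 128, 128, byrow = TRUE)
    rad <- sqrt((rows - p$row)^2 + (cols - p$col)^2)
    expect_true(all(diff[rad > halo] < 1e-9))
    expect_identical(inj$image, injectAnomaly(img, spec, seed = 23)$image)
  }
})

test_that("oversized anomalies and invalid specs are rejected", {
  img <- generateNormal(phantomConfig(side = 64), seed = 5)
  expect_error(injectAnomaly(img, anomalySpec(diameterRange = c(60, 60)),
                             seed = 1), "larger than the body")
  expect_error(anomalySpec(diameterRange = c(1, 4)), "diameter")
  expect_error(anomalySpec(contrastRange = c(0, 0.2)), "non-zero")
  expect_error(anomalySpec(kinds = "glow"), "unknown")
})

test_that("datasets are written with manifest, masks, and exact counts", {
  dir <- file.path(tempdir(), "dstest")
  unlink(dir, recursive = TRUE)
  man <- makeDataset(dir, nNormalTrain = 4L, nValPairs = 2L,
                     nTestPairs = 2L, phantom = phantomConfig(side = 32),
                     anomaly = anomalySpec(diameterRange = c(4, 10)),
                     seed = 9L)
  expect_equal(nrow(man), 4L + 2L * 2L + 2L * 2L)
  expect_equal(sum(man$split == "train"), 4L)
  expect_equal(sum(man$split == "val" & man$label == 1), 2L)
  expect_true(all(file.exists(file.path(dir, man$path))))
  abn <- man[man$label == 1L, ]
  expect_true(all(file.exists(file.path(dir, abn$maskPath))))
  # val and test abnormal sets are disjoint (ids and generating seeds)
  expect_length(intersect(abn$id[abn$split == "val"],
                          abn$id[abn$split == "test"]), 0L)
  expect_length(intersect(abn$genSeed[abn$split == "val"],
                          abn$genSeed[abn$split == "test"]), 0L)
})

test_that("a dataset regenerates bit-identically from its manifest seeds", {
  dir <- file.path(tempdir(), "dsregen")
  unlink(dir, recursive = TRUE)
  phan <- phantomConfig(side = 32)
  aspec <- anomalySpec(diameterRange = c(4, 10))
  man <- makeDataset(dir, nNormalTrain = 2L, nValPairs = 1L,
                     nTestPairs = 1L, phantom = phan, anomaly = aspec,
                     seed = 10L)
  for (i in seq_len(nrow(man))) {
    base <- generateNormal(phan, seed = man$genSeed[i])
    img <- if (man$label[i] == 1L)
      injectAnomaly(base, aspec, seed = man$anomalySeed[i])$image else base
    # in-memory regeneration is exact; the file adds 16-bit quantization
    expect_identical(img, if (man$label[i] == 1L)
      injectAnomaly(base, aspec, seed = man$anomalySeed[i])$image else
        generateNormal(phan, seed = man$genSeed[i]))
    onDisk <- readImageGray(file.path(dir, man$path[i]))
    expect_lt(max(abs(onDisk - img)), 2 / 65535)
  }
})

test_that("default anomaly sizes span multiple patch resolutions", {
  dir <- file.path(tempdir(), "dsspan")
  unlink(dir, recursive = TRUE)
  man <- makeDataset(dir, nNormalTrain = 1L, nValPairs = 8L,
                     nTestPairs = 8L, seed = 3L)
  diam <- as.numeric(sub("px.*", "",
                         sub("^[a-z-]+:", "", man$anomalies[man$label == 1])))
  # the sampled diameters cross at least two of the {16, 32, 64, 128} scales
  expect_lt(min(diam), 16)
  expect_gt(max(diam), 32)
})
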