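Package: mrpad
Title: Multiresolution Patch-Based Unsupervised Anomaly Detection for
    Grayscale Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-class anomaly screening for grayscale radiograph-like
    images. Images are tiled into non-overlapping patches at several
    resolutions; a self-supervised contrastive encoder (NT-Xent loss) is
    trained per patch size on normal images only, and every normal patch
    embedding is stored in a reference database keyed by patch size and
    grid location. A query patch is scored by its distance (Euclidean,
    Manhattan, cosine or Mahalanobis) to the nearest reference embedding
    within a configurable grid neighbourhood; per-resolution anomaly maps
    are calibrated, fused with per-resolution weights, and the maximum
    fused pixel yields the image-level score and normal/abnormal decision.
    Includes a synthetic phantom generator with controlled anomaly
    injection, confusion-matrix and AUROC evaluation, a five-fold
    cross-validation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
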