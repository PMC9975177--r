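---
title: "Multiresolution patch-based anomaly screening: models, parameters and design choices"
author: "mrpad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution patch-based anomaly screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpad)
```

## The screening problem

`mrpad` implements one-class (unsupervised) anomaly screening for
grayscale radiograph-like images: the model sees only *normal* images at
training time, and an image is flagged abnormal when it deviates from the
learned model of normality. The approach rests on three ideas:

1. **Patches at several resolutions.** An image resized to a square side
   $L$ is tiled into non-overlapping patches at each size
   $s_i \in \{s_1, \dots, s_k\}$ with $s_i \mid L$. Small patches see
   local texture; the full-size patch sees global structure. Anomalies of
   unknown scale are visible at *some* resolution.
2. **Self-supervised features + a reference database.** Per patch size, a
   contrastive encoder $f$ is trained on normal patches with the NT-Xent
   objective: two augmented views of the same patch are pulled together
   against the other views in the mini-batch,
   $$\ell_{i,j} = -\log \frac{\exp(\mathrm{sim}(z_i, z_j)/\tau)}
   {\sum_{k \ne i} \exp(\mathrm{sim}(z_i, z_k)/\tau)},$$
   where $z = g(f(x))$ is the projection-head output and $\mathrm{sim}$
   is cosine similarity; $g$ is discarded after training. Every normal
   patch embedding $h = f(x)$ is then stored in the reference database as
   a tuple (patch size, grid x, grid y, image id, $h$).
3. **Locality-restricted nearest-reference scoring and weighted
   fusion.** A query patch at grid cell $(g_x, g_y)$ is scored by its
   minimum distance (Euclidean, Manhattan, cosine dissimilarity, or
   Mahalanobis under the per-size reference covariance) to any reference
   embedding whose grid cell lies within Chebyshev radius $d$ of
   $(g_x, g_y)$. Patch scores are painted onto their pixels, giving one
   anomaly map per resolution; maps are rescaled by a calibration fitted
   on validation normals and fused multiplicatively with per-resolution
   weights. The image score is the maximum fused pixel; the image is
   abnormal iff that score exceeds the threshold (default 0.5, strict).

## Parameters that matter

| parameter | default (desk / paper profile) | meaning |
|---|---|---|
| image side $L$ | 128 px / 1024 px | everything is resized (bilinear, intensities untouched) to this square side |
| patch sizes | {16, 32, 64, 128} / {128, 256, 512, 1024} | each must divide $L$; one encoder + one DB partition per size |
| locality $d$ | 2, 1, 0, 0 (smallest size upward) | Chebyshev grid radius searched around the query cell; $d=0$ is same-cell only, $d \ge \text{grid}-1$ is a whole-grid search |
| similarity | Mahalanobis | the best-performing kind in the source study; all four are available everywhere |
| fusion weights $w_i$ | 0.1, 1.2, 1.2, 1.0 | per-resolution contribution; the smallest scale is strongly down-weighted |
| threshold | 0.5 | image-level decision bound on the fused score in $[0,1]$ |
| temperature $\tau$ | 0.5 | NT-Xent temperature; the source study does not report one, so the common contrastive-learning default is used and exposed |
| crop fraction | 0.5 | augmentation crop retains this fraction of patch *area* (then resized back); interpreted as area because only "(50%)" is stated upstream |
| rotation | ±5° | augmentation rotation range |
| covariance shrinkage $\lambda$ | 0.1 | `Sreg = (1-λ)S + λ·v̄·I`; with more feature dimensions than records the raw sample covariance is singular, so some shrinkage is required for the Mahalanobis distance to exist at all |

The **paper profile** (`defaultPipelineConfig("paper")`) records the
full-scale configuration — ResNet-50 backbone, $h \in \mathbb{R}^{2048}$,
$z \in \mathbb{R}^{128}$, LARS optimizer at learning rate 4.8 with weight
decay $10^{-6}$, batch 256, 100 epochs — verbatim, so the configuration
is preserved and exchangeable. The **desk profile** used by the test
suite replaces the backbone with a small fully-connected network
(16×16 area-pooled input → 128 hidden → 64 features, projection head
64 → 64 → 32) trained with Adam (lr $10^{-3}$, cosine-annealed) for 8
epochs at batch 32. Backbones are pluggable through an internal registry
(init / forward / backward), so a convolutional backbone can be slotted
in without touching the training loop; the fully-connected default was
chosen because at phantom scale it trains in seconds on one CPU with
exact hand-derived gradients (verified against finite differences in the
test suite), and because — see below — encoder capacity is not what
limits phantom-scale performance.

Patches wider than the backbone input are reduced by **exact block
averaging**, not point-sampled decimation: area pooling keeps a small
high-contrast anomaly's contribution proportional to its area, whereas
bilinear decimation at stride 8 can miss it entirely.

## Numerical choices

* **Anomaly score = distance.** The upstream description inverts a
  similarity into an anomaly score without fixing the transform. Any
  strictly decreasing transform preserves both the argmin (the best
  reference) and all rankings, so the package uses the distance itself
  (and $1-\cos$ for cosine), which is numerically stable near perfect
  matches. The printed form of the cosine similarity in the source
  carries a radical over the dot product; that form is dimensionally
  inconsistent and standard cosine similarity is implemented instead.
* **Calibration is never per-image.** A per-image min–max rescale would
  force every image's maximum to 1 and make a fixed threshold vacuous.
  Instead, per-resolution patch scores from *validation normals* provide
  1st/99th-percentile bounds; query maps are affinely rescaled by those
  bounds and clipped to $[\varepsilon, 1]$, $\varepsilon = 10^{-6}$.
  The floor prevents a single perfectly matched resolution from
  annihilating the multiplicative fusion.
* **Fusion weights act as exponents** (geometric mode, the default):
  $$A_{\text{final}} = \exp\!\Big(\tfrac{\sum_i w_i \log A(s_i)}
  {\sum_i w_i}\Big),$$
  the weighted geometric mean. Under literal scalar weighting the
  product $\prod_i w_i$ is a global constant that cancels under any
  scale normalization, which would make measured weight sensitivity
  inexplicable; the geometric reading makes weights ranking-relevant,
  coincides with the plain $k$-th-root normalization at unit weights,
  and is exactly invariant to rescaling all weights by one constant.
  Literal mode is retained for comparison experiments. Maps are fused in
  canonical (increasing patch size) order so results are bit-identical
  under any argument ordering. Tied nearest references keep the first
  record in storage order.
* **Undefined metrics stay undefined.** Confusion-matrix ratios with a
  zero denominator are reported as `NA` with an `"undefined"` attribute,
  never coerced to 0, because silent zeros corrupt fold averages. AUROC
  is the midrank Mann–Whitney statistic (ties count ½), implemented
  directly so the test suite can hold it against a brute-force
  pair-counting oracle.
* **Cross-validation folds the normal pool.** The detector trains on
  normals only, so $k$-fold rotation is applied to the pooled
  training + validation normals (fold = calibration set, rest =
  training set) with a fixed labeled test pool evaluated every fold;
  fold sizes differ by at most one. Encoders are retrained per fold —
  the conservative reading when the upstream procedure is silent.
  Whether the reference covariance should be pooled over grid locations
  or fitted per location is likewise unstated upstream; it is pooled
  here, which also keeps it estimable from few images.
* **Determinism.** Every stochastic step (phantom generation, anomaly
  sampling, weight initialization, batch shuffling, augmentation, fold
  assignment) draws from seeds recorded in configs and manifests;
  identically seeded runs produce byte-identical score tables, which the
  run-manifest checksums make verifiable.

## What the phantom generator emulates — and what it does not

The synthetic generator produces geometric "chest-like" phantoms: a
bright body ellipse on a dark background, two darker lung-field
ellipses, faint periodic rib bands, per-image jitter of all ellipse
parameters (±2% of the side, which at 128 px is ±2.6 px — of the order
of patient positioning variability), and Gaussian pixel noise
(σ = 0.02). Anomalies are smooth Gaussian-profile bright or dark blobs
(FWHM 8–48 px, spanning several patch scales; absolute contrast
0.15–0.40) or local magnification warps, injected inside the body with
a ground-truth mask at the half-maximum contour.

These choices were made once, to be *realistic rather than easy*: the
contrast range overlaps the body/lung intensity difference, so a bright
lung blob locally resembles normal mediastinal tissue, and the
geometric jitter means the most variable normal patches (body edges)
compete with true anomalies for the image maximum. Two consequences
observed on the phantom study are worth stating plainly:

* Single-resolution detectors at the *smallest* patch sizes perform
  near chance on phantoms — edge-jitter variability dominates their
  score maxima. This mirrors the weak smallest-patch column of the
  source study's single-resolution table and motivates the small
  default weight on that scale.
* Longer contrastive training does not substantially raise phantom-scale
  accuracy; the features' main contribution is robustness (e.g.
  translation tolerance from crop augmentation), not capacity. Passing
  the phantom study therefore demonstrates the *mechanics* of the
  pipeline — tiling, embedding, locality search, calibration, fusion,
  thresholding, reproducibility — and the benefit of multiresolution
  fusion on mixed-size anomalies. It demonstrates nothing about
  clinical radiographs: phantoms have no anatomy, no pathology
  appearance, and no acquisition physics.

The default study fixture (60 normal training images, 20+20 validation,
20+20 test at 128², patch sizes {16, 32, 64, 128}) was sized so the full
pipeline — encoder training for four sizes, database construction,
calibration, scoring — runs in a few minutes on one CPU; the evaluation
harness and five-fold cross-validation use the same machinery at
smaller image counts.

## Degenerate inputs and edge behaviour

* Non-square inputs are resized to the square side; after resizing,
  patch sizes that do not divide the side are rejected (no padding).
* A 1×1 patch augments to two identical copies; a one-patch batch has
  no negatives and contributes zero loss by construction.
* Zero-norm projections make cosine similarity undefined and raise an
  error rather than returning an arbitrary value.
* Identical duplicated reference vectors give a zero sample covariance;
  the shrinkage ridge is floored (mean variance ≥ 1e-8) so the
  regularized covariance remains positive definite.
* Empty locality neighbourhoods cannot occur with a complete database
  (every grid cell of every size holds ≥ 1 record, enforced by the
  class validity) and raise an error if a corrupted database is queried.
* Constant validation scores would give a zero calibration range; the
  upper bound is nudged by 1e-12 instead of dividing by zero.

## Known limitations

* The fixed image-level threshold of 0.5 is kept for fidelity, but on
  phantoms the fused maxima of normal images often sit above it: the
  default operating point is sensitivity-heavy and the AUROC is the
  more informative summary. A deployment would re-derive the threshold
  from the validation score distribution.
* Anomaly *localization* is coarse by construction: patch scores are
  painted uniformly over each patch, so the fused map approximates, but
  does not delineate, the anomalous region. No localization metric is
  computed.
* The literal fusion mode exists for comparison but is
  ranking-insensitive to its weights under normalization, as discussed.
* The paper-scale profile (ResNet-50 at 1024²) is recorded but not
  trainable with the built-in backbones; reproducing full-scale
  radiograph results requires GPU-class infrastructure and the original
  data, both outside this package's scope.
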