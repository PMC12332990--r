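---
title: "Methods: a two-stage cascade for adrenal incidentaloma recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage cascade for adrenal incidentaloma recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Adrenal incidentalomas (AIs) are adrenal masses found by chance on CT
performed for unrelated reasons; the working clinical definition used
throughout this package is a lesion whose **shortest diameter exceeds
10 mm**. Recognising AIs automatically on nonenhanced CT decomposes into
two stages, and `adrenalseg` implements both:

1. **Gland segmentation.** A 3-D U-Net with residual units maps a
   normalized CT volume to per-voxel class probabilities (background,
   left gland, right gland). The residual variant wires an identity (or
   1×1×1 projection) shortcut around every two-convolution unit; the
   plain variant — the classical 3-D U-Net — is available behind the same
   interface (`build_model(..., residual = FALSE)`) for controlled
   comparisons.
2. **Per-side classification.** Radiomic features are computed separately
   for the left and right gland regions, reduced by a staged selection
   pipeline, and fed to independent per-side binary classifiers; the two
   sides never share a model, matching how per-side results are reported
   in this literature.

# Preprocessing

Every volume passes the same chain (`preprocess_volume()`):

* **Reorientation** to PLI (grid axes increase toward Posterior, Left,
  Inferior) by pure permutation/flip bookkeeping on the RAS affine; world
  coordinates of voxels are preserved exactly, and the orientation code is
  always derived from the affine, never from free-text headers.
* **Resampling** to a fixed (1.0, 1.0, 3.0) mm spacing — the anisotropy
  of routine abdominal CT. Output dimensions follow
  `round(dims * spacing / target)` with round-half-away-from-zero,
  documented so grids are bit-stable across platforms. Images are
  trilinear; masks nearest-neighbour (no new labels can appear).
* **Intensity windowing** with the abdominal window W = 350, L = 40 HU:
  `out = clamp((hu - (L - W/2)) / W, 0, 1)`, so −135 HU → 0,
  +40 HU → 0.5, +215 HU → 1.

The chain is idempotent: a second pass finds the orientation and spacing
already canonical, and windowing is skipped when the volume already lies
in [0, 1] (a range no HU-valued CT occupies).

# Training

The loss is the unweighted sum of a soft Dice term and a focal term.
Per foreground class `c`, soft Dice uses
`(2 Σ p_c t_c + ε) / (Σ p_c + Σ t_c + ε)` with ε = 1e-5; classes whose
target is empty in a patch are **excluded from the mean** — an
all-background patch contributes no Dice loss and is driven purely by the
focal term `mean_v[ -α (1 - p_t)^γ log p_t ]` (γ = 2, α = 1; the focal
reference leaves them unstated, and these are its canonical values). The
exclusion rule keeps empty-target classes from dominating the gradient of
a structure that occupies about 1% of the volume.

Optimisation is Adam at an initial learning rate of 3e-4 decayed to 0.9×
every 20 epochs — `lr(e) = lr0 · 0.9^⌊e/20⌋` — for up to 200 epochs at
full scale. Patches (natively 96³) are sampled with a foreground bias of
0.5 by default (the sampling ratio is not standardised in this
literature; it is configuration, not a claim), then augmented with
Gaussian noise and one random **in-plane** rotation (default ±15°):
with (1, 1, 3) mm spacing, out-of-plane rotation would destroy the thin
gland. Per-epoch validation loss decides checkpointing; the best-loss
parameters are retained. The checkpoint criterion uses the validation
split because per-epoch inference verification is what the training
protocol describes; the alternative (training loss) is a one-line change.

The network itself is implemented natively: im2col + BLAS GEMM
convolutions (Rcpp/Armadillo), hand-derived backward passes (verified
against central finite differences to ~1e-8 relative error in the test
suite), instance normalisation (robust at batch sizes 1–2, which is what
96³ patches allow on small hardware), strided convolution downsampling
and transposed-convolution upsampling.

Inference tiles the volume with overlapping patches (default overlap
0.25) and averages probabilities in overlaps; volumes smaller than a
patch are padded and cropped back. Raw output is cleaned by
**keep-largest-component per label, then hole filling** — in that order,
because filling first could merge noise specks into the gland. Noise
removal uses 26-connectivity, cavity detection 6-connectivity (the
standard morphology pairing).

# Segmentation metrics

`evaluate_segmentation()` reports DSC, IOU (percent), RVE (percent) and
HD95 (mm) for left gland, right gland and whole image. Conventions,
each of which has a reasonable alternative:

* **Whole image** is the union of foreground labels (side-average is
  available as an option) — the union is what a single whole-organ mask
  would give.
* **HD95** is the 95th percentile (linear interpolation, `quantile`
  type 7) of the *pooled* symmetric directed boundary distances, the
  common convention in segmentation-challenge tooling; boundary voxel =
  foreground voxel with a face-adjacent background neighbour; distances
  in world mm.
* **Both-empty** overlap returns (1, 1) so perfect absence is not
  penalised; empty-mask HD95/RVE are errors reported as missing, never 0.
* Cohort aggregation is the unweighted per-patient mean ± sd.

All four metrics are checked against brute-force oracles (direct set
counts; all-pairs boundary distances) on random masks, and the identity
`IOU = DSC / (2 − DSC)` is asserted to 1e-12.

# Radiomics and selection

Features are computed on the windowed [0, 1] image (the pipeline order
puts features after preprocessing and segmentation), with **fixed bin
width** 0.04 ≈ 14 HU for discretization — fixed-bin rather than
fixed-count so gray levels mean the same thing across images. Six
families: first-order statistics, spacing-aware 3-D shape, GLCM, GLRLM,
GLSZM, NGTDM. Texture matrices aggregate the 13 unique 3-D directions
symmetrically, making all features invariant to translation and to
left–right mirroring (asserted in tests). Regions with fewer than two
voxels get `NA` texture features; first-order and shape are always
computed.

Selection is staged — (1) near-zero-variance filter, (2) correlation
filter (|r| > 0.95 drops the later column), (3) L1-penalised logistic
regression on standardized features, keeping the support of the
densest model on the glmnet path with at most `cap` nonzero
coefficients. The per-side caps default to 24 (left) and 6 (right),
echoing the published key-feature counts as configuration; the selection
algorithm itself is unreported there, so this pipeline is this package's
design, and the planted-signal simulation in the test suite is what a
green test establishes about it.

# Classification and statistics

The panel is random forest, logistic regression, linear SVM, kNN,
gradient boosting and Gaussian naive Bayes, each fitted on the training
split and scored on validation; the highest validation AUC is flagged
selected. The pre-installed R stack has no random-forest/SVM/boosting
package, so those three are compact native implementations (bootstrap +
random-subspace CART for the forest; Pegasos subgradient descent for the
linear SVM; logistic-loss boosting of depth-2 trees); logistic uses
`stats::glm`, kNN uses FNN. Hyperparameters are fixed common defaults
(200 trees, mtry = ⌈√p⌉; 100 boosting rounds at shrinkage 0.1; k = 5),
all seeded.

Scores are oriented so higher = more AI-like, and the decision rule is
`score ≥ threshold`. AUC is the midrank Mann–Whitney estimator (exact
half-credit for ties, asserted against exhaustive pair counting); its 95%
CI uses the DeLong variance with a normal approximation, clipped to
[0, 1] — chosen for consistency with the DeLong comparison test. The
Youden-optimal threshold maximises J = sens + spec − 1 over all candidate
cut-offs ("dynamic partitioning" is read as this exhaustive sweep); ties
break toward the **lowest** threshold, maximising sensitivity, the
screening-appropriate direction. The paired DeLong test uses midrank
placement values; single-positive designs degrade the variance terms to 0
rather than NA, and a zero-variance comparison (e.g. a model against
itself) reports p = 1 with a degenerate flag. Published per-side tables
can be checked arithmetically with `reconstruct_confusion()`, which
rebuilds TP/TN from a dataset's class composition and printed
sensitivity/specificity and re-derives the accuracy.

# The phantom world

`generate_phantom()` builds an abdominal-CT-like stated world: air at
−1000 HU, a body ellipsoid at +40 HU, a bright paraspinal block at
+300 HU, and per side a **bi-lobed union of two ellipsoids** (lobe
semi-axes (3, 5.5, 9) mm, splayed in-plane) at +30 HU — the thin,
small, low-contrast inverted-V silhouette that makes adrenal segmentation
hard, without any anatomical atlas. Optional nodule spheres sit at the
gland centre (+4 mm inferior) with the stated shortest diameter and an HU
contrast drawn from [+20, +60]. Gaussian acquisition noise defaults to
σ = 5 HU, a typical soft-tissue noise level for standard-dose abdominal
CT reconstructions; at the windowed scale the gland–body contrast is then
about twice the noise, so segmentation is learnable but not trivial.
The ground-truth mask labels the noiseless gland + nodule support
(left = 1, right = 2), and the per-side AI label applies the 10 mm rule
to the nodule's shortest diameter.

Cohorts draw AI-positive diameters from 12–24 mm (12–16 mm on small
fields of view so nodules stay inside the body) and give AI-negative
sides either no nodule or a sub-centimetre one (5–8 mm, probability 0.3),
so diameters straddle the cut-off but never sit on it — labels are never
ambiguous. The laterality mix among positives defaults to
left-only/right-only/bilateral = 0.65/0.14/0.21, the approximate
development-cohort bookkeeping for this condition (left AIs dominate).
Splits are stratified on AI presence (either side) at 7:3.

What the phantoms do **not** emulate: anatomy beyond the silhouette,
scanner artefacts, partial-volume effects at organ interfaces,
inter-observer delineation variability, multi-nodule glands (one nodule
per side; how a per-side ground truth should aggregate several reported
nodules is genuinely unspecified in this literature). A green test
therefore establishes that the implementation of each stage is correct
and that the cascade can recover a known signal at desk scale — not that
clinical performance numbers transfer.

# Scaled-down acceptance runs

Two acceptance criteria train networks on one CPU and are scaled
accordingly, with the scale fixed in the test file:

* *Gland recovery*: 20 training / 5 held-out phantoms at 48×48×24 voxels,
  channel plan (8, 16, 32), 24³ patches, 30 epochs × 16 patches,
  learning rate 2e-3 (the full-scale default 3e-4 is tuned for 200-epoch
  runs and converges too slowly in a 30-epoch desk-scale budget; the
  schedule shape is unchanged). The criterion is mean whole-image
  DSC ≥ 0.6 on the held-out phantoms; the run reaches ≈ 0.7.
* *Residual vs plain*: three seeds, shorter runs (10 epochs, channel plan
  (6, 12, 24)); residual must match or beat plain on mean DSC in at
  least 2 of 3 seeds. At this budget the plain variant often barely
  leaves zero DSC while the residual variant already segments — the
  optimisation-ease gap *is* the effect being echoed.
* The *cascade* criterion (60-phantom separable cohort, selected
  validation AUC ≥ 0.9, Youden threshold equal to the brute-force
  optimum) runs the classification arm on the reference masks via the
  pipeline's stage-skipping mechanism; training a segmentation model
  inside this criterion would triple the suite's runtime while testing
  nothing the gland-recovery criterion does not already test.

# Numerical choices and degenerate inputs

* Dimension rounding in `resample()`: half away from zero; minimum 1.
* Patch padding value: 0 (= air after windowing); background for masks.
* `p_t` in the focal loss is floored at 1e-7; instance-norm ε = 1e-5.
* Softmax subtracts the per-voxel maximum before exponentiation.
* Component ties in keep-largest: first component in scan order wins.
* `assign_laterality()` puts a component's side by the sign of its
  centroid's world x relative to the volume's mid-sagittal plane; if both
  components fall on one side, the one nearer the midline is reassigned,
  with a warning.
* Seeds: every stochastic routine takes one; the pipeline fans a single
  global seed out to per-stage seeds through a documented derivation
  (`derive_seeds`), so any stage can be reproduced in isolation.

# Known limitations

* The NIfTI reader is minimal by design: little-endian NIfTI-1, sform (or
  pixdim fallback) affines, axis-aligned orientations only; oblique
  acquisitions are rejected rather than resliced.
* Native convolutions are single-threaded through BLAS; full-scale
  (32–512 channels, 96³ patches, 200 epochs) training is out of reach in
  R — the architecture is faithful, the published training scale is not
  reproduced, and the package does not claim otherwise.
* The phantom world is a stated construction; none of its parameters were
  fitted to data.
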