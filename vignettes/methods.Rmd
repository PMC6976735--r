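---
title: "Synthetic CT from multi-sequence MR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT from multi-sequence MR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mr2sct)
```

This vignette is the package's own account of the science it implements:
the image-translation model, the evaluation machinery around it, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The translation model

The core task is voxel-wise translation from a three-channel MR image
(T1w, T2w, FLAIR, co-registered and intensity-standardized) to a CT-number
image. We use a conditional adversarial pair:

* **Generator** `G`: a U-Net. A full-resolution 3×3 stem convolution feeds
  `depth` encoder levels of 4×4 stride-2 convolutions (batch normalization
  from the second level, LeakyReLU 0.2). The decoder mirrors them with 4×4
  stride-2 transposed convolutions (batch normalization, ReLU) and channel
  concatenation of the matching encoder output; the stem output skips to a
  pair of full-resolution 3×3 output convolutions ending in `tanh`. The
  `tanh` output is mapped linearly onto HU, by default
  $[-1024, 3071] \leftrightarrow [-1, 1]$, which covers air to metal and
  pins the output scale for reproducibility. The network is fully
  convolutional: trained on patches, it predicts full-sized slices.

  *Why the full-resolution stem?* A generator built only from stride-2
  convolutions has its finest skip connection at half resolution. The
  translation target is dominated by a voxel-wise tissue-to-HU mapping with
  sharp interfaces (air/scalp/bone); routing a full-resolution skip around
  the strided core is the classic U-Net top level and makes that mapping
  directly representable, which we found necessary for the strided core to
  converge to sharp interfaces within CPU-scale training budgets.

* **Discriminator** `D`: a PatchGAN — a stack of 4×4 convolutions (two or
  more stride-2 layers, then two stride-1 layers ending in one logit
  channel) whose output is a *grid* of real/fake scores, each unit judging
  one receptive field of the input. The "patch size" of such a
  discriminator is this per-unit receptive field; we derive the layer stack
  from the requested value. Achievable fields are 16, 34, 70, 142, … px, so
  the default request of 32 px yields 34 px (within ±2 px). The
  discriminator sees the MR condition concatenated with the CT candidate
  (4 channels).

* **Losses.** With `BCE` the sigmoid cross-entropy on the score grid, the
  discriminator minimises
  `0.5 * (BCE(D(x, rCT), 1) + BCE(D(x, G(x)), 0))` and the generator
  minimises `BCE(D(x, G(x)), 1) + lambda * MAE(rCT, G(x))`, where
  `MAE = (1/n) * sum |rCT_i - sCT_i|` (the L1 reconstruction term,
  `l1_loss()`), `lambda = 100`.

* **Optimisation.** He-initialised weights, zero biases; Adam with
  `beta1 = 0.5`. Two named profiles exist: `"paper"` (depth 5, width 64,
  128-px patches, 500 epochs, mini-batch 32, lr 2e-4) mirrors the
  full-scale protocol; `"desk"` (depth 3, width 16, 64-px patches,
  50 epochs, mini-batch 8, lr 1e-3 with linear decay to zero over the
  second half) is sized for single-CPU runs and the test suite. The desk
  profile's larger learning rate is deliberate: Adam advances roughly one
  learning-rate unit per update, so a budget of ~10³ updates cannot
  traverse unit-scale output changes at 2e-4; the linear decay schedule is
  itself standard pix2pix practice. Training data are split 9:1 into
  training and validation at the slice level (all patches cut from one
  slice stay on one side), and per-epoch train/validation L1 (in HU) is
  recorded in the returned history.

* **Cross-validation.** `make_cv_folds()` partitions subject IDs into `k`
  seeded folds whose sizes differ by at most one; 15 subjects at `k = 5`
  always give five groups of three.

* **Inference.** `predict_sct()` runs slice-wise with batch-norm running
  statistics; sides not divisible by `2^depth` are reflect-padded and
  cropped back, so output geometry always equals input geometry and HU stay
  within the configured range even for an untrained network.

## Missing-slice compensation

When the MR volume does not cover the full CT extent, the uncovered slices
are filled from the real CT after re-valuing each CT number through a
lookup: over the region where both exist, all (body-masked) voxels with
integer rCT value `v` contribute the *median* of their predicted HU, giving
`lookup[v]`. Missing-slice voxels take `lookup[v]`; values never seen in
the overlap are linearly interpolated between the nearest covered CT
numbers and held constant beyond the covered range (a monotone,
deterministic fallback the data do not dictate — the covered set is usually
dense, so the fallback rarely fires). Background voxels at exactly
−1000 HU pass through unchanged. Medians with even counts average the two
central values.

## Image-quality evaluation

`region_mae()` reports MAE over all body-mask voxels, over the soft-tissue
region and over bone, with region membership decided by the *real* CT:
soft tissue is strict on both ends (−100 HU < rCT < 150 HU) and bone is
rCT ≥ 250 HU. An empty region reports `NA` with a zero count rather than
an error. `binned_difference()` groups masked voxels by rCT into 20-HU bins
anchored at −1000 HU (edges −1000, −980, …) and reports the 25th/50th/75th
percentiles of the signed difference sCT − rCT per bin, plus the same
percentiles of the absolute difference; percentiles interpolate linearly
between order statistics (R type 7). The signed profile is the primary
output; both are emitted because published difference profiles are
sometimes described either way.

## Dosimetric evaluation

* **Density calibration.** EPL needs an HU → relative-electron-density
  (RED) curve. Clinical systems carry their own; we pin a documented,
  configurable default — anchors (−1000, 0), (0, 1), (1000, 1.52),
  (3000, 2.5), linear between, clipped outside — so results are
  reproducible. Anchors (−1000, 0) and (0, 1) are required of any
  user-supplied table.
* **EPL.** One scalar per gantry angle: the ray through the isocenter in
  the axial isocenter plane (IEC 61217 convention: 0° enters anteriorly,
  clockwise viewed from the couch foot) is traversed with exact
  voxel-boundary (Siddon-type) stepping; physical depth is the
  surface-entry→isocenter distance and EPL is the line integral of
  RED(HU). In water EPL equals depth exactly; in air it is zero. The
  180-beam sweep (181°→179° in 2° steps) tabulates per-angle differences
  between two CT volumes with mean ± SD, range, and the fraction of beams
  within ±5 mm. Measuring to the isocenter (not the exit) matches a
  per-angle scalar comparison; an `--to exit` style option exists on
  `compute_epl()`.
* **Gamma.** Global 2D gamma: the map is defined on the evaluated
  distribution's points, each minimising
  `sqrt((dD / (dd% * D_norm))^2 + (r / DTA)^2)` over reference points
  within a search disc of 3×DTA; the searched (reference) grid is first
  upsampled ×3 bilinearly. A point passes at γ ≤ 1 (boundary passes). The
  normalisation dose defaults to the prescription (global gamma) and the
  low-dose cutoff defaults to 0 so closed-form cases are exact; the
  clinical 10 % convention is a flag. These conventions — global
  normalisation, evaluated-grid gamma map, search over the reference —
  are pinned because they make the worked boundary cases exact (a uniform
  +2 % offset at 2 %/2 mm gives γ ≡ 1; a single +6 % pixel at 3 %/3 mm
  gives γ = 2 at that pixel) and are verified against an exhaustive
  full-grid search oracle in the tests.
* **DVH.** `D_x%` is the dose exceeded by exactly x % of the structure
  volume, computed by linear interpolation on the sorted voxel doses
  (type-7 quantile at 1 − x/100); `V_95%` is the percentage of structure
  voxels at or above 95 % of the prescription; `Dmax`/`Dmean` are the
  maximum and mean. These definitions guarantee D2% ≥ D50% ≥ D98% and a
  uniform field at prescription gives V = 100 %.
* **Paired statistics.** Differences are tested for normality
  (Shapiro–Wilk, α = 0.05): normal → paired t-test, otherwise Wilcoxon
  signed-rank with the exact null when n ≤ 25 and no zero or tied
  differences (the exact null is undefined under ties), else the normal
  approximation with continuity correction. All-zero differences short-
  circuit to a degenerate result (statistic 0, p = 1).

## The phantom generator: what it emulates, and what it does not

`generate_head_phantom()` builds axial head volumes from nested ellipsoids
— scalp, skull, brain, a CSF ventricle, an off-centre spherical lesion, an
optional metal clip — because analytic shapes give exact voxel censuses for
test oracles. Default HU: air −1000, scalp 40, bone 900, brain 30, CSF 10,
lesion 35, metal 3000. `simulate_mr()` assigns per-sequence tissue means
with the usual contrast relations (CSF bright on T2w, suppressed on FLAIR;
cortical bone dark; lesion bright on FLAIR), multiplies by a smooth bias
field (the exponential of a seeded low-order polynomial in normalised
coordinates — smooth, strictly positive, cheap) and adds Rician noise as
the magnitude of a complex Gaussian, matching MR magnitude-image physics.
`analytic_dose_grid()` superposes beams with Gaussian lateral profiles and
exponential depth attenuation; given a CT and calibration, the depth
becomes radiological, so doses computed on a real and a synthetic CT
differ exactly where their HU differ — that is what makes the gamma and
DVH comparisons in the pipeline informative.

What the phantom deliberately does *not* emulate: partial-volume mixing at
tissue interfaces (labels are crisp, so with noise off the CT is an exact
voxel-wise function of the MR triple), anatomical variability beyond the
ellipsoid parameters, MR pulse-sequence physics, scanner-specific
artifacts, and scatter/beam-hardening in CT. Passing tests on phantoms
therefore demonstrates that the pipeline's machinery is correct and that
the network can recover a deterministic MR→HU mapping — not that it
reaches clinical accuracy on patient data, which additionally suffers
registration error, partial volume and population variability.

## Numerical choices and degenerate inputs

* Arrays are stored `(row, column, slice)` with 1-based indices; the voxel
  `(i, j, k)` centre sits at `origin + (c(i, j, k) - 1) * spacing` mm.
  This single convention is shared by patch extraction, ray tracing and
  dose computation.
* Bias correction fits a 3rd-order polynomial to the masked log-image by
  iterated weighted least squares (two passes, Tukey biweight on
  MAD-scaled residuals) and rescales the corrected image so the masked
  mean is preserved exactly; the estimated field is attached as an
  attribute. An external correction algorithm can be substituted behind
  the same contract.
* The intensity standardizer uses landmarks p1, deciles, p99 (robust
  percentiles instead of min/max). Constant or overly discrete masked
  histograms (tied landmarks) raise a degenerate-histogram error rather
  than producing a non-monotone map — noise-free piecewise-constant
  phantoms fall in this category, and are instead rescaled linearly onto
  the 0–4095 range where needed.
* Otsu runs on a 256-bin histogram of the blurred image (default σ of one
  voxel, closing radius 2 voxels); masks keep the largest 26-connected
  component after hole-filling with 6-connected background labelling.
* Patch positions are sampled uniformly over all admissible top-left
  corners (body fraction ≥ 0.5 by default) with an integer-seeded RNG, so
  sampling is reproducible across platforms.
* Augmentation composes flip → rotation → zoom → shift about the patch
  centre with bilinear resampling; exposed pixels take the background
  values (MR 0, CT −1000). Degenerate parameters give the exact identity.
* Ties, medians and quantiles are pinned everywhere to R's conventions
  (median = mean of central pair; quantile type 7).
* Gamma boundary comparisons use an absolute tolerance of 1e−9 on γ so
  "γ = 1 passes" is stable under floating-point rounding.

## Open design points, resolved

* Whether the intensity standard scale is fitted per sequence or globally:
  per sequence, per training fold — sequences have unrelated intensity
  distributions, and fitting on training subjects only avoids leakage.
* Whether body masks derive from CT or MR: a parameter; CT drives CT
  masks, T1w drives MR masks by default.
* Whether the discriminator's "32 × 32 patch size" means receptive field
  or output granularity: receptive field (the standard PatchGAN reading).
* Gamma normalisation (global), low-dose threshold (off by default) and
  evaluated plane (the isocenter slice): all exposed as arguments.
* The missing-slice lookup's out-of-coverage behaviour is this package's
  own rule (interpolate, then clamp), chosen for monotonicity and
  determinism.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
phantoms of 80×80×32 voxels at 3 mm spacing, 64-px patches, 180 patches
over three training subjects, 25 epochs of the desk profile (~10³
generator updates), one held-out subject, a 180-angle EPL sweep, gamma on
80×80 isocenter slices at three criteria, and 50 random ray-trace cases
against a dense-integration oracle. These sizes are the package's chosen
trade-off between statistical meaningfulness and a comfortable
single-core run; every one of them is a function argument, and the paper
profile scales the same code to 512×512 slices, depth-5/width-64 networks
and 500 epochs.

## Known limitations

* The adversarial training loop is plain R + BLAS; it is adequate for the
  desk profile but not for full-scale 500-epoch training, which the
  `"paper"` profile parameterises without promising GPU-class speed.
* Registration is out of scope: inputs are assumed co-registered.
* The dose model is analytic (Gaussian profiles, exponential attenuation
  on radiological depth); it is a stand-in adequate for exercising gamma
  and DVH machinery, not a clinical dose engine.
* DICOM/DICOM-RT are out of scope; NIfTI is the single interchange format.
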