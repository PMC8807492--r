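---
title: "stromatex: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stromatex: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Ex vivo MR microscopy (MRM) of high-grade serous ovarian cancer implants
resolves tissue architecture at tens of micrometres: tumor cell lobules are
bright and fairly uniform, the fibrous stroma separating them is darker and
spatially heterogeneous, and several structures (glandular lumens, psammoma
bodies, hyaline stroma) produce no signal. The quantitative question is
whether local image texture carries the tumor–stroma composition: does a
pixel's gray-level co-occurrence structure predict the stromal proportion
measured on a co-registered histology segmentation, and can a classifier
turn texture maps into stroma-rich/stroma-poor segmentations?

`stromatex` implements that analysis as a reusable, fully tested pipeline,
with a synthetic phantom generator standing in for specimen data.

## Pipeline model and assumptions

The chain is fixed: denoise → bias-field correction → isotropic resampling
→ µ ± 3σ outlier filtering → gray-level quantization → per-pixel GLCM
texture maps; in parallel, the histology label raster is brought to the MR
grid by majority vote and converted to a stromal-proportion map. Both map
stacks are then joined pixel-wise for correlation and classification.
Assumptions worth making explicit:

* the image and the label raster are co-registered (the generator
  guarantees it; `inject_misalignment()` exists to stress-test violations);
* intensity is an arbitrary scale — nothing downstream uses physical units,
  and the bias correction preserves the masked mean on purpose;
* analysis is per-slice 2D by default; 3D stacks are handled slice-wise
  except in the explicit 13-direction 3D texture mode.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| gray levels G | 64 | levels | standard radiomics dynamic-range reduction; entropy then lives in [0, 12] bits |
| GLCM window radius | 3 | px | 7×7 neighborhood gives per-pixel maps at the granularity the analysis needs |
| GLCM offset distance | 1 | px | distance-1 co-occurrence inside the window; the "3 neighboring pixels" phrasing admits an offset-distance-3 reading, so the distance is exposed as a parameter |
| directions | 4 in-plane | — | 0°/45°/90°/135°, symmetric accumulation, features averaged over directions (orientation-invariant maps); a 13-direction 3D mode exists |
| entropy log base | 2 | bits | makes the constant-image limit 0 and the uniform-GLCM limit 2·log₂G exactly |
| denoise | Gaussian, σ = 0.5 | px | mild; the original filter is unspecified, so the method and strength are options (non-local means included) |
| outlier filtering | µ ± 3σ | — | exclusion from the mask, not clipping — excluded pixels stay invalid through texture and classification |
| resampling target | min(spacing) | µm | isotropic with the minimum interpolation factor (upsampling only) |
| stromal disk radius | 3 | px | 29-pixel Euclidean disk on the MR grid; fat/void/background excluded from the stroma:(stroma+tumor) ratio |
| proportion bins | 10 × 10 | % | bin means vs bin centers feed the Pearson correlation (10 points, t-test with n−2 df) |
| class threshold | 50 | % | >50 rich, <50 poor; pixels exactly at 50 are excluded since neither class is defined there |
| sampling | 30%, then 50/50 | — | training half balanced by random undersampling; test half untouched |
| SVM | RBF, C = 1, γ = 1/d | — | on standardized features; stratified 20-fold CV; kernel and C are options |

Quantization bounds are **global** (masked min/max after outlier filtering),
not per window: per-window rescaling would erase the inter-regional signal
contrast that the SI correlations rely on.

## What the phantom emulates — and what it does not

`generate_phantom()` draws random rotated ellipses (tumor lobules) inside an
elliptical tissue envelope until a target stromal fraction (default 50%) is
reached; the remaining envelope is stroma, with an optional peripheral fat
rim and small zero-signal voids. Tissue intensity is the configured mean
modulated by band-limited Gaussian fields — stroma at relative amplitude
0.35, tumor at 0.05, so stroma is the texturally heterogeneous compartment —
then a smooth multiplicative bias field (broad blob or linear ramp, default
fractional amplitude 0.2) and Rician noise (σ = 2 intensity units on means
of 60–100) are applied to the image only. Defaults were chosen once, for
clear class separability rather than realism: no public quantitative texture
statistics of real stroma vs tumor exist to calibrate against.

It does **not** simulate MR physics (relaxation contrast, sequence
parameters), contrast agent uptake, scanner drift, histology staining or
sectioning artifacts, or registration error (unless injected). A green test
therefore establishes that the *computational chain* is correct and that
the *direction* of every effect matches the generative premise — not that
real-tissue effect sizes are reproduced. Phantom accuracies (~90%) are well
above the 60–72% regime reported on real specimens, as expected for a
separable stated world.

## Numerical choices and degenerate inputs

* `0·log 0 ≡ 0` throughout; GLCM correlation is defined as 0 (flagged) when
  either marginal is degenerate.
* A constant masked image quantizes to level 0 with a warning; σ = 0 makes
  outlier filtering a no-op; an empty-vs-empty Dice is 1 by logged
  convention.
* Diagonal GLCM pairs count twice under symmetric accumulation (the ordered
  pair and its reverse coincide) — the brute-force oracle test pins this.
* Majority-vote label resampling breaks ties by the fixed priority
  stroma > tumor > fat > void > background. At exact integer grid ratios
  this resolves boundary tissue/background ties toward tissue and inflates
  tissue area by roughly the boundary length (~1% on a 2:1 downsample), so
  area preservation is tested at 2% relative tolerance rather than one
  pixel.
* Nearest-neighbor label warping makes sub-pixel displacements invisible:
  misalignment amplitude 1 px can reproduce the input exactly (Dice 1).
* Bias-field estimation is a robust (Tukey-reweighted) order-2 polynomial
  fit of log-intensity — a homomorphic surface fit. No retrospective
  estimator can separate anatomy-scale tissue contrast from a low-order
  field; on contrasted phantoms the recovered field absorbs some lobule
  structure (correlation with truth ~0.4–0.8), so the recovery test uses a
  contrast-free textured phantom, where recovery exceeds 0.99. The
  estimator's hard contract — smooth, strictly positive, mean 1 over the
  mask, masked mean preserved within 0.5% — holds regardless.
* Stroma entropy saturates near the global dynamic range: above relative
  amplitude ~0.35 more heterogeneity widens the quantization range instead
  of adding entropy, so the monotone-heterogeneity property is tested at
  amplitudes 0.1–0.35.

## Open design points and how they were resolved

* **2D vs 3D**: the texture description is per-slice 2D with 4 directions
  (the only reading consistent with per-pixel 2D maps); the 13-direction 3D
  mode is provided for completeness.
* **"3 neighboring pixels of each direction"**: read as window radius 3
  with distance-1 offsets, not offset distance 3; the distance is a
  parameter for the other reading.
* **Pooling**: pixels from all specimens are pooled before binning and
  classification; per-specimen reports remain available via `tumor_id`.
* **13 vs 14 inputs**: the default feature set is the 13 texture features;
  `with_si = TRUE` adds signal intensity — both variants of the published
  description are supported rather than silently merged.
* **Balancing order**: undersampling happens after the train/test split, so
  the test set keeps its natural class mix; cross-validation folds are
  stratified.
* **Permutation control**: chance level is asserted on the balanced
  training set (CV accuracy), where it is exactly 50%; on an unbalanced
  test set a degenerate permuted model drifts toward the majority share.

## Known limitations

Bias-field/anatomy non-identifiability (above); no rigid or elastic
registration (pairs are assumed registered); no stain handling or automated
histology segmentation; no radiomics families beyond GLCM — the design
deliberately stays with basic texture features; phantom realism is
qualitative, not calibrated. Every empirical number quoted here is computed
by the test suite or the README example — the vignette states none of its
own.
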