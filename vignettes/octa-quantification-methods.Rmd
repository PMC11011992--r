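---
title: "Quantifying retinal microvasculature on OCTA en-face images: methods and design"
author: "octaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microvasculature on OCTA en-face images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face
projections of retinal blood flow over depth slabs — the superficial (SCP)
and deep (DCP) capillary plexuses. Clinical studies of macular disease
summarize these images with three scalar metrics:

* **VAD** (vessel area density): the fraction of pixels with detectable
  perfusion in the binarized angiogram;
* **VSD** (vessel skeleton density): the fraction of pixels on the
  one-pixel skeleton, proportional to total vessel *length* and therefore
  insensitive to caliber;
* **VDI** (vessel diameter index): the ratio of vessel area to skeleton
  length, i.e. the average vessel caliber.

`octaquant` implements the full chain from raw grayscale image to these
metrics, a synthetic phantom generator that makes the chain testable
without patient data, and the cohort-level statistical endpoints used to
relate the metrics to visual outcome after retinal-detachment surgery.

## Image quantification pipeline

The input is a 2-D grayscale en-face image with known physical extent,
nominally 3 × 3 mm over a 586 × 585 raster, so one pixel is
5.13 × 5.13 µm. The pixel pitch is always recomputed as
`extent_mm × 1000 / n_px`; images of other sizes are processed at native
resolution without resampling.

1. **8-bit conversion** (`to_eight_bit`): linear min–max rescale to
   integers 0–255. A constant image maps to all-zero. This makes the
   pipeline invariant to affine intensity rescaling of the input.
2. **Speckle reduction**: a single 3 × 3 median filter applied to the
   8-bit image, feeding all three binarization branches. OCTA speckle is
   multiplicative and heavy-tailed; a local-mean gate on raw speckle
   drops roughly half of the vessel-interior pixels (a ~0.05 VAD
   undercount in phantom validation), while Gaussian smoothing restores
   VAD but widens 2–3 px capillaries enough to corrupt VDI. The
   edge-preserving median does neither; the Gaussian variant and a
   no-filter option remain selectable in `quant_config()`.
3. **Three-way binarization**: (a) a *global threshold* chosen by Otsu's
   between-class-variance criterion, which captures large high-signal
   vessels; (b) a *multiscale Hessian vesselness* filter (Frangi-type,
   β = 0.5, scale-normalized second derivatives, response thresholded at
   its own 0.90 quantile), which captures fine capillaries as bright
   curvilinear ridges; (c) a *local adaptive mean threshold* (window
   15 px, offset 0, reflective borders), which tracks slowly varying
   background.
4. **Combination** (`combine_binarizations`): the default `adaptive_gate`
   rule keeps `(global ∨ hessian) ∧ adaptive` — the two detectors propose,
   the adaptive map vetoes diffuse background. `union` and `majority` are
   available for sensitivity analysis. Components smaller than 10 px
   (8-connectivity) are then removed as speckle debris.
5. **Skeletonization** (`skeletonize`): Guo–Hall parallel thinning, which
   removes outer-perimeter pixels in two alternating raster-synchronous
   subiterations until every segment is one pixel wide. The deletion
   conditions preserve 8-connectivity of foreground, so component counts
   and loops survive; being a parallel scheme, the result is
   deterministic with no tie-break ordering to specify.
6. **Metrics**: VAD and VSD are plain pixel fractions; VDI is
   `n_binary / n_skeleton` in pixels, also reported in µm via the pixel
   pitch. VDI is flagged undefined when the skeleton is empty rather than
   silently returning a number.

### Choices where the method description is open

The published description of this family of pipelines names the three
binarizations but not their numeric settings nor the combination rule.
The package's position:

* All numeric settings live in `quant_config()` and are recorded in every
  result (`params_used`, `config_hash`), so no run is unauditable.
  Defaults (Otsu; scales {1, 2, 3} px; 0.90 response quantile; 15 px
  window, offset 0; 10 px minimum component) were fixed once from standard
  practice for 3 × 3 mm capillary imaging at ~5 µm pitch.
* `adaptive_gate` is the default combination because a plain union badly
  over-segments speckled background (the Hessian branch responds to noise
  ridges), while gating by the adaptive map keeps only pixels that are
  also locally bright. The two alternative rules remain one flag away.
* Whether the three branches should see differently pre-filtered copies
  of the image is left unspecified upstream; here all three operate on
  the same median-denoised 8-bit image (the Hessian branch additionally
  applies its own scale-space Gaussian as part of the derivative
  computation). The shared pre-filter was adopted after phantom
  validation exposed the speckle undercount described above.
* The full frame is quantified; no foveal-avascular-zone exclusion is
  applied.
* **VSD units**: reported as a unitless skeleton-pixel fraction; the
  published follow-up tables print VSD of roughly 0.15–0.17, which is
  consistent with this convention.
* **VDI units**: reported both as a pixel ratio (`vdi_px`) and in µm.
  Published tables print VDI near 18.6 without a stated unit; that
  magnitude is not consistent with (VAD/VSD) × 5.13 µm ≈ 13 µm, so no
  attempt is made to reverse-engineer the vendor scaling, and no printed
  VDI magnitude is used as a correctness target here.
* An optional, deliberately naive projection-artifact hook (subtracting a
  scaled SCP image from the DCP image) was considered and dropped: the
  published pipelines use a dedicated external algorithm for this, and a
  stand-in would change DCP metrics in ways the tests could not anchor.

## Synthetic phantoms

`generate_network()` builds a random branching network: persistent random
walks from edge seed points, spawning branches with probability 0.08 per
step, capped at 10 walks per trunk, each segment drawn with a caliber
sampled uniformly from 12–28 µm. The truth is rasterized twice — at full
caliber (pixels within caliber/2 of a centerline) and at one pixel
(the drawn centerline) — and the truth metrics are computed from those
rasters. `render()` then applies the image formation model
`background + contrast · truth`, Gaussian PSF blur (σ = 1 px), and
unit-mean multiplicative gamma speckle (CV 0.35), the standard OCT noise
proxy. Both stages are pure functions of their seeds.

What the phantom *is not*: a physiological angiogenesis model. It has no
capillary-free zone, no plexus-specific architecture, no flow-dependent
signal, and no projection artifacts. Passing recovery tests on phantoms
therefore demonstrates that the pipeline measures what it claims on
curvilinear structures of known geometry under speckle — not that it
reproduces any clinical value on patient scans.

Two known biases are worth stating. Thinning merges junction and overlap
regions that the drawn centerlines count separately, so on dense networks
the measured skeleton is ~15–20% shorter than the drawn one and the
measured VDI correspondingly higher than the truth-raster VDI; caliber
*ratios* cancel this bias, which is why the caliber-doubling check is
ratio-based and caliber recovery is validated on sparse fixed-caliber
networks. Second, PSF blur plus Otsu slightly widens vessels at high
contrast; at the default settings the net VAD error stays within ±0.05.

## Cohort simulator

`simulate_cohort()` draws a paired-eye, two-plexus, four-visit cohort.
Defaults reproduce the published 23-eye summary statistics: e.g.
preoperative SCP VDI 18.6 ± 1.1 (study eye) vs 19.2 ± 0.7 (fellow), DCP
VAD 0.38 ± 0.03 vs 0.40 ± 0.02, with essentially flat follow-up drifts.
Each metric's total variance splits evenly into a stable between-eye
level and visit-level measurement noise — a package choice; the published
tables report only totals, but the even split keeps the configured
follow-up drifts within visit noise, which reproduces the published
pattern of nonsignificant longitudinal tests at n = 23. The binary visual outcome (BCVA gain
≥ 0.1 LogMAR at month 6, base rate 8/23) follows a logistic link on the
standardized preoperative SCP VDI and VSD and their 6-month changes, with
per-SD log-odds defaults of 1.0/0.8/0.8/0.6 — on the order of the
published per-unit odds ratios, but not asserted to equal them. Month-6
BCVA is constructed from the drawn responder flag, so the flag and the
gain are consistent by construction.

## Statistical endpoints

* `hodges_lehmann()`: the location shift estimate is the median of all
  pairwise differences; p-value and CI come from the Wilcoxon rank-sum
  machinery, exact below a combined n of 20 without ties, normal
  approximation with tie/continuity correction otherwise.
* `longitudinal_test()`: Shapiro–Wilk screen per timepoint at α = 0.05;
  any rejection (or a degenerate constant column) routes to the Friedman
  rank test, otherwise repeated-measures ANOVA with an eye stratum.
  Missing cells are an error — nothing is imputed.
* `fit_univariate_logistic()` / `backward_select()`: ML logistic fits;
  univariate screening at p < 0.1, backward elimination of the largest
  Wald p until all remaining terms are below 0.05 or one term remains;
  p-ties break lexicographically so the path is order-invariant. Both the
  entry model (every entrant adjusted for the others) and the final model
  are reported, because published tables often print per-variable
  adjusted ORs whose exact co-adjustment set is ambiguous. Separation is
  flagged, never silently reported.
* `roc_youden()`: empirical ROC over midpoints between observed scores;
  AUC via midranks (identical to U/(n₁n₀)); the optimal cut maximizes
  Youden's J (equivalent to the nearest-top-left rule under equal axis
  scaling, which is also available); BCa bootstrap CIs for AUC and J with
  10,000 iterations and seed 9780 by default, resampling stratified by
  class so every resample contains both classes; the AUC-vs-0.5 p-value
  is the two-sided bootstrap tail probability (floored at 1/n_boot), with
  a DeLong alternative. Orientation is data-driven (direction chosen so
  AUC ≥ 0.5) and logged per variable.

## Numerical and validation choices

* Convolutions use reflective padding; the adaptive comparison `x ≥ mean`
  carries a 10⁻⁷ slack so integer ties resolve deterministically under
  floating-point summation.
* Otsu maximizes between-class variance over all 255 splits and takes the
  smallest maximizer on plateaus.
* 8-connected component labeling is built on an explicit pixel-adjacency
  graph; thinning invariants (containment, one-pixel width, component
  preservation) are asserted in the test suite on bars, grids, blobs and
  random dilated masks.
* Every estimator with a closed-form or brute-force counterpart is tested
  against one: exhaustive Otsu sweep, sliding-window mean, finite
  -difference Hessian eigenvalues, pairwise-median Hodges–Lehmann, rank
  -formula Friedman, 2×2 odds ratio, U-statistic AUC, and an independent
  ROC implementation.
* Validation problem sizes are package choices: recovery loops run 20
  phantoms at the native 585 px geometry (caliber checks on sparse
  fixed-caliber networks);
  calibration uses 1000 null replicates at the cohort's n = 23; parameter
  recovery uses n = 2000. The type-I bands asserted are [3%, 7%] at
  α = 0.05.

## Limitations

The pipeline is validated against synthetic truth, not against a vendor
implementation or reader gradings; absolute VDI scaling conventions vary
between vendors and are not reconciled here. The cohort simulator encodes
the published summary statistics, not patient-level correlation structure
(fellow-eye correlation is zero by default, consistent with the published
report of no significant cross-eye correlations). Backward selection on
23 eyes with many candidates is fragile in the ways the literature
documents; the package flags low events-per-variable rather than blocking
the fit, since reproducing that published design is part of its purpose.
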