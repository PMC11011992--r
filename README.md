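# octaquant

Quantification of retinal microvasculature on OCTA en-face angiograms,
with the cohort-level statistics used to relate microvascular metrics to
visual outcome after macula-on retinal-detachment surgery.

## What it computes

Optical coherence tomography angiography (OCTA) images the retinal
capillary plexuses as 2-D en-face projections (nominally 3 × 3 mm over a
~585 px raster, so 1 pixel ≈ 5.13 µm). `octaquant` turns such an image
into a binary vessel map by a **three-way combined binarization** — a
global Otsu threshold, a multiscale Hessian (Frangi-type) vesselness
filter, and a local adaptive mean threshold, merged as
`(global ∨ hessian) ∧ adaptive` — then thins it to a one-pixel skeleton
by topology-preserving Guo–Hall thinning, and reports:

* **VAD** = n_binary / n_total — vessel area density (perfused fraction);
* **VSD** = n_skeleton / n_total — vessel skeleton density (length proxy);
* **VDI** = n_binary / n_skeleton — vessel diameter index (mean caliber,
  in px and µm).

Because clinical OCTA scans are rarely shared, the package ships a
phantom generator (`generate_network` / `render`) producing capillary
networks with exact rasterized ground truth under Gaussian PSF blur and
multiplicative gamma speckle, and a cohort simulator
(`simulate_cohort`) reproducing the summary statistics of a 23-eye,
four-visit, paired-fellow-eye cohort. The statistical layer
(`run_endpoint_suite`) covers Hodges–Lehmann/Mann–Whitney group
comparisons, Friedman or repeated-measures longitudinal tests, backward
-selected logistic predictors of a BCVA gain ≥ 0.1 LogMAR, and ROC/Youden
optimal cut-points with BCa bootstrap confidence intervals (default
10,000 iterations, seed 9780).

## Worked example

```r
library(octaquant)

tr  <- generate_network(seed = 3)        # 585 px, 3 mm phantom with truth
img <- render(tr, seed = 3)              # PSF blur + speckle
m   <- quantify(img)
m
#> <vessel_metrics> VAD 0.2698  VSD 0.0632  VDI 4.267 px (21.88 um)
tr$truth_metrics$vad
#> [1] 0.2858792
```

The phantom's true VAD here is 0.286 and the pipeline recovers 0.270
under default speckle (CV 0.35) — well within the ±0.05 budget the
validation suite enforces. On noise-free renders recovery is exact to
better than 0.01.

For the cohort side:

```r
coh <- simulate_cohort(cohort_sim_params(seed = 7))
rep <- run_endpoint_suite(coh, n_boot = 10000, seed = 9780)
rep$group_comparisons[1, c("plexus", "metric", "hl_estimate", "p")]
#>   plexus metric hl_estimate         p
#> 1    SCP    vdi   0.3891178 0.3448249
```

i.e. in this particular 23-eye draw the fellow eyes' preoperative SCP
vessel diameter index sits about 0.39 above the study eyes'
(Hodges–Lehmann shift) but does not reach significance — at this sample
size the true generating gap of 0.6 is detected only in a fraction of
replicates, which is exactly the power situation the simulator is built
to explore.

The `analysis/` directory holds the narrative drivers:
`01_simulate_angiograms.R` → `02_quantify_phantoms.R` →
`03_simulate_cohort.R` → `04_cohort_endpoints.R`, writing tables under
`results/`.

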