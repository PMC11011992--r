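Package: octaquant
Title: Microvascular Quantification of OCTA En Face Angiograms and Cohort
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies retinal microvasculature on 2-D en-face optical
    coherence tomography angiography (OCTA) images: a three-way combined
    binarization (global Otsu threshold, multiscale Hessian vesselness,
    local adaptive threshold), topology-preserving one-pixel
    skeletonization, and the vessel area density (VAD), vessel skeleton
    density (VSD) and vessel diameter index (VDI) metrics. Includes a
    synthetic angiogram phantom generator with exact ground truth, a
    longitudinal cohort simulator, and the cohort-level statistical
    endpoints used in clinical OCTA studies: Hodges-Lehmann/Mann-Whitney
    group comparisons, Friedman or repeated-measures longitudinal tests,
    backward-selected logistic predictors of visual gain, and ROC/Youden
    optimal cut-points with BCa bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
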