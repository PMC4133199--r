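Package: strokeatlas
Title: Population-Based Stroke Atlases for Lesion-Driven Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds voxel-wise, weighted population maps (population-based
    stroke maps, PSMs) of clinical parameters such as the modified Rankin
    Scale and the Barthel Index from spatially normalized binary infarct
    masks, and predicts a new patient's outcome from the map distribution
    inside that patient's normalized lesion. Includes a landmark-driven
    piecewise-affine Talairach normalization, eight pluggable contour
    weighting variants, case selection by infarct volume and NIHSS ranges,
    exact atlas merging for the pre-computable variants, a leave-one-out
    evaluation grid with error summaries and dichotomized ROC analysis, a
    synthetic cohort generator with a spatial ground-truth outcome field,
    minimal NIfTI-1 input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
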