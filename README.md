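# strokeatlas

Population-based stroke atlases (PSA) for lesion-driven outcome
prediction in ischemic stroke.

## The problem

Most stroke outcome prediction models are of a
"same-patient-different-parameters" kind: they regress a patient's
outcome on other variables measured for that same patient, usually
ignoring *where* the infarct sits. The population-based stroke atlas
takes the opposite, "same-parameter-different-patients" view: it
aggregates one clinical parameter (for example the modified Rankin Scale
at day 90) across many previously treated patients, each represented by
the binary mask of their delineated infarct in a common stereotactic
(Talairach) space, and turns it into a 3D map of that parameter's
spatial distribution. A new patient's outcome is then predicted from the
map values inside that patient's own normalized infarct region.

For a parameter `p` and weight variant `k`, the population-based stroke
map (PSM) is the voxel-wise weighted mean over the `N` contributing
contour files `C_i`:

    PSM_{p,k}(v) = sum_i w_k(i) * p_i * 1[v in C_i] / sum_i w_k(i) * 1[v in C_i]

Eight weighting variants are provided: `w1 = 1` (plain averaging,
pre-computable and mergeable across centers), `w2 = 1/Vpsa` (favours
small, well-localized contours), and six predicted-case-aware variants
built from the contour volumes `Vpsa`, `Vp`, their overlap `Vo` and the
centroid distance `d` (e.g. `w3 = Vo/Vpsa + Vo/Vp`, which equals 2 when a
contributing contour is identical to the predicted one). The contributing
cohort can be restricted by closed ranges of infarct volume, NIHSS at
admission and NIHSS at day 7 (case selection). A prediction is the
unweighted mean of the covered map values inside the normalized contour,
with an optional infarct-frequency threshold to mask low-evidence voxels;
it is deliberately not rounded to the ordinal scale.

The package implements the full pipeline: landmark-driven
piecewise-affine (12-block proportional grid) spatial normalization of
native-space masks, weighted map construction and exact accumulator
merging, per-case prediction, a leave-one-out evaluation grid (8 weights
x 4 x 4 x 4 selection ranges = 512 cells per case and parameter) with
error summaries, error-reduction ratios, best-selection-variable
analysis, pairwise variant t-tests and dichotomized ROC analysis
(mRS 0-2 | 3-6, mRS 0-1 | 2-6, BI 0-45 | 46-100), plus a synthetic
cohort generator with a spatial ground-truth outcome field so every stage
is testable without patient data. Minimal NIfTI-1 I/O and a CLI are
included.

## Worked example

```r
library(strokeatlas)
space <- reduced_space() # 64 x 64 x 16 test grid; atlas_space() is full-res
cohort <- make_cohort(n = 32, seed = 7, space = space, sigma = 0.5)

# leave case032 out, build its mRS90 atlas from the remaining cases
target <- "case032"
train <- cohort$cases[cohort$cases$case_id != target, ]
psm <- build_psm(train, cohort$contours_atlas, "mRS90",
                 weight_id = 1, space = space)
print(psm)
#> <stroke_map> mrs90, weight w1, 29 contributing case(s), 9802 covered voxel(s)

# normalize the held-out case's native mask via its landmarks and predict
tr <- fit_transform(cohort$landmarks[[target]], space)
contour <- normalize_contour(cohort$contours_native[[target]], tr, space)
res <- predict_case(psm, contour,
                    actuals = cohort$cases[cohort$cases$case_id == target, ])
print(res$mrs90)
#> <prediction> mrs90: 3.053 (sd 0.083, range [3.000, 3.250], 157 voxels,
#>   coverage 100.0%); actual 3, |error| 0.053
```

29 of the 31 training cases carry a non-missing mRS90 value and
contribute. Every voxel of the held-out lesion is covered by at least one
training lesion (coverage 100%); the map values there range from 3.0 to
3.25, and their mean — the point prediction, kept continuous rather than
rounded — is 3.05 against an actual grade of 3, an absolute error of
0.05.

The same pipeline is available from the command line:

```sh
Rscript -e 'strokeatlas::psa_cli()' simulate --n 32 --seed 7 --out cohort/
Rscript -e 'strokeatlas::psa_cli()' build --cohort cohort/ --param mRS90 --out psm/
Rscript -e 'strokeatlas::psa_cli()' predict --atlas psm/ \
    --mask cohort/masks/case032_mask.nii \
    --landmarks cohort/landmarks/case032.json \
    --clinical cohort/clinical.csv --case case032
Rscript -e 'strokeatlas::psa_cli()' evaluate --cohort cohort/ --out results/
```

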