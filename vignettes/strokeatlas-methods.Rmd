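---
title: "Population-based stroke atlases: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based stroke atlases: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strokeatlas)
```

## The model

A population-based stroke atlas (PSA) estimates the spatial distribution
of a clinical parameter from a cohort of stroke patients whose infarcts
have been delineated as binary masks ("contour files") and projected
into a common stereotactic grid. For one parameter `p` (say mRS at day
90) and one weighting variant `k`, the population-based stroke map is
the per-voxel weighted mean

    PSM_{p,k}(v) = ( sum_i w_i p_i [v in C_i] ) / ( sum_i w_i [v in C_i] )

over the contributing contour files `C_i` with parameter values `p_i`
and scalar per-case weights `w_i`. The map is undefined (not zero) at
voxels no contributing contour covers, and — being a weighted mean — is
always bounded by the range of the contributing `p_i` at each voxel.

A prediction for a new case is the unweighted mean of the covered map
values inside that case's normalized contour, reported together with the
SD, range, median, covered-voxel count and coverage fraction. Values are
kept continuous (a prediction of, e.g., 3.05 against an ordinal grade of
3 is meaningful); rounding or calibrating to the ordinal scale is out of
scope. A contour with no covered voxel is an explicit "uncovered" result,
never a silent zero.

The underlying assumption is "same-parameter-different-patients":
outcome depends on lesion size and location, so pooling the outcomes of
patients whose lesions covered a voxel estimates the outcome burden that
location carries. The method does not model time-varying treatment
effects, non-stroke mortality or any covariate other than the three case
selection variables below.

## Accumulator representation, merging

Maps are stored as three exact accumulators — `sum_map` (sum of `w p`),
`weight_map` (sum of `w`) and `count_map` (contributor count) — rather
than as the ratio. Consequences:

* maps built from disjoint sub-cohorts merge by element-wise addition,
  exactly; a cohort split across centers gives bit-identical accumulators
  to a one-shot build (sums are associative; exactness is guaranteed for
  integer-valued parameters under `w1`, and holds to double rounding
  otherwise);
* a map is updatable case-by-case (a "dynamic atlas");
* only variants that do not depend on the predicted case (`w1`, `w2`)
  may be pre-computed and merged; `merge_psm()` refuses the others.

On disk a map is a directory with `sum.nii`, `weight.nii` (float64 —
chosen over float32 so the accumulators round-trip exactly and merged
bundles remain exact), `count.nii` (int32) and a JSON sidecar.

## The eight weighting variants

The published panel defining the eight weights is not machine-readable;
the formulas used here are reconstructions honoring every stated
behavioural constraint, and the registry is pluggable
(`register_weight()`, ids >= 9) so an alternative reading drops in
without touching the build code. With `Vpsa` the contributing contour's
volume, `Vp` the predicted contour's volume, `Vo` their overlap and `d`
the centroid distance (all from atlas-space masks, where overlap and
distance are meaningful):

| id | formula | behaviour |
|----|---------|-----------|
| w1 | 1 | plain averaging; pre-computable |
| w2 | 1/Vpsa | favours small (well-localized) contours; pre-computable |
| w3 | Vo/Vpsa + Vo/Vp | overlap fractions of both contours; equals 2 for identical contours |
| w4 | Vo/Vp | overlap fraction of the predicted contour |
| w5 | 1/(1+d) | centroid proximity (d in mm) |
| w6 | (1/Vpsa)(1 − (Vpsa − Vo)/Vpsa) | penalizes the unoverlapped contributing remainder |
| w7 | (1/Vpsa)(1 − (Vp − Vo)/Vp) | penalizes the unoverlapped predicted remainder |
| w8 | (1/Vpsa)(Vo/Vp) | size-normalized overlap fraction |

Under this reconstruction w7 and w8 are algebraically identical; both
ids are kept because the interface is contractual and the variants are
statistically equivalent in practice anyway. Weights carrying units
(cm^-3) need no rescaling: the division by the summed weights cancels
them. The normalization is by the sum of weights, which for `w1` reduces
to division by the contributor count; this is the only reading that
makes all eight variants well-defined means. A voxel where the total
weight is zero (possible for the overlap weights when every contributing
contour is disjoint from the predicted one) is undefined, and a wholly
undefined map yields an "uncovered" prediction.

## Spatial normalization

Native-space masks are mapped to the atlas grid by the classic
12-subvolume Talairach proportional-grid transform, fitted from the
modified Talairach landmarks supplied per case (AC, PC, the six cortical
extremes, and the midsagittal-plane normal). Automatic landmark and MSP
detection are external problems; landmarks are inputs. An orthonormal
frame is anchored at AC (x along the MSP normal toward R, y along
PC→AC); each axis is a monotone piecewise-linear stretch carrying the
native landmarks onto their atlas counterparts, giving 2 × 3 × 2 affine
blocks that agree on shared boundary planes by construction and are
invertible whenever the landmark ordering is valid (which `fit_transform`
checks). Resampling is pull-back nearest-neighbor: an atlas voxel is
foreground iff its center maps back inside the native mask — hole-free
and faithful to binary-mask semantics. Cases violating the no-mass-shift
assumption (midline shift, large edema) are the caller's responsibility;
only landmark geometry is validated.

The atlas grid is 512 × 512 × 64 voxels at 0.320119 × 0.320119 × 2 mm.
The anatomical anchor of the grid is not part of the published
specification; the package ships a documented convention
(`default_atlas_landmarks()`: AC on the grid midline at 59% of the
anteroposterior and 55% of the craniocaudal extent, cortical extremes at
fractional positions), overridable per config. All simulations and tests
run on a reduced 64 × 64 × 16 grid with the same physical field of view
(`reduced_space()`); the full grid is a switch.

## Case selection and the evaluation grid

A map can be restricted to cases whose infarct volume, NIHSS at
admission (NIHSSa) and NIHSS at day 7 (NIHSS7) lie in closed intervals.
An interval covering the whole domain is unconstrained and does not
exclude cases missing that variable; a constrained variable excludes
cases missing it. The reference design crosses 8 weights with 4 volume
ranges (whole, <= 8, <= 25.9, <= 70 cm^3) and 4 + 4 NIHSS ranges from
thresholds 5 and 13 ([0-42], [0-5], [6-13], [14-42]) — 512 cells per
case and parameter; `loo_workload()` reproduces the published
bookkeeping (589,824 map builds, 74,907,648 case-processings at n = 128,
9 parameters).

`run_loo()` evaluates the grid leave-one-out. It aggregates only inside
the predicted contour (the only voxels a prediction reads), grouping
cells by selection and evaluating all weights of a group with one matrix
product; this is algebraically identical to the full
`build_psm()` + `extract_distribution()` composition (asserted exactly in
tests) and makes the n = 64 × 512-cell × 9-parameter demo run in well
under a minute where the naive composition would take hours.

Summaries follow the published analyses: per-variant pooled mean ± sample
SD of the absolute error by selection mode (which variables are
constrained), with mRS errors pooled across time and value; the
"average" row is the mean of the per-weight means (the published pooling
for that row is not stated; this is the reading adopted). Uncovered
predictions are excluded from pools and counted separately (the source
is silent on them). The error-reduction ratio divides the constrained
pool's mean error by the unconstrained pool's. Best selection variables
for a given actual grade are the modal selection cell among rows at or
below the 25th error percentile (linear-interpolation quantile, boundary
ties included), ties broken by the wider range then enumeration order.
Variant comparison uses Welch's two-sample t-test by default (the source
says only "Student's t"; Welch is the safer default, the pooled test is
a flag), two-tailed, with degenerate pairs mapped to p = 1 (equal
constant pools) or 0. No multiple-testing correction is applied, matching
the published analysis.

Dichotomized ROC analysis scores the continuous predictions against
dichotomized actuals (mRS 0-2 vs 3-6, mRS 0-1 vs 2-6, BI 0-45 vs
46-100). For BI the score is sign-flipped so that the unfavourable (low
BI) class gets the high scores; an unflipped score would report AUC
below 0.5 for an informative predictor. The AUC is the rank-statistic
(pairwise concordance, ties = 1/2); the 95% CI is a percentile bootstrap
with 2000 resamples and an explicit seed (default 0), with a DeLong
normal-approximation CI behind a flag — the published CI method is not
stated.

## The synthetic cohort: what it emulates, what it does not

`make_cohort()` generates the world the method assumes. A smooth
ground-truth field `G_p` per parameter (a mixture of 12 random plane
cosine waves with wavelengths in [smoothness, 4 x smoothness], default
smoothness 40 mm) makes outcome depend on lesion location by
construction; fields are centered at the reference cohort's printed
per-parameter means (mRS 2.9/2.4/2.04/2.02/2.2 at days 7-360, BI
73/83.8/86.8/87) — centering at the range midpoint skews nearly every
case into the unfavourable class, unlike the cohort the method was
reported on — and clipped into range. Lesions are voxelized random
ellipsoids with log-normal volumes (median 8 cm^3, the reference 50th
percentile; sdlog 1.74 reaching the reported ~251 cm^3 maximum at the
upper tail; truncated to [1, 251] cm^3), centered around left/right
MCA-like hotspots: uniformly placed lesions essentially never overlap at
desk-scale n, which would contradict the territory clustering of real
infarct cohorts and make every prediction uncovered. Outcomes are
`clip(round(mean(G_p over the atlas-space mask) + N(0, sigma)))` with
`sigma` in mRS grades (BI noise scaled by 100/6); NIHSSa is
`clip(round(2.5 log(V) + 3 + N(0, 3)))` (volume-correlated, matching the
reported mean of ~8.3 at median volume) and NIHSS7
`clip(round(0.85 NIHSSa + noise))`. Outcomes go missing with the
reference cohort's per-day rates (e.g. 2/128 for mRS7 up to 29/128 for
BI360). The native frame is the atlas frame perturbed by a random
rotation–anisotropic-scaling–translation jitter whose exact landmark
images are emitted, so the landmark-fitted transform inverts the jitter
exactly pointwise; voxelwise mask recovery passes through two
nearest-neighbor resamplings and can differ by a one-voxel boundary
shell (identity jitter is bit-exact). All randomness flows from one
master seed through per-case counters.

Not emulated: CT appearance, vascular-territory lesion shapes, lesion
growth, correlated missingness, or inter-rater contouring variability.
A green synthetic test therefore establishes the correctness of the
machinery and the statistical behaviour of the estimator under its own
assumptions — not clinical performance.

## Numerical choices and degenerate inputs

* Voxel indexing is 0-based; a voxel belongs to a mask iff its flag is
  set; volumes are voxel counts times the voxel volume (no
  partial-volume geometry). Centroids are unweighted means of foreground
  voxel centers.
* Missing clinical values are first-class (`NA`); a case is excluded
  only from computations needing that value.
* `min_count` (default 0, matching the main analyses) masks map voxels
  supported by fewer contour files than the threshold — the
  low-thresholded infarct-frequency idea for outlier reduction.
* Degenerate landmark sets (coincident AC/PC, L/R on one side, swapped
  A/P, MSP normal parallel to AC-PC) are rejected at fit time; a lesion
  mapping wholly outside the grid, or an empty normalized mask, is an
  error, as is building a map with zero contributing cases.
* Prediction SD of a single covered voxel is reported as 0 (with the
  voxel count alongside), as is the sample SD of a single pooled error.

## Known limitations

The low-DOF piecewise-affine normalization trades registration accuracy
for speed and robustness on sparse CT; high-DOF warping is explicitly
out of scope. The w7/w8 coincidence above means this reconstruction has
seven distinct weighting behaviours, not eight. Published clinical
result tables are properties of a private 128-patient dataset and are
not reproduced; the package's empirical claims are limited to what its
tests and acceptance script compute on synthetic cohorts (for example:
the noiseless 200-case recovery correlation r = 0.78 against a pilot-
pinned threshold of 0.75, and leave-one-out error increasing with the
outcome noise).
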