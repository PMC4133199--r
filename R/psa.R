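#' Case-selection specification
#'
#' Closed intervals on the three case-selection variables: infarct volume
#' (cm^3), NIHSS at admission and NIHSS at day 7. A variable whose interval
#' covers its whole domain (volume `[0, Inf]`, NIHSS `[0, 42]`) is treated
#' as unconstrained: cases with a missing value of that variable are then
#' NOT excluded.
#'
#' @param volume closed interval, cm^3; default whole range.
#' @param nihssa,nihss7 closed integer intervals within `[0, 42]`.
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(volume = c(0, Inf), nihssa = c(0, 42),
                           nihss7 = c(0, 42)) {
  chk <- function(r, name, lo, hi) {
    r <- as.numeric(r)
    if (length(r) != 2 || is.na(r[1]) || is.na(r[2]) || r[1] > r[2])
      stop(sprintf("selection_spec: %s must be a closed interval lo <= hi", name))
    if (r[1] < lo || (is.finite(hi) && r[2] > hi))
      stop(sprintf("selection_spec: %s must lie within [%s, %s]", name, lo, hi))
    r
  }
  structure(list(volume = chk(volume, "volume", 0, Inf),
                 nihssa = chk(nihssa, "nihssa", 0, 42),
                 nihss7 = chk(nihss7, "nihss7", 0, 42)),
            class = "selection_spec")
}

#' The unconstrained ("all cases") selection
#' @export
selection_all <- function() selection_spec()

#' @export
print.selection_spec <- function(x, ...) {
  cat(sprintf("<selection> volume [%g, %g] cm^3, NIHSSa [%g, %g], NIHSS7 [%g, %g]\n",
              x$volume[1], x$volume[2], x$nihssa[1], x$nihssa[2],
              x$nihss7[1], x$nihss7[2]))
  invisible(x)
}

selection_constrained <- function(spec) {
  c(volume = !(spec$volume[1] <= 0 && !is.finite(spec$volume[2])),
    nihssa = !(spec$nihssa[1] <= 0 && spec$nihssa[2] >= 42),
    nihss7 = !(spec$nihss7[1] <= 0 && spec$nihss7[2] >= 42))
}

selection_id <- function(spec) {
  paste(format(c(spec$volume, spec$nihssa, spec$nihss7), trim = TRUE),
        collapse = "|")
}

selection_mask <- function(cases, spec) {
  con <- selection_constrained(spec)
  keep <- rep(TRUE, nrow(cases))
  test <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]
  if (con["volume"]) keep <- keep & test(cases$infarct_volume_cm3, spec$volume)
  if (con["nihssa"]) keep <- keep & test(cases$nihssa, spec$nihssa)
  if (con["nihss7"]) keep <- keep & test(cases$nihss7, spec$nihss7)
  keep
}

#' Select the cases contributing to a population map
#'
#' Closed-interval membership on each constrained variable; a case with a
#' missing value of a constrained variable is excluded; input order is
#' preserved.
#'
#' @param cases clinical data.frame (see [read_clinical_table()]).
#' @param spec a [selection_spec()].
#' @return the selected subset of `cases`.
#' @export
select_cases <- function(cases, spec = selection_all()) {
  stopifnot(inherits(spec, "selection_spec"))
  cases[selection_mask(cases, spec), , drop = FALSE]
}

#' Population-based stroke map (PSM)
#'
#' One parameter's weighted spatial distribution over the atlas grid,
#' stored as exact accumulators so maps can be merged and updated:
#' `sum_map` holds the per-voxel sum of `weight * value` over contributing
#' contour files, `weight_map` the per-voxel sum of weights, `count_map`
#' the number of contributing contour files covering the voxel. The map
#' value at a voxel is `sum_map / weight_map` where `weight_map > 0` and
#' undefined (NA) elsewhere; for the plain-averaging variant (weight 1)
#' this is the arithmetic mean and `weight_map` equals `count_map`.
#'
#' @name stroke_map
NULL

new_stroke_map <- function(parameter, weight_id, sum_map, weight_map,
                           count_map, n_cases, case_ids, selection, space) {
  structure(list(parameter = parameter, weight_id = as.integer(weight_id),
                 sum_map = sum_map, weight_map = weight_map,
                 count_map = count_map, n_cases = as.integer(n_cases),
                 case_ids = as.character(case_ids), selection = selection,
                 space = space),
            class = "stroke_map")
}

#' @export
print.stroke_map <- function(x, ...) {
  cat(sprintf("<stroke_map> %s, weight w%d, %d contributing case(s), %d covered voxel(s)\n",
              x$parameter, x$weight_id, x$n_cases, sum(x$count_map > 0)))
  invisible(x)
}

#' Per-voxel map values of a stroke map
#' @param psm a `stroke_map`.
#' @return numeric 3D array: `sum_map / weight_map`, NA where undefined.
#' @export
psm_values <- function(psm) {
  v <- psm$sum_map / psm$weight_map
  v[psm$weight_map <= 0] <- NA_real_
  v
}

#' Build a population-based stroke map
#'
#' For each selected case with a non-missing value `p` of `parameter` and
#' an atlas-space contour: compute the case's weight `w` under variant
#' `weight_id`, then add `w * p` to `sum_map`, `w` to `weight_map` and 1 to
#' `count_map` on every voxel of the contour. Cases missing the parameter
#' are silently skipped; `n_cases` reflects actual contributors. Variants
#' 3..8 need the contour of the case under prediction.
#'
#' @param cases clinical data.frame.
#' @param contours named list (by case id) of atlas-frame `contour_file`s.
#' @param parameter parameter name, e.g. `"mRS90"`.
#' @param weight_id variant id 1..8 (or registered user id).
#' @param selection a [selection_spec()].
#' @param predicted_contour atlas-frame `contour_file` of the case under
#'   prediction; required iff the variant needs it.
#' @param space atlas `psa_space`.
#' @return a `stroke_map`.
#' @export
build_psm <- function(cases, contours, parameter, weight_id = 1L,
                      selection = selection_all(), predicted_contour = NULL,
                      space) {
  stopifnot(is_psa_space(space))
  spec <- weight_spec(weight_id)
  if (spec$needs_predicted_case && is.null(predicted_contour))
    stop(sprintf("build_psm: weight %d requires predicted_contour", spec$id))
  col <- parameter_column(parameter)
  sel <- select_cases(cases, selection)
  sel <- sel[!is.na(sel[[col]]), , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("build_psm: no contributing cases after selection and missing-value removal")
  miss <- setdiff(sel$case_id, names(contours))
  if (length(miss))
    stop(sprintf("build_psm: no contour for case(s): %s",
                 paste(miss, collapse = ", ")))
  pc_idx <- NULL
  if (!is.null(predicted_contour)) {
    if (!spaces_equal(predicted_contour$space, space))
      stop("build_psm: predicted_contour grid mismatch")
    pc_idx <- predicted_contour$idx
  }
  dims <- space$dims
  sum_map <- array(0, dims)
  weight_map <- array(0, dims)
  count_map <- array(0L, dims)
  for (r in seq_len(nrow(sel))) {
    cf <- contours[[sel$case_id[r]]]
    if (!spaces_equal(cf$space, space))
      stop(sprintf("build_psm: contour grid mismatch for case %s", cf$case_id))
    ctx <- contour_weight_context(cf, predicted_contour, space)
    w <- compute_weight(spec$id, ctx)
    p <- sel[[col]][r]
    sum_map[cf$idx] <- sum_map[cf$idx] + w * p
    weight_map[cf$idx] <- weight_map[cf$idx] + w
    count_map[cf$idx] <- count_map[cf$idx] + 1L
  }
  new_stroke_map(col, spec$id, sum_map, weight_map, count_map,
                 nrow(sel), sel$case_id, selection, space)
}

# WeightContext of a contributing contour versus the predicted contour,
# computed from atlas-space (normalized) masks.
contour_weight_context <- function(cf, predicted_contour, space) {
  if (is.null(predicted_contour))
    return(weight_context(v_psa = cf$volume_cm3))
  weight_context(
    v_psa = cf$volume_cm3,
    v_p = predicted_contour$volume_cm3,
    v_o = overlap_volume(cf, predicted_contour, space),
    d = centroid_distance(cf, predicted_contour, space)
  )
}

#' An empty (zero-case) stroke map
#'
#' All-zero accumulators; the identity element of [merge_psm()].
#' @inheritParams build_psm
#' @return a `stroke_map` with `n_cases = 0`.
#' @export
empty_psm <- function(parameter, weight_id = 1L, selection = selection_all(),
                      space) {
  stopifnot(is_psa_space(space))
  new_stroke_map(parameter_column(parameter), weight_id,
                 array(0, space$dims), array(0, space$dims),
                 array(0L, space$dims), 0L, character(0), selection, space)
}

#' Infarct frequency map
#'
#' Per-voxel count of contour files covering each voxel (the `count_map`
#' of any plain-averaging build). Low counts flag map regions supported by
#' few cases; thresholding them reduces prediction outliers.
#'
#' @param contours list of atlas-frame `contour_file`s.
#' @param space atlas `psa_space`.
#' @return integer 3D array.
#' @export
build_frequency_map <- function(contours, space) {
  stopifnot(is_psa_space(space))
  freq <- array(0L, space$dims)
  for (cf in contours) {
    if (!spaces_equal(cf$space, space))
      stop("build_frequency_map: contour grid mismatch")
    freq[cf$idx] <- freq[cf$idx] + 1L
  }
  freq
}

#' Merge two pre-computable stroke maps
#'
#' Element-wise addition of the accumulators. Only the variants that do
#' not depend on the predicted case (weights 1 and 2) can be built
#' independently, e.g. at different centers, and merged; the contributing
#' case sets must be disjoint and all metadata must match.
#'
#' @param a,b `stroke_map`s with equal parameter, weight, selection, space.
#' @return merged `stroke_map`.
#' @export
merge_psm <- function(a, b) {
  stopifnot(inherits(a, "stroke_map"), inherits(b, "stroke_map"))
  if (weight_spec(a$weight_id)$needs_predicted_case ||
      weight_spec(b$weight_id)$needs_predicted_case)
    stop("merge_psm: only weights 1 and 2 are pre-computable and mergeable")
  if (!identical(a$parameter, b$parameter) ||
      a$weight_id != b$weight_id ||
      !identical(selection_id(a$selection), selection_id(b$selection)) ||
      !spaces_equal(a$space, b$space))
    stop("merge_psm: metadata mismatch (parameter, weight, selection or space)")
  if (length(intersect(a$case_ids, b$case_ids)))
    stop("merge_psm: contributing case sets are not disjoint")
  new_stroke_map(a$parameter, a$weight_id,
                 a$sum_map + b$sum_map,
                 a$weight_map + b$weight_map,
                 a$count_map + b$count_map,
                 a$n_cases + b$n_cases,
                 c(a$case_ids, b$case_ids),
                 a$selection, a$space)
}
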