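#' Extract the map distribution inside a predicted case's contour
#'
#' Collects the map values `sum_map/weight_map` over the voxels of the
#' normalized contour that are covered by the map (`weight_map > 0`) and
#' supported by at least `min_count` contributing contour files, and
#' summarizes them. The point prediction is the unweighted mean of the
#' covered voxel values (the median and a value histogram are reported as
#' extras). `min_count = 0` disables frequency thresholding. Predictions
#' are never rounded to the ordinal scale.
#'
#' A contour with zero covered voxels yields `covered = FALSE` with NA
#' statistics: an explicit "uncovered" signal, never a silent 0.
#'
#' @param psm a `stroke_map`.
#' @param contour atlas-frame `contour_file` of the case under prediction.
#' @param min_count minimum per-voxel contributor count (integer >= 0).
#' @return object of class `prediction_result` with fields `parameter`,
#'   `predicted_mean`, `predicted_median`, `sd`, `min`, `max`,
#'   `n_voxels_covered`, `coverage_fraction`, `covered`, `actual`,
#'   `abs_error`.
#' @export
extract_distribution <- function(psm, contour, min_count = 0L) {
  stopifnot(inherits(psm, "stroke_map"), is_contour_file(contour))
  if (!spaces_equal(psm$space, contour$space))
    stop("extract_distribution: contour grid does not match the map grid")
  if (min_count < 0) stop("extract_distribution: min_count must be >= 0")
  idx <- contour$idx
  ok <- psm$weight_map[idx] > 0 & psm$count_map[idx] >= min_count
  vals <- psm$sum_map[idx][ok] / psm$weight_map[idx][ok]
  n <- length(vals)
  res <- list(
    parameter = psm$parameter,
    predicted_mean = if (n) mean(vals) else NA_real_,
    predicted_median = if (n) stats::median(vals) else NA_real_,
    sd = if (n > 1) stats::sd(vals) else if (n == 1) 0 else NA_real_,
    min = if (n) min(vals) else NA_real_,
    max = if (n) max(vals) else NA_real_,
    n_voxels_covered = n,
    coverage_fraction = n / contour$volume_voxels,
    covered = n > 0L,
    actual = NA_real_,
    abs_error = NA_real_
  )
  structure(res, class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  if (x$covered) {
    cat(sprintf("<prediction> %s: %.3f (sd %.3f, range [%.3f, %.3f], %d voxels, coverage %.1f%%)",
                x$parameter, x$predicted_mean, x$sd, x$min, x$max,
                x$n_voxels_covered, 100 * x$coverage_fraction))
    if (!is.na(x$actual))
      cat(sprintf("; actual %g, |error| %.3f", x$actual, x$abs_error))
    cat("\n")
  } else {
    cat(sprintf("<prediction> %s: UNCOVERED (no atlas support inside the contour)\n",
                x$parameter))
  }
  invisible(x)
}

#' Predict all parameters of one case from a set of stroke maps
#'
#' One [extract_distribution()] per map; the absolute prediction error
#' (|predicted - actual|) is filled in wherever the case's actual value is
#' known. An uncovered parameter is reported as such without aborting the
#' remaining parameters.
#'
#' @param atlas named/unnamed list of `stroke_map`s sharing one space.
#' @param contour atlas-frame `contour_file` of the case.
#' @param actuals optional one-row clinical data.frame (or NULL) holding
#'   the case's actual values.
#' @param min_count per-voxel contributor-count threshold.
#' @return list of `prediction_result`, one per map, named by parameter.
#' @export
predict_case <- function(atlas, contour, actuals = NULL, min_count = 0L) {
  if (inherits(atlas, "stroke_map")) atlas <- list(atlas)
  out <- vector("list", length(atlas))
  nms <- character(length(atlas))
  for (i in seq_along(atlas)) {
    psm <- atlas[[i]]
    res <- extract_distribution(psm, contour, min_count)
    if (!is.null(actuals)) {
      col <- parameter_column(psm$parameter)
      if (col %in% names(actuals) && nrow(actuals) == 1) {
        res$actual <- as.numeric(actuals[[col]][1])
        if (res$covered && !is.na(res$actual))
          res$abs_error <- abs(res$predicted_mean - res$actual)
      }
    }
    out[[i]] <- res
    nms[i] <- psm$parameter
  }
  names(out) <- nms
  out
}

#' Tabulate prediction results
#' @param results list of `prediction_result` (as from [predict_case()]).
#' @return data.frame with one row per parameter.
#' @export
prediction_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(parameter = r$parameter, predicted = r$predicted_mean,
               sd = r$sd, min = r$min, max = r$max,
               n_voxels_covered = r$n_voxels_covered,
               coverage_fraction = r$coverage_fraction,
               covered = r$covered, actual = r$actual,
               abs_error = r$abs_error, stringsAsFactors = FALSE)))
}
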