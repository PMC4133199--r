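# Leave-one-out experiment grid and summary statistics.

#' The default experiment-grid factors
#'
#' Eight weight variants; four infarct-volume ranges (whole range and the
#' <= 8.0 / 25.9 / 70 cm^3 thresholds, the first two sitting at the 50th
#' and 75th volume percentiles of a 128-case reference cohort); four
#' ranges for each of NIHSSa and NIHSS7 from the thresholds 5 and 13
#' ([0-42], [0-5], [6-13], [14-42]).
#'
#' @return list with `weights`, `volume`, `nihssa`, `nihss7`.
#' @export
default_grid_factors <- function() {
  nihss_ranges <- list(c(0, 42), c(0, 5), c(6, 13), c(14, 42))
  list(
    weights = 1:8,
    volume = list(c(0, Inf), c(0, 8.0), c(0, 25.9), c(0, 70)),
    nihssa = nihss_ranges,
    nihss7 = nihss_ranges
  )
}

#' Enumerate the experiment grid
#'
#' Full Cartesian product of weight ids and the three selection-variable
#' range lists, in deterministic order (weight slowest, NIHSS7 fastest).
#' With the default factors (8 x 4 x 4 x 4) this yields 512 cells: the
#' number of map instances evaluated per case and per predicted parameter.
#'
#' @param weights integer vector of weight ids.
#' @param volume_ranges,nihssa_ranges,nihss7_ranges lists of closed
#'   intervals.
#' @return data.frame with columns `weight_id`, `vol_lo`, `vol_hi`,
#'   `na_lo`, `na_hi`, `n7_lo`, `n7_hi`.
#' @export
enumerate_grid <- function(weights = default_grid_factors()$weights,
                           volume_ranges = default_grid_factors()$volume,
                           nihssa_ranges = default_grid_factors()$nihssa,
                           nihss7_ranges = default_grid_factors()$nihss7) {
  if (!length(weights) || !length(volume_ranges) || !length(nihssa_ranges) ||
      !length(nihss7_ranges))
    stop("enumerate_grid: all factor lists must be nonempty")
  idx <- expand.grid(n7 = seq_along(nihss7_ranges),
                     na = seq_along(nihssa_ranges),
                     vol = seq_along(volume_ranges),
                     w = seq_along(weights))
  vget <- function(lst, i, j) vapply(lst[i], function(r) r[j], numeric(1))
  data.frame(
    weight_id = as.integer(weights[idx$w]),
    vol_lo = vget(volume_ranges, idx$vol, 1),
    vol_hi = vget(volume_ranges, idx$vol, 2),
    na_lo = vget(nihssa_ranges, idx$na, 1),
    na_hi = vget(nihssa_ranges, idx$na, 2),
    n7_lo = vget(nihss7_ranges, idx$n7, 1),
    n7_hi = vget(nihss7_ranges, idx$n7, 2)
  )
}

grid_row_selection <- function(grid, i) {
  selection_spec(volume = c(grid$vol_lo[i], grid$vol_hi[i]),
                 nihssa = c(grid$na_lo[i], grid$na_hi[i]),
                 nihss7 = c(grid$n7_lo[i], grid$n7_hi[i]))
}

#' Bookkeeping of a leave-one-out experiment
#'
#' Exact combinatorial consequences of the experimental design: the number
#' of grid cells, the number of map builds (`n_cases x n_parameters x
#' cells`, each map built from the remaining `n_cases - 1` cases) and the
#' total number of case-processings.
#'
#' @param n_cases cohort size.
#' @param n_parameters number of predicted parameters.
#' @param grid experiment grid (data.frame from [enumerate_grid()]).
#' @return list with `cells`, `psm_builds`, `case_processings`.
#' @export
loo_workload <- function(n_cases, n_parameters, grid = enumerate_grid()) {
  cells <- nrow(grid)
  builds <- as.numeric(n_cases) * n_parameters * cells
  list(cells = cells, psm_builds = builds,
       case_processings = builds * (n_cases - 1))
}

#' Leave-one-out evaluation over the experiment grid
#'
#' For every case `c`, parameter `p` and grid cell (weight, selection):
#' build the population map from all cases except `c` under that cell's
#' selection and weight (using `c`'s contour for the predicted-case-aware
#' weights), predict `c`, and record the prediction and its absolute
#' error. Cells whose map gives the contour no covered voxel are recorded
#' with `covered = FALSE`, never as silent zeros.
#'
#' The implementation aggregates only within the predicted contour (the
#' only voxels a prediction reads), which is algebraically identical to a
#' full [build_psm()] + [extract_distribution()] composition.
#'
#' @param cases clinical data.frame.
#' @param contours named list of atlas-frame `contour_file`s.
#' @param parameters character vector of parameter names.
#' @param grid data.frame from [enumerate_grid()].
#' @param space atlas `psa_space`.
#' @param min_count per-voxel contributor-count threshold.
#' @param progress print one line per case.
#' @return data.frame (the evaluation table): one row per case x parameter
#'   x grid cell with columns `case_id`, `parameter`, `weight_id`,
#'   `vol_lo..n7_hi`, `predicted`, `actual`, `abs_error`, `covered`,
#'   `n_voxels`, `n_contributors`.
#' @export
run_loo <- function(cases, contours, parameters = outcome_parameters(),
                    grid = enumerate_grid(), space, min_count = 0L,
                    progress = FALSE) {
  n <- nrow(cases)
  if (n < 2) stop("run_loo: need at least 2 cases")
  stopifnot(is_psa_space(space))
  ids <- cases$case_id
  miss <- setdiff(ids, names(contours))
  if (length(miss))
    stop(sprintf("run_loo: no contour for case(s): %s", paste(miss, collapse = ", ")))
  cfs <- contours[ids]
  for (cf in cfs)
    if (!spaces_equal(cf$space, space)) stop("run_loo: contour grid mismatch")
  cols <- vapply(parameters, parameter_column, character(1))
  vols <- vapply(cfs, function(cf) cf$volume_cm3, numeric(1))
  cents <- t(vapply(cfs, function(cf) mask_centroid_mm(cf, space), numeric(3)))

  # group grid cells by unique selection; weights evaluated jointly per group
  sel_key <- paste(grid$vol_lo, grid$vol_hi, grid$na_lo, grid$na_hi,
                   grid$n7_lo, grid$n7_hi, sep = "|")
  sel_groups <- split(seq_len(nrow(grid)), sel_key)
  # deterministic order: by first occurrence
  sel_groups <- sel_groups[order(vapply(sel_groups, min, integer(1)))]
  sel_specs <- lapply(sel_groups, function(rows) grid_row_selection(grid, rows[1]))

  n_rows <- n * length(parameters) * nrow(grid)
  out_case <- character(n_rows); out_param <- character(n_rows)
  out_grid_row <- integer(n_rows)
  out_pred <- rep(NA_real_, n_rows); out_actual <- rep(NA_real_, n_rows)
  out_nvox <- integer(n_rows); out_ncontrib <- integer(n_rows)
  pos <- 0L

  for (ci in seq_len(n)) {
    cf <- cfs[[ci]]
    v <- cf$idx
    others <- setdiff(seq_len(n), ci)
    m <- length(others)
    # coverage matrix restricted to the predicted contour
    M <- matrix(0, length(v), m)
    for (j in seq_len(m)) {
      hit <- match(cfs[[others[j]]]$idx, v)
      hit <- hit[!is.na(hit)]
      if (length(hit)) M[hit, j] <- 1
    }
    # weight matrix: one column per weight id in the grid
    wids <- sort(unique(grid$weight_id))
    W <- matrix(0, m, length(wids))
    for (j in seq_len(m)) {
      oj <- others[j]
      ov <- length(intersect_sorted(cfs[[oj]]$idx, v)) *
        space$voxel_volume_mm3 / 1000
      ctx <- weight_context(v_psa = vols[oj], v_p = vols[ci], v_o = ov,
                            d = sqrt(sum((cents[oj, ] - cents[ci, ])^2)))
      for (wi in seq_along(wids)) W[j, wi] <- compute_weight(wids[wi], ctx)
    }
    sub <- cases[others, , drop = FALSE]
    for (gi in seq_along(sel_groups)) {
      rows <- sel_groups[[gi]]
      selm <- selection_mask(sub, sel_specs[[gi]])
      row_wid <- match(grid$weight_id[rows], wids)
      for (pi in seq_along(cols)) {
        p <- sub[[cols[pi]]]
        keep <- which(selm & !is.na(p))
        actual <- as.numeric(cases[[cols[pi]]][ci])
        if (length(keep) == 0L) {
          for (ri in seq_along(rows)) {
            pos <- pos + 1L
            out_case[pos] <- ids[ci]; out_param[pos] <- cols[pi]
            out_grid_row[pos] <- rows[ri]
            out_actual[pos] <- actual
            out_nvox[pos] <- 0L; out_ncontrib[pos] <- 0L
          }
          next
        }
        A <- M[, keep, drop = FALSE]
        Wk <- W[keep, , drop = FALSE]
        num <- A %*% (Wk * p[keep])
        den <- A %*% Wk
        cnt <- as.vector(A %*% rep(1, length(keep)))
        for (ri in seq_along(rows)) {
          wcol <- row_wid[ri]
          okv <- den[, wcol] > 0 & cnt >= min_count
          pos <- pos + 1L
          out_case[pos] <- ids[ci]; out_param[pos] <- cols[pi]
          out_grid_row[pos] <- rows[ri]
          out_actual[pos] <- actual
          out_ncontrib[pos] <- length(keep)
          nv <- sum(okv)
          out_nvox[pos] <- nv
          if (nv > 0) out_pred[pos] <- mean(num[okv, wcol] / den[okv, wcol])
        }
      }
    }
    if (progress)
      message(sprintf("run_loo: case %d/%d (%s) done", ci, n, ids[ci]))
  }
  stopifnot(pos == n_rows)
  res <- data.frame(
    case_id = out_case, parameter = out_param,
    weight_id = grid$weight_id[out_grid_row],
    vol_lo = grid$vol_lo[out_grid_row], vol_hi = grid$vol_hi[out_grid_row],
    na_lo = grid$na_lo[out_grid_row], na_hi = grid$na_hi[out_grid_row],
    n7_lo = grid$n7_lo[out_grid_row], n7_hi = grid$n7_hi[out_grid_row],
    predicted = out_pred, actual = out_actual,
    abs_error = ifelse(!is.na(out_pred) & !is.na(out_actual),
                       abs(out_pred - out_actual), NA_real_),
    covered = out_nvox > 0L,
    n_voxels = out_nvox, n_contributors = out_ncontrib,
    stringsAsFactors = FALSE
  )
  # order: case x parameter blocks in grid order already; sort stably by
  # case, parameter, grid row for a reproducible layout
  res[order(match(res$case_id, ids), match(res$parameter, cols),
            out_grid_row), , drop = FALSE]
}

# classify each table row's selection cell into a selection mode by which
# variables are constrained
row_selection_mode <- function(table) {
  vol_con <- !(table$vol_lo <= 0 & !is.finite(table$vol_hi))
  na_con <- !(table$na_lo <= 0 & table$na_hi >= 42)
  n7_con <- !(table$n7_lo <= 0 & table$n7_hi >= 42)
  mode <- rep(NA_character_, nrow(table))
  mode[!vol_con & !na_con & !n7_con] <- "all"
  mode[vol_con & !na_con & !n7_con] <- "volume"
  mode[!vol_con & na_con & !n7_con] <- "nihssa"
  mode[vol_con & na_con & !n7_con] <- "volume_nihssa"
  mode[vol_con & na_con & n7_con] <- "volume_nihssa_nihss7"
  mode
}

SELECTION_MODES <- c("all", "volume", "nihssa", "volume_nihssa",
                     "volume_nihssa_nihss7")

pool_errors <- function(table, selection_mode, weight_id = NULL) {
  keep <- row_selection_mode(table) %in% selection_mode &
    table$covered & !is.na(table$abs_error)
  if (!is.null(weight_id)) keep <- keep & table$weight_id %in% weight_id
  table$abs_error[keep]
}

#' Per-variant prediction-error summary
#'
#' Pools the absolute errors of all covered rows whose selection cell
#' belongs to the given selection mode (which selection variables are
#' constrained), across cases, parameters and cells, and reports the mean
#' and sample SD per weight variant. The `average` attribute holds the
#' mean of the per-weight means and their SD.
#'
#' @param table evaluation table from [run_loo()].
#' @param selection_mode one of `"all"`, `"volume"`, `"nihssa"`,
#'   `"volume_nihssa"`, `"volume_nihssa_nihss7"`.
#' @return data.frame with `weight_id`, `mean_error`, `sd_error`
#'   (0 with `n = 1`), `n`.
#' @export
summarize_by_variant <- function(table, selection_mode = "all") {
  selection_mode <- match.arg(selection_mode, SELECTION_MODES)
  wids <- sort(unique(table$weight_id))
  rows <- lapply(wids, function(w) {
    e <- pool_errors(table, selection_mode, w)
    if (length(e) == 0L) stop("summarize_by_variant: empty error pool")
    data.frame(weight_id = w, mean_error = mean(e),
               sd_error = if (length(e) > 1) stats::sd(e) else 0,
               n = length(e))
  })
  out <- do.call(rbind, rows)
  attr(out, "average") <- list(mean_error = mean(out$mean_error),
                               sd_error = if (nrow(out) > 1)
                                 stats::sd(out$mean_error) else 0)
  out
}

#' Error reduction ratio of case selection
#'
#' Mean absolute prediction error under the constrained selection mode
#' divided by the mean error under the baseline (unconstrained) mode.
#'
#' @param table evaluation table.
#' @param constrained_mode,baseline_mode selection modes (see
#'   [summarize_by_variant()]).
#' @param weight_id optional weight filter.
#' @return scalar ratio.
#' @export
error_reduction_ratio <- function(table, constrained_mode,
                                  baseline_mode = "all", weight_id = NULL) {
  constrained_mode <- match.arg(constrained_mode, SELECTION_MODES)
  baseline_mode <- match.arg(baseline_mode, SELECTION_MODES)
  num <- pool_errors(table, constrained_mode, weight_id)
  den <- pool_errors(table, baseline_mode, weight_id)
  if (!length(num) || !length(den))
    stop("error_reduction_ratio: empty error pool")
  b <- mean(den)
  if (b == 0) stop("error_reduction_ratio: zero baseline error, ratio undefined")
  mean(num) / b
}

#' Best selection variables for one actual outcome value
#'
#' Among the covered rows whose actual outcome equals `actual_value`, take
#' the rows whose absolute error lies at or below the 25th percentile of
#' those errors (linear-interpolation quantile, boundary ties included)
#' and return the modal selection cell among them, with that cell's
#' overall mean and SD error over the same actual value. Ties are broken
#' by the wider selection (larger total range, hence more cases), then by
#' first occurrence.
#'
#' @param table evaluation table.
#' @param actual_value the actual outcome value (e.g. an mRS grade).
#' @return list with `selection` (a [selection_spec()]), `mean_error`,
#'   `sd_error`, `n`.
#' @export
best_selection_variables <- function(table, actual_value) {
  rows <- table[table$covered & !is.na(table$abs_error) &
                  !is.na(table$actual) & table$actual == actual_value, ,
                drop = FALSE]
  if (nrow(rows) < 4)
    stop("best_selection_variables: need at least 4 rows with that actual value")
  q25 <- stats::quantile(rows$abs_error, 0.25, names = FALSE)
  first_q <- rows[rows$abs_error <= q25, , drop = FALSE]
  key <- paste(first_q$vol_lo, first_q$vol_hi, first_q$na_lo, first_q$na_hi,
               first_q$n7_lo, first_q$n7_hi, sep = "|")
  tab <- table(key)
  width_of <- function(k) {
    p <- as.numeric(strsplit(k, "|", fixed = TRUE)[[1]])
    vol_w <- if (is.finite(p[2])) p[2] - p[1] else 1e9
    vol_w + (p[4] - p[3]) + (p[6] - p[5])
  }
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1) {
    w <- vapply(cand, width_of, numeric(1))
    cand <- cand[w == max(w)]
    if (length(cand) > 1) # first occurrence in the table
      cand <- cand[which.min(vapply(cand, function(k) match(k, key), numeric(1)))]
  }
  p <- as.numeric(strsplit(cand[1], "|", fixed = TRUE)[[1]])
  sel <- selection_spec(volume = p[1:2], nihssa = p[3:4], nihss7 = p[5:6])
  all_key <- paste(rows$vol_lo, rows$vol_hi, rows$na_lo, rows$na_hi,
                   rows$n7_lo, rows$n7_hi, sep = "|")
  e <- rows$abs_error[all_key == cand[1]]
  list(selection = sel, mean_error = mean(e),
       sd_error = if (length(e) > 1) stats::sd(e) else 0, n = length(e))
}

#' Pairwise comparison of the weight variants
#'
#' Two-sample t-test on the pooled absolute errors of each pair of weight
#' variants; returns the symmetric matrix of 2-tailed p-values (diagonal
#' 1). Welch's unequal-variance test is the default; the classic pooled
#' test is available with `method = "pooled"`. Degenerate pairs (both
#' pools constant) get p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param table evaluation table.
#' @param selection_mode which selection cells to pool (default all modes).
#' @param method `"welch"` or `"pooled"`.
#' @return k x k numeric matrix, dimnames the weight ids.
#' @export
compare_variants <- function(table, selection_mode = SELECTION_MODES,
                             method = c("welch", "pooled")) {
  method <- match.arg(method)
  wids <- sort(unique(table$weight_id))
  pools <- lapply(wids, function(w) pool_errors(table, selection_mode, w))
  k <- length(wids)
  for (i in seq_len(k))
    if (length(pools[[i]]) < 2)
      stop(sprintf("compare_variants: fewer than 2 errors for weight %d", wids[i]))
  P <- matrix(1, k, k, dimnames = list(wids, wids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- pools[[i]]; y <- pools[[j]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = (method == "pooled"))$p.value
    }
    P[i, j] <- P[j, i] <- p
  }
  P
}

# rank-based AUC (pairwise concordance with ties counted 1/2)
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auc_score: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

dichotomize <- function(actual, predicted, scheme) {
  switch(scheme,
    mrs_0_2 = list(labels = as.integer(actual >= 3), scores = predicted),
    mrs_0_1 = list(labels = as.integer(actual >= 2), scores = predicted),
    # low BI is the unfavourable class, so the score is sign-flipped
    bi_0_45 = list(labels = as.integer(actual <= 45), scores = -predicted),
    stop(sprintf("unknown dichotomization scheme '%s'", scheme))
  )
}

#' Dichotomized ROC analysis of continuous predictions
#'
#' Dichotomizes the actual outcomes (mRS favourable 0-2 vs unfavourable
#' 3-6; mRS excellent 0-1 vs 2-6; BI 0-45 vs 46-100) and measures the area
#' under the ROC curve of the continuous predictions as scores for the
#' unfavourable class, with a 95% confidence interval (percentile
#' bootstrap by default, DeLong by flag).
#'
#' @param predicted continuous predictions.
#' @param actual actual outcome values (same length).
#' @param scheme `"mrs_0_2"`, `"mrs_0_1"` or `"bi_0_45"`.
#' @param ci_method `"bootstrap"` or `"delong"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`,
#'   `scheme`, `ci_method`.
#' @export
dichotomized_auc <- function(predicted, actual,
                             scheme = c("mrs_0_2", "mrs_0_1", "bi_0_45"),
                             ci_method = c("bootstrap", "delong"),
                             n_boot = 2000L, conf = 0.95, seed = 0L) {
  scheme <- match.arg(scheme)
  ci_method <- match.arg(ci_method)
  ok <- !is.na(predicted) & !is.na(actual)
  d <- dichotomize(actual[ok], predicted[ok], scheme)
  n1 <- sum(d$labels == 1); n0 <- sum(d$labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("dichotomized_auc: both outcome classes must be present")
  auc <- auc_score(d$scores, d$labels)
  if (ci_method == "bootstrap") {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          i <- sample.int(length(d$labels), replace = TRUE)
          if (any(d$labels[i] == 1) && any(d$labels[i] == 0))
            return(auc_score(d$scores[i], d$labels[i]))
        }
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    ci <- c(qs[1], qs[2])
  } else {
    ci <- delong_ci(d$scores, d$labels, conf)
  }
  list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
       n_pos = n1, n_neg = n0, scheme = scheme, ci_method = ci_method)
}

# DeLong placement-based normal-approximation CI
delong_ci <- function(scores, labels, conf = 0.95) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r[seq_len(m)] - rx) / n
  v01 <- 1 - (r[m + seq_len(n)] - ry) / m
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

# run a block with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
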