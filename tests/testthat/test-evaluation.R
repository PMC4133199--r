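# Leave-one-out grid, summaries, variant comparison, ROC.

# minimal hand-built evaluation table rows
eval_row <- function(case_id, abs_error, weight_id = 1L, actual = 3,
                     vol = c(0, Inf), na = c(0, 42), n7 = c(0, 42),
                     covered = TRUE, parameter = "mrs90") {
  data.frame(case_id = case_id, parameter = parameter, weight_id = weight_id,
             vol_lo = vol[1], vol_hi = vol[2], na_lo = na[1], na_hi = na[2],
             n7_lo = n7[1], n7_hi = n7[2],
             predicted = actual + abs_error, actual = actual,
             abs_error = abs_error, covered = covered,
             n_voxels = 10L, n_contributors = 5L, stringsAsFactors = FALSE)
}

test_that("enumerate_grid is the exact Cartesian product", {
  expect_identical(nrow(enumerate_grid()), 512L) # the paper-default design
  g1 <- enumerate_grid(1L, list(c(0, Inf)), list(c(0, 42)), list(c(0, 42)))
  expect_identical(nrow(g1), 1L)
  g6 <- enumerate_grid(c(1L, 3L), list(c(0, 8), c(0, 25.9), c(0, Inf)),
                       list(c(0, 42)), list(c(0, 42)))
  expect_identical(nrow(g6), 6L)
  for (seed in 1:4) {
    set.seed(seed)
    ns <- sample(1:4, 4, replace = TRUE)
    g <- enumerate_grid(seq_len(ns[1]),
                        rep(list(c(0, Inf)), ns[2]),
                        rep(list(c(0, 42)), ns[3]),
                        rep(list(c(0, 42)), ns[4]))
    expect_identical(nrow(g), as.integer(prod(ns)))
  }
  expect_error(enumerate_grid(integer(0)), "nonempty")
})

test_that("loo_workload reproduces the experiment bookkeeping", {
  wl <- loo_workload(128, 9, enumerate_grid())
  expect_identical(wl$cells, 512L)
  expect_identical(wl$psm_builds, 589824)
  expect_identical(wl$case_processings, 74907648)
})

test_that("run_loo equals the direct build+predict composition", {
  sp <- tiny_space()
  mc <- micro_cohort(6, sp, seed = 61)
  grid <- enumerate_grid(c(1L, 2L, 4L, 5L),
                         list(c(0, Inf), c(0, 0.5)),
                         list(c(0, 42)), list(c(0, 42)))
  tab <- run_loo(mc$cases, mc$contours, "mRS90", grid, sp)
  expect_identical(nrow(tab), 6L * 1L * nrow(grid))
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    others <- mc$cases[mc$cases$case_id != row$case_id, ]
    sel <- selection_spec(volume = c(row$vol_lo, row$vol_hi),
                          nihssa = c(row$na_lo, row$na_hi),
                          nihss7 = c(row$n7_lo, row$n7_hi))
    pc <- mc$contours[[row$case_id]]
    ref <- tryCatch({
      psm <- build_psm(others, mc$contours, row$parameter, row$weight_id,
                       sel, predicted_contour =
                         if (weight_spec(row$weight_id)$needs_predicted_case)
                           pc else NULL,
                       space = sp)
      extract_distribution(psm, pc)
    }, error = function(e) NULL)
    if (is.null(ref) || !ref$covered) {
      expect_false(row$covered)
    } else {
      # BLAS accumulation order may differ from the case-by-case build
      expect_equal(row$predicted, ref$predicted_mean, tolerance = 1e-12)
      expect_identical(row$n_voxels, ref$n_voxels_covered)
    }
  }
})

test_that("a case never contributes to its own prediction", {
  sp <- tiny_space()
  mc <- micro_cohort(6, sp, seed = 62)
  grid <- enumerate_grid(1L, list(c(0, Inf)), list(c(0, 42)), list(c(0, 42)))
  base <- run_loo(mc$cases, mc$contours, "mRS90", grid, sp)
  poisoned <- mc$cases
  poisoned$mrs90[3] <- 6 - poisoned$mrs90[3] # flip case 3's own value
  after <- run_loo(poisoned, mc$contours, "mRS90", grid, sp)
  i <- base$case_id == mc$cases$case_id[3]
  expect_identical(base$predicted[i], after$predicted[i])
})

test_that("two identical cases predict each other without error", {
  sp <- tiny_space()
  cf <- box_contour("t1", sp, c(2, 2, 1), c(6, 6, 4))
  cases <- rbind(
    case_record("t1", infarct_volume_cm3 = cf$volume_cm3,
                mrs = c(NA, NA, 4, NA, NA)),
    case_record("t2", infarct_volume_cm3 = cf$volume_cm3,
                mrs = c(NA, NA, 4, NA, NA))
  )
  contours <- list(t1 = cf, t2 = contour_file("t2", cf$idx, sp))
  grid <- enumerate_grid(1L, list(c(0, Inf)), list(c(0, 42)), list(c(0, 42)))
  tab <- run_loo(cases, contours, "mRS90", grid, sp)
  expect_true(all(tab$covered))
  expect_true(all(tab$abs_error == 0))
  expect_error(run_loo(cases[1, ], contours[1], "mRS90", grid, sp),
               "at least 2")
})

test_that("per-variant summaries pool errors with sample SD", {
  tab <- rbind(eval_row("a", 0), eval_row("b", 2))
  s <- summarize_by_variant(tab, "all")
  expect_identical(s$mean_error, 1)
  expect_equal(s$sd_error, sqrt(2), tolerance = 1e-12)
  expect_identical(s$n, 2L)

  tab2 <- do.call(rbind, lapply(1:5, function(i) eval_row(letters[i], 0.7)))
  s2 <- summarize_by_variant(tab2, "all")
  expect_identical(s2$mean_error, 0.7)
  expect_identical(s2$sd_error, 0)

  s3 <- summarize_by_variant(eval_row("a", 1.5), "all")
  expect_identical(s3$sd_error, 0) # single row: SD reported as 0
  expect_identical(s3$n, 1L)

  # uncovered rows never enter the pool
  tab4 <- rbind(eval_row("a", 0), eval_row("b", 2),
                eval_row("x", 99, covered = FALSE))
  tab4$abs_error[3] <- NA
  expect_identical(summarize_by_variant(tab4, "all")$n, 2L)
  expect_error(summarize_by_variant(eval_row("a", 1, vol = c(0, 8)), "all"),
               "empty")
})

test_that("error reduction ratios divide constrained by baseline means", {
  tab <- rbind(eval_row("a", 1.0), eval_row("b", 1.0),
               eval_row("a", 0.5, vol = c(0, 8), na = c(0, 5), n7 = c(0, 5)),
               eval_row("b", 0.5, vol = c(0, 8), na = c(0, 5), n7 = c(0, 5)))
  expect_identical(error_reduction_ratio(tab, "all", "all"), 1)
  expect_identical(error_reduction_ratio(tab, "volume_nihssa_nihss7", "all"),
                   0.5)
  zero <- rbind(eval_row("a", 0), eval_row("b", 0.5, vol = c(0, 8)))
  expect_error(error_reduction_ratio(zero, "volume", "all"), "zero baseline")
})

test_that("best selection variables follow the first-quartile modal rule", {
  # 8 rows with actual = 2: errors 0.1..0.8; the 25th percentile is 0.275,
  # so the first quartile holds the 0.1 and 0.2 rows -> spec B is modal
  specA <- list(vol = c(0, Inf), na = c(0, 42), n7 = c(0, 42))
  specB <- list(vol = c(0, 8), na = c(0, 5), n7 = c(0, 5))
  rows <- rbind(
    eval_row("a", 0.1, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7),
    eval_row("b", 0.2, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7),
    eval_row("c", 0.3, actual = 2, vol = specA$vol, na = specA$na, n7 = specA$n7),
    eval_row("d", 0.4, actual = 2, vol = specA$vol, na = specA$na, n7 = specA$n7),
    eval_row("e", 0.5, actual = 2, vol = specA$vol, na = specA$na, n7 = specA$n7),
    eval_row("f", 0.6, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7),
    eval_row("g", 0.7, actual = 2, vol = specA$vol, na = specA$na, n7 = specA$n7),
    eval_row("h", 0.8, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7)
  )
  best <- best_selection_variables(rows, actual_value = 2)
  expect_identical(best$selection$volume, c(0, 8))
  expect_identical(best$selection$nihssa, c(0, 5))
  # overall stats of spec B at actual 2: errors {0.1, 0.2, 0.6, 0.8}
  expect_equal(best$mean_error, mean(c(0.1, 0.2, 0.6, 0.8)), tolerance = 1e-12)
  expect_equal(best$sd_error, sd(c(0.1, 0.2, 0.6, 0.8)), tolerance = 1e-12)

  # all errors equal: every row is in the first quartile; the wider
  # (all-range) spec wins the tie
  ties <- rbind(
    eval_row("a", 0.5, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7),
    eval_row("b", 0.5, actual = 2, vol = specB$vol, na = specB$na, n7 = specB$n7),
    eval_row("c", 0.5, actual = 2),
    eval_row("d", 0.5, actual = 2)
  )
  best2 <- best_selection_variables(ties, actual_value = 2)
  expect_identical(best2$selection$volume, c(0, Inf))
  expect_error(best_selection_variables(rows[1:3, ], 2), "at least 4")
})

test_that("variant comparison returns a symmetric p-value matrix", {
  tab <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      eval_row(letters[i], c(1, 2, 3, 4)[i], weight_id = 1L))),
    do.call(rbind, lapply(1:4, function(i)
      eval_row(letters[i], c(1, 2, 3, 4)[i], weight_id = 2L))),
    do.call(rbind, lapply(1:4, function(i)
      eval_row(letters[i], 0, weight_id = 3L))),
    do.call(rbind, lapply(1:4, function(i)
      eval_row(letters[i], 5, weight_id = 4L)))
  )
  P <- compare_variants(tab)
  expect_identical(dim(P), c(4L, 4L))
  expect_identical(P, t(P))
  expect_true(all(diag(P) == 1))
  expect_identical(P["1", "2"], 1) # identical samples -> t = 0 -> p = 1
  expect_identical(P["3", "4"], 0) # constant, fully separated
  expect_lt(P["1", "3"], 0.05)
})

test_that("AUC matches hand values and brute-force concordance", {
  expect_identical(dichotomized_auc(c(1, 2, 3, 10), c(0, 1, 1, 6),
                                    "mrs_0_2", n_boot = 50)$auc, 1)
  expect_identical(dichotomized_auc(rep(2, 6), c(0, 1, 4, 5, 2, 6),
                                    "mrs_0_2", n_boot = 50)$auc, 0.5)
  # 3 of 4 pos-neg pairs concordant
  r <- dichotomized_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 3, 0, 3), "mrs_0_2",
                        n_boot = 50)
  expect_identical(r$auc, 0.75)
  expect_error(dichotomized_auc(c(1, 2), c(0, 1), "mrs_0_2", n_boot = 10),
               "both outcome classes")

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    actual <- sample(0:6, n, replace = TRUE)
    labels <- as.integer(actual >= 3)
    if (length(unique(labels)) < 2) next
    r <- dichotomized_auc(scores, actual, "mrs_0_2", n_boot = 25,
                          seed = seed)
    expect_identical(r$auc, brute_auc(scores, labels))
    expect_lte(r$ci_lower, r$auc + 1e-12)
    expect_gte(r$ci_upper, r$auc - 1e-12)
  }
})

test_that("BI dichotomization orients low scores as unfavourable", {
  # low predicted BI should score high for the unfavourable class
  pred <- c(10, 20, 80, 90)
  act <- c(20, 30, 85, 95) # two unfavourable (<= 45), two favourable
  r <- dichotomized_auc(pred, act, "bi_0_45", n_boot = 50)
  expect_identical(r$auc, 1)
  d <- dichotomized_auc(pred, act, "bi_0_45", ci_method = "delong")
  expect_identical(d$auc, 1)
  expect_lte(d$ci_lower, 1)
})

test_that("bootstrap CIs are reproducible for a fixed seed", {
  set.seed(999) # outer RNG state must not leak in
  pred <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9, 0.2, 0.8)
  act <- c(0, 1, 3, 4, 1, 6, 5, 2)
  a <- dichotomized_auc(pred, act, "mrs_0_2", n_boot = 200, seed = 7)
  b <- dichotomized_auc(pred, act, "mrs_0_2", n_boot = 200, seed = 7)
  expect_identical(a$ci_lower, b$ci_lower)
  expect_identical(a$ci_upper, b$ci_upper)
})
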