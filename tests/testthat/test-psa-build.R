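# Case selection, weighted aggregation, frequency maps and merging.

test_that("select_cases applies closed intervals and handles missing values", {
  cases <- rbind(
    case_record("a", nihssa = 5, nihss7 = 4, infarct_volume_cm3 = 5.0),
    case_record("b", nihssa = 6, nihss7 = NA, infarct_volume_cm3 = 8.0),
    case_record("c", nihssa = 13, nihss7 = 2, infarct_volume_cm3 = 9.0),
    case_record("d", nihssa = 14, nihss7 = 1, infarct_volume_cm3 = 70.0),
    case_record("e", nihssa = NA, nihss7 = 0, infarct_volume_cm3 = 2.0)
  )
  # the all-range spec keeps everything, including missing values
  expect_identical(select_cases(cases, selection_all()), cases)

  vol8 <- selection_spec(volume = c(0, 8.0))
  expect_identical(select_cases(cases, vol8)$case_id, c("a", "b", "e"))

  na_6_13 <- selection_spec(nihssa = c(6, 13))
  expect_identical(select_cases(cases, na_6_13)$case_id, c("b", "c"))

  # a missing value of a constrained variable excludes the case
  n7 <- selection_spec(nihss7 = c(0, 5))
  expect_false("b" %in% select_cases(cases, n7)$case_id)
  expect_identical(select_cases(cases, n7)$case_id, c("a", "c", "d", "e"))

  expect_error(selection_spec(nihssa = c(13, 6)), "lo <= hi")
  expect_error(selection_spec(nihssa = c(0, 50)), "within")
})

test_that("build_psm implements weighted accumulation with shared/unshared voxels", {
  sp <- tiny_space()
  u_only <- box_contour("c1", sp, c(1, 1, 1), c(3, 3, 2)) # covers u and v
  v_only <- box_contour("c2", sp, c(2, 2, 1), c(3, 3, 2)) # covers v
  cases <- rbind(
    case_record("c1", infarct_volume_cm3 = u_only$volume_cm3,
                mrs = c(NA, NA, 2, NA, NA)),
    case_record("c2", infarct_volume_cm3 = v_only$volume_cm3,
                mrs = c(NA, NA, 4, NA, NA))
  )
  psm <- build_psm(cases, list(c1 = u_only, c2 = v_only), "mRS90", 1,
                   space = sp)
  vals <- psm_values(psm)
  expect_identical(vals[3, 3, 2], 3) # both cases: mean(2, 4)
  expect_identical(vals[2, 2, 2], 2) # only case 1
  expect_true(is.na(vals[10, 10, 5])) # outside both
  expect_identical(psm$n_cases, 2L)
  # w1: weight map == count map
  expect_identical(psm$weight_map[psm$count_map > 0],
                   as.numeric(psm$count_map[psm$count_map > 0]))
})

test_that("single-case map is constant on its contour, undefined elsewhere", {
  sp <- tiny_space()
  cf <- box_contour("solo", sp, c(4, 4, 2), c(6, 6, 3))
  cases <- case_record("solo", infarct_volume_cm3 = cf$volume_cm3,
                       mrs = c(NA, NA, 5, NA, NA))
  psm <- build_psm(cases, list(solo = cf), "mRS90", 1, space = sp)
  vals <- psm_values(psm)
  expect_true(all(vals[cf$idx] == 5))
  expect_identical(sum(!is.na(vals)), cf$volume_voxels)
})

test_that("plain-averaging maps equal the brute-force per-voxel mean exactly", {
  sp <- tiny_space()
  for (seed in 1:6) {
    n <- sample(5:15, 1)
    mc <- micro_cohort(n, sp, seed = seed)
    psm <- build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp)
    oracle <- brute_mean_map(mc$cases, mc$contours, "mRS90", sp)
    expect_identical(psm_values(psm), oracle)
  }
})

test_that("map values stay within the contributing value range for every variant", {
  sp <- tiny_space()
  mc <- micro_cohort(10, sp, seed = 31)
  pc <- random_contour("pred", sp, 999)
  for (k in 1:8) {
    psm <- build_psm(mc$cases, mc$contours, "mRS90", k,
                     predicted_contour = pc, space = sp)
    vals <- psm_values(psm)
    ok <- !is.na(vals)
    if (!any(ok)) next
    expect_gte(min(vals[ok]), min(mc$p))
    expect_lte(max(vals[ok]), max(mc$p))
  }
})

test_that("all-range selection equals no selection; counts are conserved", {
  sp <- tiny_space()
  mc <- micro_cohort(8, sp, seed = 12)
  a <- build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp)
  b <- build_psm(mc$cases, mc$contours, "mRS90", 1,
                 selection = selection_all(), space = sp)
  expect_identical(a$sum_map, b$sum_map)
  expect_identical(sum(a$count_map),
                   sum(vapply(mc$contours, function(cf) cf$volume_voxels,
                              integer(1))))
})

test_that("missing parameter values and empty selections are handled", {
  sp <- tiny_space()
  mc <- micro_cohort(5, sp, seed = 44)
  mc$cases$mrs90[2] <- NA
  psm <- build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp)
  expect_identical(psm$n_cases, 4L)
  expect_false(mc$cases$case_id[2] %in% psm$case_ids)
  mc$cases$mrs90 <- NA
  expect_error(build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp),
               "no contributing cases")
})

test_that("a disjoint predicted contour yields zero weight everywhere for w3", {
  sp <- tiny_space()
  a <- box_contour("a", sp, c(1, 1, 1), c(4, 4, 3))
  cases <- case_record("a", infarct_volume_cm3 = a$volume_cm3,
                       mrs = c(NA, NA, 3, NA, NA))
  pred <- box_contour("p", sp, c(10, 10, 5), c(13, 13, 7))
  psm <- build_psm(cases, list(a = a), "mRS90", 3, predicted_contour = pred,
                   space = sp)
  expect_true(all(psm$weight_map == 0))
  expect_true(all(psm$count_map[a$idx] == 1L)) # contributors still counted
  res <- extract_distribution(psm, pred)
  expect_false(res$covered)
})

test_that("frequency map equals the w1 count map", {
  sp <- tiny_space()
  mc <- micro_cohort(9, sp, seed = 5)
  psm <- build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp)
  expect_identical(build_frequency_map(mc$contours, sp), psm$count_map)
  cf <- mc$contours[[1]]
  rep3 <- list(cf, cf, cf)
  f3 <- build_frequency_map(rep3, sp)
  expect_true(all(f3[cf$idx] == 3L))
  expect_identical(sum(f3), 3L * cf$volume_voxels)
})

test_that("merging split cohorts is bit-identical to the one-shot build", {
  # unit-volume voxels & power-of-two contour sizes keep w2 weights dyadic,
  # so all accumulator sums are exact in double arithmetic
  sp <- dyadic_space()
  ids <- sprintf("d%02d", 1:8)
  contours <- list()
  set.seed(77)
  for (i in 1:8) {
    nvox <- 2^sample(2:5, 1)
    contours[[ids[i]]] <- contour_file(ids[i],
                                       sample(prod(sp$dims), nvox), sp)
  }
  cases <- do.call(rbind, lapply(1:8, function(i)
    case_record(ids[i], infarct_volume_cm3 = contours[[ids[i]]]$volume_cm3,
                mrs = c(NA, NA, sample(0:6, 1), NA, NA))))
  for (k in 1:2) {
    whole <- build_psm(cases, contours, "mRS90", k, space = sp)
    first <- build_psm(cases[1:4, ], contours[1:4], "mRS90", k, space = sp)
    second <- build_psm(cases[5:8, ], contours[5:8], "mRS90", k, space = sp)
    merged <- merge_psm(first, second)
    expect_identical(merged$sum_map, whole$sum_map)
    expect_identical(merged$weight_map, whole$weight_map)
    expect_identical(merged$count_map, whole$count_map)
    expect_identical(merged$n_cases, whole$n_cases)
    # commutativity on accumulators
    swapped <- merge_psm(second, first)
    expect_identical(swapped$sum_map, merged$sum_map)
  }
})

test_that("merge contracts: empty identity, k >= 3 refusal, metadata checks", {
  sp <- dyadic_space()
  mc <- micro_cohort(4, sp, seed = 9)
  psm <- build_psm(mc$cases, mc$contours, "mRS90", 1, space = sp)
  merged <- merge_psm(psm, empty_psm("mRS90", 1, space = sp))
  expect_identical(merged$sum_map, psm$sum_map)
  expect_identical(merged$n_cases, psm$n_cases)

  pc <- random_contour("pred", sp, 1)
  p3 <- build_psm(mc$cases[1:2, ], mc$contours[1:2], "mRS90", 3,
                  predicted_contour = pc, space = sp)
  q3 <- build_psm(mc$cases[3:4, ], mc$contours[3:4], "mRS90", 3,
                  predicted_contour = pc, space = sp)
  expect_error(merge_psm(p3, q3), "pre-computable")
  expect_error(merge_psm(psm, psm), "disjoint")
  other_sel <- build_psm(mc$cases, mc$contours, "mRS90", 1,
                         selection = selection_spec(volume = c(0, 500)),
                         space = sp)
  expect_error(merge_psm(psm, other_sel), "metadata")
})
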