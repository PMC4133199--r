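# Synthetic cohorts with the statistical structure the atlas method
# assumes: outcomes depend on lesion location through a smooth spatial
# ground-truth field, plus noise.

#' Construct a ground-truth field from an explicit array
#'
#' Low-level constructor, mostly for tests; [make_field()] generates
#' random fields.
#'
#' @param parameter parameter name (fixes the admissible value range).
#' @param field numeric 3D array on the grid of `space`.
#' @param space a `psa_space`.
#' @param smoothness smoothness scale in mm (metadata).
#' @param seed generating seed (metadata).
#' @return object of class `ground_truth_field`.
#' @export
ground_truth_field <- function(parameter, field, space, smoothness = NA_real_,
                               seed = NA_integer_) {
  rng <- parameter_range(parameter)
  if (!identical(as.integer(dim(field)), space$dims))
    stop("ground_truth_field: field grid does not match space dims")
  if (min(field) < rng[1] || max(field) > rng[2])
    stop("ground_truth_field: values outside the parameter range")
  structure(list(parameter = parameter_column(parameter), field = field,
                 space = space, range = rng, smoothness = smoothness,
                 seed = seed),
            class = "ground_truth_field")
}

#' Generate a smooth random ground-truth field
#'
#' A band-limited random field: a mixture of random plane cosine waves
#' with wavelengths drawn from `[smoothness, 4 * smoothness]`, centered at
#' the parameter's reference-cohort mean (e.g. mRS90 at 2.04, BI90 at
#' 83.8) and clipped into the parameter's range, which bounds the values
#' by construction. As `smoothness` grows beyond the grid extent every
#' wave becomes constant over the grid, so the field tends to a constant.
#' An optional left/right asymmetry adds a hemispheric offset, mimicking
#' the lower stroke-scale scores seen with right-sided infarcts.
#'
#' @param parameter parameter name (mRS in \[0,6\], BI in \[0,100\],
#'   NIHSS in \[0,42\]).
#' @param space a `psa_space`.
#' @param smoothness correlation scale in mm (> 0); default 40 mm.
#' @param seed RNG seed; the field is deterministic given the seed.
#' @param n_waves number of cosine components.
#' @param asymmetry hemispheric offset as a fraction of the range
#'   (positive = higher values in the left half of the grid).
#' @return a `ground_truth_field`.
#' @export
make_field <- function(parameter, space, smoothness = 40, seed = 0L,
                       n_waves = 12L, asymmetry = 0) {
  stopifnot(is_psa_space(space), smoothness > 0)
  rng <- parameter_range(parameter)
  center <- parameter_center(parameter)
  spread <- diff(rng)
  dims <- space$dims
  coords <- voxel_centers_mm(idx_to_ijk(seq_len(prod(dims)), dims), space)
  raw <- numeric(prod(dims))
  with_seed(seed, {
    for (j in seq_len(n_waves)) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      lambda <- stats::runif(1, smoothness, 4 * smoothness)
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- stats::rnorm(1) / sqrt(n_waves)
      raw <- raw + amp * cos(2 * pi * (coords %*% dir) / lambda + phase)
    }
  })
  x_mid <- space$extent_mm[1] / 2
  f <- center + 0.45 * spread * raw +
    0.25 * spread * asymmetry * sign(x_mid - coords[, 1])
  f <- pmin(pmax(f, rng[1]), rng[2])
  ground_truth_field(parameter, array(f, dims), space, smoothness,
                     as.integer(seed))
}

#' Affine jitter parameters for the synthetic native frame
#'
#' The native scanner frame of a synthetic case is the atlas frame
#' perturbed by rotation, anisotropic scaling about the atlas AC, and
#' translation; the exact landmark images are emitted with the case, so
#' the landmark-fitted normalization inverts the perturbation exactly.
#'
#' @param rot_sd SD of the three rotation angles (radians).
#' @param scale_sd SD of log per-axis scale factors.
#' @param trans_sd SD of each translation component (mm).
#' @return list of class `jitter_params`; `jitter_params(0, 0, 0)` is the
#'   identity (native frame == atlas frame).
#' @export
jitter_params <- function(rot_sd = 0.04, scale_sd = 0.05, trans_sd = 4) {
  stopifnot(rot_sd >= 0, scale_sd >= 0, trans_sd >= 0)
  structure(list(rot_sd = rot_sd, scale_sd = scale_sd, trans_sd = trans_sd),
            class = "jitter_params")
}

#' @rdname jitter_params
#' @export
identity_jitter <- function() jitter_params(0, 0, 0)

rotation_matrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Per-outcome missing-value rates of the reference 128-case cohort
# (unavailable values / 128 at each follow-up day).
#' Default missingness rates per outcome parameter
#' @return named numeric vector of Bernoulli missingness rates.
#' @export
default_missingness <- function() {
  c(mrs7 = 2, mrs30 = 3, mrs90 = 6, mrs180 = 10, mrs360 = 12,
    bi30 = 9, bi90 = 17, bi180 = 25, bi360 = 29) / 128
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 100000 * 20011 + i * 7127 + 17) %%
               2147483647)
}

#' Sample one synthetic stroke case
#'
#' Draws a lesion as a voxelized random ellipsoid inside an ellipsoidal
#' brain region of the atlas grid, with volume drawn log-normally
#' (median 8 cm^3, upper tail reaching ~251 cm^3, truncated to
#' `volume_range`). The native frame is the atlas frame perturbed by a
#' random affine whose exact landmark images are emitted. Outcomes are
#' `clip(round(mean of the ground-truth field over the atlas-space mask
#' + N(0, sigma)))` (BI noise scaled by 100/6 so `sigma` is in mRS-grade
#' units); NIHSSa follows `clip(round(2.5 log(volume) + 3 + noise))` and
#' NIHSS7 `clip(round(0.85 NIHSSa + noise))`; outcomes are masked missing
#' at the configured rates.
#'
#' @param fields named list of `ground_truth_field`s (one per outcome).
#' @param space atlas `psa_space`.
#' @param seed per-case RNG seed.
#' @param case_id identifier.
#' @param sigma outcome noise SD in mRS grades (>= 0).
#' @param volume_meanlog,volume_sdlog,volume_range lognormal lesion-volume
#'   model (cm^3).
#' @param nihss_noise_sd SD of the NIHSS noise terms.
#' @param jitter a [jitter_params()].
#' @param missingness named missingness rates (see [default_missingness()]).
#' @param max_retries lesion-generation retries before failing.
#' @return list with `record` (one-row clinical data.frame),
#'   `native_contour`, `atlas_contour`, `landmarks`, `field_means`.
#' @export
sample_case <- function(fields, space, seed, case_id = "case",
                        sigma = 0.5,
                        volume_meanlog = log(8), volume_sdlog = 1.74,
                        volume_range = c(1, 251),
                        nihss_noise_sd = 3,
                        jitter = jitter_params(),
                        missingness = default_missingness(),
                        max_retries = 25L) {
  stopifnot(sigma >= 0)
  with_seed(seed, {
    ext <- space$extent_mm
    brain_c <- ext / 2
    brain_r <- 0.48 * ext
    atlas_idx <- NULL
    for (try in seq_len(max_retries)) {
      v_cm3 <- exp(stats::rnorm(1, volume_meanlog, volume_sdlog))
      if (v_cm3 < volume_range[1] || v_cm3 > volume_range[2]) next
      # infarcts cluster in vascular territories: centers are drawn
      # around a left or right MCA-like hotspot rather than uniformly
      side <- if (stats::runif(1) < 0.5) -1 else 1
      hotspot <- brain_c + c(side * 0.42, 0.05, 0.10) * brain_r
      center <- hotspot + stats::rnorm(3) * 0.16 * brain_r
      rel <- (center - brain_c) / brain_r
      if (sum(rel^2) > 0.8^2) # keep the center well inside the brain
        center <- brain_c + rel / sqrt(sum(rel^2)) * 0.8 * brain_r
      r0 <- (3 * v_cm3 * 1000 / (4 * pi))^(1 / 3)
      f <- exp(stats::rnorm(3, 0, 0.25))
      f <- f / prod(f)^(1 / 3)
      radii <- r0 * f
      lo <- pmax(floor((center - radii) / space$voxel_size) - 1, 0)
      hi <- pmin(ceiling((center + radii) / space$voxel_size) + 1,
                 space$dims - 1)
      if (any(lo > hi)) next
      cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
      cc <- voxel_centers_mm(cand, space)
      in_lesion <- rowSums(sweep(cc, 2, center, `-`)^2 %*%
                             diag(1 / radii^2)) <= 1
      in_brain <- rowSums(sweep(cc, 2, brain_c, `-`)^2 %*%
                            diag(1 / brain_r^2)) <= 1
      keep <- in_lesion & in_brain
      if (any(keep)) {
        atlas_idx <- ijk_to_idx(cand[keep, , drop = FALSE], space$dims)
        break
      }
    }
    if (is.null(atlas_idx))
      stop("sample_case: lesion generation failed after max retries")
    atlas_contour <- contour_file(case_id, atlas_idx, space, frame = "atlas")

    # native frame: affine perturbation about the atlas AC
    al <- default_atlas_landmarks(space)
    identity_T <- jitter$rot_sd == 0 && jitter$scale_sd == 0 &&
      jitter$trans_sd == 0
    Rj <- rotation_matrix(stats::rnorm(3, 0, jitter$rot_sd))
    sj <- exp(stats::rnorm(3, 0, jitter$scale_sd))
    tj <- stats::rnorm(3, 0, jitter$trans_sd)
    fwd <- function(x) { # atlas mm -> native mm
      x <- rbind_point(x)
      sweep(sweep(x, 2, al$AC, `-`) %*% diag(sj) %*% t(Rj), 2, al$AC + tj, `+`)
    }
    lms <- landmark_set(AC = fwd(al$AC), PC = fwd(al$PC), L = fwd(al$L),
                        R = fwd(al$R), A = fwd(al$A), P = fwd(al$P),
                        S = fwd(al$S), I = fwd(al$I),
                        msp_normal = as.numeric(Rj %*% c(1, 0, 0)))
    if (identity_T) {
      native_contour <- contour_file(case_id, atlas_idx, space,
                                     frame = "native")
    } else {
      # native mask: forward image of the atlas mask on the native grid
      aijk <- idx_to_ijk(atlas_idx, space$dims)
      lo <- apply(aijk, 2, min); hi <- apply(aijk, 2, max) + 1L
      corners <- as.matrix(expand.grid(c(lo[1], hi[1]) * space$voxel_size[1],
                                       c(lo[2], hi[2]) * space$voxel_size[2],
                                       c(lo[3], hi[3]) * space$voxel_size[3]))
      nmm <- fwd(corners)
      vlo <- pmax(floor(apply(nmm, 2, min) / space$voxel_size) - 1, 0)
      vhi <- pmin(ceiling(apply(nmm, 2, max) / space$voxel_size) + 1,
                  space$dims - 1)
      cand <- as.matrix(expand.grid(vlo[1]:vhi[1], vlo[2]:vhi[2],
                                    vlo[3]:vhi[3]))
      centers <- voxel_centers_mm(cand, space)
      back <- sweep(sweep(centers, 2, al$AC + tj, `-`) %*% Rj %*%
                      diag(1 / sj), 2, al$AC, `+`)
      bijk <- mm_to_voxel(back, space)
      inside <- bijk[, 1] >= 0 & bijk[, 1] < space$dims[1] &
        bijk[, 2] >= 0 & bijk[, 2] < space$dims[2] &
        bijk[, 3] >= 0 & bijk[, 3] < space$dims[3]
      hitv <- logical(nrow(cand))
      if (any(inside))
        hitv[inside] <- ijk_to_idx(bijk[inside, , drop = FALSE],
                                   space$dims) %in% atlas_idx
      if (!any(hitv))
        stop("sample_case: native lesion fell outside the native grid")
      native_contour <- contour_file(case_id,
                                     ijk_to_idx(cand[hitv, , drop = FALSE],
                                                space$dims),
                                     space, frame = "native")
    }

    vol <- native_contour$volume_cm3
    nihssa <- clip_round(2.5 * log(vol) + 3 +
                           stats::rnorm(1, 0, nihss_noise_sd), 0, 42)
    nihss7 <- clip_round(0.85 * nihssa +
                           stats::rnorm(1, 0, nihss_noise_sd * 2 / 3), 0, 42)
    field_means <- vapply(fields, function(g) mean(g$field[atlas_idx]),
                          numeric(1))
    names(field_means) <- vapply(fields, function(g) g$parameter, character(1))
    outcome <- function(col, lo, hi, noise_sd) {
      if (!col %in% names(field_means)) return(NA_real_)
      val <- clip_round(field_means[[col]] + stats::rnorm(1, 0, noise_sd),
                        lo, hi)
      rate <- if (col %in% names(missingness)) missingness[[col]] else 0
      if (stats::runif(1) < rate) NA_real_ else val
    }
    mrs <- vapply(MRS_DAYS, function(d)
      outcome(paste0("mrs", d), 0, 6, sigma), numeric(1))
    bi <- vapply(BI_DAYS, function(d)
      outcome(paste0("bi", d), 0, 100, sigma * 100 / 6), numeric(1))
    record <- case_record(case_id, nihssa = nihssa, nihss7 = nihss7,
                          infarct_volume_cm3 = vol, mrs = mrs, bi = bi)
    list(record = record, native_contour = native_contour,
         atlas_contour = atlas_contour, landmarks = lms,
         field_means = field_means)
  })
}

clip_round <- function(x, lo, hi) min(max(round(x), lo), hi)

#' Generate a full synthetic cohort
#'
#' `n` independent cases drawn against one set of per-parameter
#' ground-truth fields; all randomness flows from the master seed through
#' a per-case counter. With `out_dir` set, the on-disk layout the CLI
#' consumes is written: native masks (NIfTI-1), per-case landmark JSON,
#' the clinical CSV, a space/config JSON and the ground-truth bundle.
#'
#' @param n number of cases (>= 0).
#' @param seed master seed.
#' @param space atlas `psa_space`; default the reduced 64 x 64 x 16 grid.
#' @param sigma outcome noise SD (mRS grades).
#' @param parameters outcome parameters to generate fields for.
#' @param smoothness field smoothness (mm).
#' @param asymmetry hemispheric field asymmetry.
#' @param jitter a [jitter_params()].
#' @param missingness named missingness rates.
#' @param out_dir optional output directory.
#' @param ... further arguments passed to [sample_case()].
#' @return list with `cases` (clinical data.frame), `contours_native`,
#'   `contours_atlas`, `landmarks` (named lists), `fields`, `space`.
#' @export
make_cohort <- function(n, seed = 0L, space = reduced_space(), sigma = 0.5,
                        parameters = outcome_parameters(), smoothness = 40,
                        asymmetry = 0, jitter = jitter_params(),
                        missingness = default_missingness(),
                        out_dir = NULL, ...) {
  stopifnot(n >= 0)
  fields <- lapply(seq_along(parameters), function(j)
    make_field(parameters[j], space, smoothness = smoothness,
               seed = derive_seed(seed, j), asymmetry = asymmetry))
  names(fields) <- vapply(fields, function(g) g$parameter, character(1))
  cases_list <- vector("list", n)
  contours_native <- contours_atlas <- landmarks <- vector("list", n)
  ids <- if (n > 0) sprintf("case%03d", seq_len(n)) else character(0)
  for (i in seq_len(n)) {
    sc <- sample_case(fields, space, seed = derive_seed(seed, 1000 + i),
                      case_id = ids[i], sigma = sigma, jitter = jitter,
                      missingness = missingness, ...)
    cases_list[[i]] <- sc$record
    contours_native[[i]] <- sc$native_contour
    contours_atlas[[i]] <- sc$atlas_contour
    landmarks[[i]] <- sc$landmarks
  }
  names(contours_native) <- names(contours_atlas) <- names(landmarks) <- ids
  cases <- if (n > 0) do.call(rbind, cases_list) else
    case_record("x")[0, , drop = FALSE]
  cohort <- list(cases = cases, contours_native = contours_native,
                 contours_atlas = contours_atlas, landmarks = landmarks,
                 fields = fields, space = space, sigma = sigma, seed = seed)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to the on-disk layout the CLI consumes
#' @param cohort list as returned by [make_cohort()].
#' @param out_dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "landmarks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  write_clinical_table(cohort$cases, file.path(out_dir, "clinical.csv"))
  write_space_json(cohort$space, file.path(out_dir, "space.json"))
  for (id in names(cohort$contours_native)) {
    write_mask(cohort$contours_native[[id]],
               file.path(out_dir, "masks", paste0(id, "_mask.nii")))
    write_landmarks(cohort$landmarks[[id]],
                    file.path(out_dir, "landmarks", paste0(id, ".json")))
  }
  for (g in cohort$fields)
    write_nifti(g$field, cohort$space,
                file.path(out_dir, "truth", paste0(g$parameter, "_field.nii")),
                datatype = "float32")
  jsonlite::write_json(
    list(seed = cohort$seed, sigma = cohort$sigma,
         n = nrow(cohort$cases),
         parameters = vapply(cohort$fields, function(g) g$parameter,
                             character(1))),
    file.path(out_dir, "truth", "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
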