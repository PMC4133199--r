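# Shared fixtures: tiny grids, box/blob masks, landmark builders and the
# independent brute-force map oracle. Everything is generated in code.

tiny_space <- function(dims = c(16L, 16L, 8L), voxel = c(1, 1, 2)) {
  atlas_space(dims, voxel)
}

# unit-volume voxels make volumes (and 1/v weights for power-of-two
# counts) exactly representable
dyadic_space <- function(dims = c(10L, 10L, 10L)) {
  atlas_space(dims, c(10, 10, 10))
}

# axis-aligned box of voxels, 0-based inclusive index ranges
box_contour <- function(id, space, lo, hi, frame = "atlas") {
  ijk <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  contour_file(id, ijk_to_idx_test(ijk, space$dims), space, frame = frame)
}

ijk_to_idx_test <- function(ijk, dims) {
  as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1)
}

# random connected-ish blob: a random box plus random extra voxels
random_contour <- function(id, space, seed) {
  set.seed(seed)
  d <- space$dims
  lo <- c(sample(0:(d[1] - 3), 1), sample(0:(d[2] - 3), 1),
          sample(0:(d[3] - 2), 1))
  hi <- pmin(lo + c(sample(1:4, 1), sample(1:4, 1), sample(0:2, 1)), d - 1)
  cf <- box_contour(id, space, lo, hi)
  extra <- sample(prod(d), 5)
  contour_file(id, sort(unique(c(cf$idx, extra))), space, frame = "atlas")
}

# micro cohort with integer mRS-like parameter values (exact arithmetic)
micro_cohort <- function(n, space, seed, p_values = NULL) {
  set.seed(seed)
  ids <- sprintf("m%02d", seq_len(n))
  contours <- lapply(seq_len(n), function(i)
    random_contour(ids[i], space, seed * 1000 + i))
  names(contours) <- ids
  if (is.null(p_values)) p_values <- sample(0:6, n, replace = TRUE)
  cases <- do.call(rbind, lapply(seq_len(n), function(i)
    case_record(ids[i], nihssa = sample(0:42, 1), nihss7 = sample(0:42, 1),
                infarct_volume_cm3 = contours[[i]]$volume_cm3,
                mrs = c(NA, NA, p_values[i], NA, NA))))
  list(cases = cases, contours = contours, p = p_values)
}

# independent per-voxel brute-force oracle for the plain-averaging map:
# loops voxels x cases through a dense membership matrix, no shared code
# with build_psm's accumulator path
brute_mean_map <- function(cases, contours, parameter, space) {
  nvox <- prod(space$dims)
  col <- parameter_column(parameter)
  vals <- matrix(NA_real_, nrow = nvox, ncol = nrow(cases))
  for (i in seq_len(nrow(cases))) {
    p <- cases[[col]][i]
    if (is.na(p)) next
    vals[contours[[cases$case_id[i]]]$idx, i] <- p
  }
  out <- rowMeans(vals, na.rm = TRUE)
  out[!rowSums(!is.na(vals))] <- NA_real_
  array(out, space$dims)
}

# native landmark set produced by applying an affine (native = A x + b,
# atlas mm coordinates x) to the default atlas landmark positions
affine_landmarks <- function(space, A = diag(3), b = c(0, 0, 0)) {
  al <- default_atlas_landmarks(space)
  f <- function(p) as.numeric(A %*% p + b)
  landmark_set(AC = f(al$AC), PC = f(al$PC), L = f(al$L), R = f(al$R),
               A = f(al$A), P = f(al$P), S = f(al$S), I = f(al$I),
               msp_normal = as.numeric(A %*% c(1, 0, 0)))
}

# brute-force AUC: pairwise concordance count with ties worth 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

zero_missing <- function() {
  r <- default_missingness()
  r[] <- 0
  r
}
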