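#' Contour file: one patient's binary lesion mask
#'
#' A "contour file" is the complete delineation of one ischemic lesion as a
#' binary mask on a known grid, tagged with the case it belongs to and
#' whether it lives in the native scanner frame or the atlas frame.
#'
#' @param case_id identifier (scalar character or coercible).
#' @param mask logical/0-1 3D array, or an integer vector of 1-based linear
#'   foreground indices (then `dims` is taken from `space`).
#' @param space the `psa_space` the mask lives on.
#' @param frame `"native"` or `"atlas"`.
#' @return An object of class `contour_file` with fields `case_id`, `idx`
#'   (sorted 1-based linear foreground indices), `space`, `frame`,
#'   `volume_voxels` and `volume_cm3`.
#' @export
contour_file <- function(case_id, mask, space, frame = c("atlas", "native")) {
  frame <- match.arg(frame)
  stopifnot(is_psa_space(space))
  if (is.array(mask)) {
    if (!identical(as.integer(dim(mask)), space$dims))
      stop("contour_file: mask grid does not match space dims")
    idx <- which(mask != 0)
  } else {
    idx <- as.integer(mask)
    if (length(idx) && (min(idx) < 1L || max(idx) > prod(space$dims)))
      stop("contour_file: foreground index outside grid")
  }
  if (length(idx) == 0L)
    stop("contour_file: mask is empty (no foreground voxel)")
  idx <- sort(unique(as.integer(idx)))
  structure(
    list(
      case_id = as.character(case_id),
      idx = idx,
      space = space,
      frame = frame,
      volume_voxels = length(idx),
      volume_cm3 = length(idx) * space$voxel_volume_mm3 / 1000
    ),
    class = "contour_file"
  )
}

#' @export
print.contour_file <- function(x, ...) {
  cat(sprintf("<contour_file> case %s [%s]: %d voxels, %.4g cm^3\n",
              x$case_id, x$frame, x$volume_voxels, x$volume_cm3))
  invisible(x)
}

is_contour_file <- function(x) inherits(x, "contour_file")

#' Expand a contour file into a full logical array
#' @param x a `contour_file`.
#' @return logical 3D array on the contour's grid.
#' @export
as_mask_array <- function(x) {
  stopifnot(is_contour_file(x))
  m <- array(FALSE, dim = x$space$dims)
  m[x$idx] <- TRUE
  m
}

mask_indices <- function(mask, space) {
  if (is_contour_file(mask)) {
    if (!spaces_equal(mask$space, space))
      stop("mask grid does not match space dims")
    return(mask$idx)
  }
  if (!identical(as.integer(dim(mask)), space$dims))
    stop("mask grid does not match space dims")
  which(mask != 0)
}

#' Mask volume in cubic centimeters
#'
#' Foreground voxel count times the voxel volume. All volumes in the package
#' are voxel-count based; no partial-volume geometry.
#'
#' @param mask logical/0-1 3D array or `contour_file`.
#' @param space a `psa_space` whose dims must match the mask grid.
#' @return volume in cm^3 (0 for an all-background array).
#' @export
mask_volume_cm3 <- function(mask, space) {
  length(mask_indices(mask, space)) * space$voxel_volume_mm3 / 1000
}

#' Overlap volume of two masks
#'
#' Volume (cm^3) of the voxel-wise AND of two masks on the same grid.
#' Symmetric; bounded by the smaller of the two volumes.
#'
#' @inheritParams mask_volume_cm3
#' @param a,b masks (arrays or `contour_file`s) on the same grid.
#' @export
overlap_volume <- function(a, b, space) {
  ia <- mask_indices(a, space)
  ib <- mask_indices(b, space)
  length(intersect_sorted(ia, ib)) * space$voxel_volume_mm3 / 1000
}

# fast intersection of two sorted integer vectors
intersect_sorted <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  a[match(a, b, nomatch = 0L) > 0L]
}

#' Centroid of a mask, in mm
#'
#' Unweighted mean of foreground voxel centers, in mm from the grid corner.
#'
#' @inheritParams mask_volume_cm3
#' @return numeric length-3 (mm).
#' @export
mask_centroid_mm <- function(mask, space) {
  idx <- mask_indices(mask, space)
  if (length(idx) == 0L) stop("mask_centroid_mm: empty mask")
  colMeans(voxel_centers_mm(idx_to_ijk(idx, space$dims), space))
}

#' Euclidean distance between mask centroids, in mm
#'
#' @inheritParams overlap_volume
#' @export
centroid_distance <- function(a, b, space) {
  sqrt(sum((mask_centroid_mm(a, space) - mask_centroid_mm(b, space))^2))
}
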