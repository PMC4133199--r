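#' Atlas coordinate space
#'
#' The stereotactic (Talairach) grid into which all lesions are normalized
#' and on which all population maps live. The default is the classic
#' 512 x 512 x 64 grid at 0.320119 x 0.320119 x 2 mm resolution.
#'
#' Conventions (documented, fixed): voxel indices are 0-based; voxel `(i,j,k)`
#' occupies the axis-aligned box `[i*vx, (i+1)*vx) x ...` in mm measured from
#' the grid corner, so its center sits at `((i+0.5)*vx, (j+0.5)*vy, (k+0.5)*vz)`.
#' Axes: x runs left-to-right, y posterior-to-anterior, z inferior-to-superior.
#'
#' @param dims integer length-3, grid size in voxels.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `psa_space`.
#' @examples
#' sp <- atlas_space()
#' sp$voxel_volume_mm3
#' @export
atlas_space <- function(dims = c(512L, 512L, 64L),
                        voxel_size = c(0.320119, 0.320119, 2.0)) {
  dims <- as.integer(dims)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(dims) == 3, length(voxel_size) == 3)
  if (any(dims <= 0L)) stop("atlas_space: all dims must be > 0")
  if (any(voxel_size <= 0)) stop("atlas_space: all voxel sizes must be > 0")
  structure(
    list(
      dims = dims,
      voxel_size = voxel_size,
      voxel_volume_mm3 = prod(voxel_size),
      extent_mm = dims * voxel_size
    ),
    class = "psa_space"
  )
}

#' Reduced grid used for simulations and tests
#'
#' A 64 x 64 x 16 grid covering the same physical field of view as the full
#' atlas grid (in-plane voxels 8x coarser, 8 mm slices). The full-resolution
#' grid remains available through [atlas_space()].
#'
#' @return A `psa_space`.
#' @export
reduced_space <- function() {
  atlas_space(dims = c(64L, 64L, 16L),
              voxel_size = c(0.320119 * 8, 0.320119 * 8, 8.0))
}

#' @export
print.psa_space <- function(x, ...) {
  cat(sprintf("<psa_space> %d x %d x %d voxels @ %.6g x %.6g x %.6g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

is_psa_space <- function(x) inherits(x, "psa_space")

spaces_equal <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

# 0-based voxel index triples -> voxel-center mm coordinates (n x 3 matrices)
voxel_centers_mm <- function(ijk, space) {
  sweep(ijk + 0.5, 2, space$voxel_size, `*`)
}

# mm coordinates -> 0-based containing-voxel indices (may fall outside grid)
mm_to_voxel <- function(xyz, space) {
  floor(sweep(xyz, 2, space$voxel_size, `/`))
}

# linear (1-based, R array order) index <-> 0-based ijk triples
idx_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i, j, k)
}

ijk_to_idx <- function(ijk, dims) {
  as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1)
}
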