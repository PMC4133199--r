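#' Talairach landmark set for one case
#'
#' The modified-Talairach landmark points of a native scan, in mm in the
#' native scanner frame: the anterior and posterior commissures (AC, PC),
#' the six cortical extremes (L, R, A, P, S, I) and the unit normal of the
#' midsagittal plane (MSP). Automatic landmark/MSP detection is out of
#' scope: landmarks are inputs, typically read from a per-case JSON file
#' (see [read_landmarks()]).
#'
#' @param AC,PC,L,R,A,P,S,I numeric length-3 points (mm, native frame).
#' @param msp_normal numeric length-3; normalized internally.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(AC, PC, L, R, A, P, S, I, msp_normal) {
  pts <- list(AC = AC, PC = PC, L = L, R = R, A = A, P = P, S = S, I = I)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3 || any(!is.finite(p)))
      stop(sprintf("landmark_set: %s must be a finite length-3 point", nm))
    pts[[nm]] <- p
  }
  n <- as.numeric(msp_normal)
  if (length(n) != 3 || sum(n^2) < 1e-12)
    stop("landmark_set: msp_normal must be a nonzero length-3 vector")
  pts$msp_normal <- n / sqrt(sum(n^2))
  if (sqrt(sum((pts$AC - pts$PC)^2)) < 1e-6)
    stop("landmark_set: AC and PC coincide")
  structure(pts, class = "landmark_set")
}

#' Default atlas-side landmark coordinates
#'
#' Where the Talairach landmarks sit in the atlas grid, in mm from the grid
#' corner. These are package conventions (fractions of the grid extent with
#' AC on the grid midline), not values from any dataset; override them via
#' the `atlas_landmarks` argument of [fit_transform()] or the config file.
#'
#' @param space a `psa_space`.
#' @return named list of length-3 mm points (AC, PC, L, R, A, P, S, I).
#' @export
default_atlas_landmarks <- function(space) {
  e <- space$extent_mm
  list(
    AC = c(0.500, 0.590, 0.550) * e,
    PC = c(0.500, 0.440, 0.550) * e,
    L  = c(0.085, 0.590, 0.550) * e,
    R  = c(0.915, 0.590, 0.550) * e,
    A  = c(0.500, 0.960, 0.550) * e,
    P  = c(0.500, 0.050, 0.550) * e,
    S  = c(0.500, 0.590, 0.950) * e,
    I  = c(0.500, 0.590, 0.150) * e
  )
}

# monotone piecewise-linear map defined by matching knot sequences;
# linear extrapolation beyond the end knots
piecewise_map <- function(v, from_knots, to_knots) {
  seg <- findInterval(v, from_knots, all.inside = TRUE)
  slope <- diff(to_knots) / diff(from_knots)
  to_knots[seg] + (v - from_knots[seg]) * slope[seg]
}

#' Fit the piecewise-affine Talairach transform from landmarks
#'
#' Builds the classic 12-subvolume proportional-grid transform: an
#' orthonormal frame is anchored at AC (x along the MSP normal toward R,
#' y along PC->AC, z completing a right-handed frame), and each axis is
#' mapped by a monotone piecewise-linear stretch that carries the native
#' landmarks onto their configured atlas counterparts (2 x-segments x
#' 3 y-segments x 2 z-segments = 12 affine blocks, continuous across
#' shared boundary planes by construction).
#'
#' @param landmarks a [landmark_set()].
#' @param space target `psa_space`.
#' @param atlas_landmarks atlas-side landmark positions (mm from grid
#'   corner); defaults to [default_atlas_landmarks()].
#' @return An object of class `talairach_transform`.
#' @export
fit_transform <- function(landmarks, space,
                          atlas_landmarks = default_atlas_landmarks(space)) {
  stopifnot(inherits(landmarks, "landmark_set"), is_psa_space(space))
  lm <- landmarks
  ey <- lm$AC - lm$PC
  ey <- ey / sqrt(sum(ey^2))
  ex <- lm$msp_normal - sum(lm$msp_normal * ey) * ey
  if (sum(ex^2) < 1e-8)
    stop("fit_transform: msp_normal is (near-)parallel to the AC-PC axis")
  ex <- ex / sqrt(sum(ex^2))
  if (sum((lm$R - lm$AC) * ex) < 0) ex <- -ex
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  Rm <- cbind(ex, ey, ez) # columns: canonical axes in native coords
  u <- function(p) as.numeric(crossprod(Rm, p - lm$AC))
  uL <- u(lm$L); uR <- u(lm$R); uA <- u(lm$A); uP <- u(lm$P)
  uS <- u(lm$S); uI <- u(lm$I); uPC <- u(lm$PC)
  if (!(uL[1] < 0 && uR[1] > 0))
    stop("fit_transform: L and R must lie on opposite sides of the MSP")
  if (!(uA[2] > 0))
    stop("fit_transform: A must be anterior to AC along the AC-PC axis")
  if (!(uP[2] < uPC[2]))
    stop("fit_transform: P must be posterior to PC along the AC-PC axis")
  if (!(uS[3] > 0 && uI[3] < 0))
    stop("fit_transform: S/I must lie above/below the AC-PC plane")
  al <- atlas_landmarks
  knots <- list(
    x = list(native = c(uL[1], 0, uR[1]),
             atlas = c(al$L[1], al$AC[1], al$R[1])),
    y = list(native = c(uP[2], uPC[2], 0, uA[2]),
             atlas = c(al$P[2], al$PC[2], al$AC[2], al$A[2])),
    z = list(native = c(uI[3], 0, uS[3]),
             atlas = c(al$I[3], al$AC[3], al$S[3]))
  )
  for (ax in names(knots)) {
    for (side in c("native", "atlas")) {
      if (any(diff(knots[[ax]][[side]]) <= 0))
        stop(sprintf("fit_transform: degenerate %s knots on axis %s", side, ax))
    }
  }
  structure(list(Rm = Rm, AC = lm$AC, knots = knots, space = space,
                 atlas_landmarks = al),
            class = "talairach_transform")
}

#' Map native-frame points to atlas mm coordinates
#' @param transform a `talairach_transform`.
#' @param xyz n x 3 matrix (or length-3 vector) of native mm points.
#' @return n x 3 matrix of atlas mm coordinates (from the grid corner).
#' @export
transform_points <- function(transform, xyz) {
  xyz <- rbind_point(xyz)
  u <- sweep(xyz, 2, transform$AC, `-`) %*% transform$Rm
  k <- transform$knots
  cbind(piecewise_map(u[, 1], k$x$native, k$x$atlas),
        piecewise_map(u[, 2], k$y$native, k$y$atlas),
        piecewise_map(u[, 3], k$z$native, k$z$atlas))
}

#' Map atlas mm coordinates back to the native frame
#' @inheritParams transform_points
#' @param xyz n x 3 matrix of atlas mm coordinates.
#' @export
inverse_transform_points <- function(transform, xyz) {
  xyz <- rbind_point(xyz)
  k <- transform$knots
  u <- cbind(piecewise_map(xyz[, 1], k$x$atlas, k$x$native),
             piecewise_map(xyz[, 2], k$y$atlas, k$y$native),
             piecewise_map(xyz[, 3], k$z$atlas, k$z$native))
  sweep(u %*% t(transform$Rm), 2, transform$AC, `+`)
}

rbind_point <- function(xyz) {
  if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
}

#' Determinants of the 12 affine blocks
#'
#' One determinant per (x-segment, y-segment, z-segment) cell of the
#' proportional grid; the rotation contributes determinant 1, so each value
#' is the product of the three axis scale factors of that block.
#'
#' @param transform a `talairach_transform`.
#' @return numeric array of dim c(2, 3, 2) (x-, y-, z-segment).
#' @export
block_determinants <- function(transform) {
  k <- transform$knots
  sx <- diff(k$x$atlas) / diff(k$x$native)
  sy <- diff(k$y$atlas) / diff(k$y$native)
  sz <- diff(k$z$atlas) / diff(k$z$native)
  outer(outer(sx, sy), sz)
}

#' Normalize a native-space contour file into the atlas grid
#'
#' Pull-back resampling with nearest-neighbor semantics: an atlas voxel is
#' foreground iff its center, mapped through the inverse transform, falls
#' inside the native binary mask. This guarantees a hole-free atlas mask
#' and matches binary-mask semantics.
#'
#' @param contour a native-frame `contour_file` (its `space` describes the
#'   native grid).
#' @param transform `talairach_transform` fitted from the case's landmarks.
#' @param space target atlas `psa_space`.
#' @return an atlas-frame `contour_file`.
#' @export
normalize_contour <- function(contour, transform, space) {
  stopifnot(is_contour_file(contour), inherits(transform, "talairach_transform"))
  if (contour$frame != "native")
    stop("normalize_contour: contour is not in the native frame")
  nspace <- contour$space
  ijk <- idx_to_ijk(contour$idx, nspace$dims)
  lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max) + 1L
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  corners_mm <- sweep(corners, 2, nspace$voxel_size, `*`)
  # the per-axis maps are monotone, so the atlas image of the native
  # bounding box is contained in the box spanned by the corner images
  amm <- transform_points(transform, corners_mm)
  vlo <- pmax(floor(apply(amm, 2, min) / space$voxel_size) - 1, 0)
  vhi <- pmin(ceiling(apply(amm, 2, max) / space$voxel_size) + 1,
              space$dims - 1)
  if (any(vlo > vhi))
    stop("normalize_contour: lesion maps entirely outside the atlas grid")
  cand <- as.matrix(expand.grid(vlo[1]:vhi[1], vlo[2]:vhi[2], vlo[3]:vhi[3]))
  centers <- voxel_centers_mm(cand, space)
  native_mm <- inverse_transform_points(transform, centers)
  nijk <- mm_to_voxel(native_mm, nspace)
  inside <- nijk[, 1] >= 0 & nijk[, 1] < nspace$dims[1] &
    nijk[, 2] >= 0 & nijk[, 2] < nspace$dims[2] &
    nijk[, 3] >= 0 & nijk[, 3] < nspace$dims[3]
  hit <- logical(nrow(cand))
  if (any(inside)) {
    nidx <- ijk_to_idx(nijk[inside, , drop = FALSE], nspace$dims)
    hit[inside] <- nidx %in% contour$idx
  }
  if (!any(hit))
    stop(paste("normalize_contour: normalized mask is empty",
               "(lesion outside the grid or below atlas resolution)"))
  contour_file(contour$case_id,
               ijk_to_idx(cand[hit, , drop = FALSE], space$dims),
               space, frame = "atlas")
}
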