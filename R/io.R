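# JSON sidecars: landmarks, space, stroke-map bundles, config.

#' Write a landmark set to JSON
#' @param landmarks a `landmark_set`.
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' Expected keys: `AC, PC, L, R, A, P, S, I` (length-3 mm points, native
#' frame) and `msp_normal`.
#' @param path JSON path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("AC", "PC", "L", "R", "A", "P", "S", "I", "msp_normal")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop(sprintf("read_landmarks: %s missing key(s): %s", path,
                 paste(miss, collapse = ", ")))
  landmark_set(j$AC, j$PC, j$L, j$R, j$A, j$P, j$S, j$I, j$msp_normal)
}

write_space_json <- function(space, path) {
  jsonlite::write_json(list(dims = space$dims,
                            voxel_size = space$voxel_size),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

read_space_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas_space(j$dims, j$voxel_size)
}

#' Persist a stroke map as a NIfTI bundle
#'
#' Writes `sum.nii` and `weight.nii` (float64, so the accumulators
#' round-trip exactly and merged maps stay exact), `count.nii` (int32)
#' and a `meta.json` sidecar (parameter, weight id, selection, case ids,
#' space) into a directory.
#'
#' @param psm a `stroke_map`.
#' @param dir output directory (created if needed).
#' @export
write_psm <- function(psm, dir) {
  stopifnot(inherits(psm, "stroke_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(psm$sum_map, psm$space, file.path(dir, "sum.nii"), "float64")
  write_nifti(psm$weight_map, psm$space, file.path(dir, "weight.nii"),
              "float64")
  write_nifti(psm$count_map, psm$space, file.path(dir, "count.nii"), "int32")
  sel <- psm$selection
  jsonlite::write_json(
    list(parameter = psm$parameter, weight_id = psm$weight_id,
         n_cases = psm$n_cases, case_ids = psm$case_ids,
         selection = list(volume = unname(sel$volume),
                          nihssa = unname(sel$nihssa),
                          nihss7 = unname(sel$nihss7)),
         dims = psm$space$dims, voxel_size = psm$space$voxel_size),
    file.path(dir, "meta.json"), auto_unbox = FALSE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a stroke map bundle written by [write_psm()]
#' @param dir bundle directory.
#' @return a `stroke_map`.
#' @export
read_psm <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  space <- atlas_space(meta$dims, meta$voxel_size)
  vol <- function(name, int = FALSE) {
    nii <- read_nifti(file.path(dir, name))
    if (!identical(nii$dims, space$dims))
      stop(sprintf("read_psm: %s dims do not match the meta.json space", name))
    if (int) array(as.integer(nii$data), space$dims) else nii$data
  }
  sel <- selection_spec(volume = unlist(meta$selection$volume),
                        nihssa = unlist(meta$selection$nihssa),
                        nihss7 = unlist(meta$selection$nihss7))
  new_stroke_map(meta$parameter, meta$weight_id,
                 vol("sum.nii"), vol("weight.nii"), vol("count.nii", int = TRUE),
                 meta$n_cases, unlist(meta$case_ids), sel, space)
}

#' Read a run configuration (JSON)
#'
#' Recognized keys (all optional): `dims`, `voxel_size`,
#' `atlas_landmarks` (named list of mm points), `grid` (lists `weights`,
#' `volume`, `nihssa`, `nihss7`), `seed`, `sigma`, `min_count`. CLI flags
#' override config values.
#'
#' @param path JSON path, or NULL for all defaults.
#' @return config list with defaults filled in.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$dims)) cfg$dims <- reduced_space()$dims
  if (is.null(cfg$voxel_size)) cfg$voxel_size <- reduced_space()$voxel_size
  cfg$space <- atlas_space(cfg$dims, cfg$voxel_size)
  if (is.null(cfg$seed)) cfg$seed <- 0L
  if (is.null(cfg$sigma)) cfg$sigma <- 0.5
  if (is.null(cfg$min_count)) cfg$min_count <- 0L
  if (is.null(cfg$grid)) cfg$grid <- default_grid_factors()
  cfg
}
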