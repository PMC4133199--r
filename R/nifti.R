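# Minimal NIfTI-1 I/O (single-file uncompressed .nii). Supports the
# datatypes this package emits: uint8 masks, int32 counts, float32/float64
# maps. The sform carries the grid frame: index (i,j,k) -> mm coordinates
# (i + 0.5) * voxel_size from the grid corner, matching the package's
# voxel-center convention.

NIFTI_DTYPES <- list(
  uint8 = list(code = 2L, bitpix = 8L),
  int16 = list(code = 4L, bitpix = 16L),
  int32 = list(code = 8L, bitpix = 32L),
  float32 = list(code = 16L, bitpix = 32L),
  float64 = list(code = 64L, bitpix = 64L)
)

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param data numeric/integer/logical 3D array.
#' @param space `psa_space` providing voxel sizes (dims must match).
#' @param path output `.nii` path.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @export
write_nifti <- function(data, space, path,
                        datatype = c("float32", "float64", "uint8",
                                     "int16", "int32")) {
  datatype <- match.arg(datatype)
  stopifnot(is_psa_space(space))
  if (!identical(as.integer(dim(data)), space$dims))
    stop("write_nifti: data grid does not match space dims")
  dt <- NIFTI_DTYPES[[datatype]]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4) writeBin(as.numeric(x), con, size = size,
                                       endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr
  wraw(10 + 18)                                 # data_type, db_name
  wi(0L, 4); wi(0L, 2)                          # extents, session_error
  writeBin(charToRaw("r"), con); wraw(1)        # regular, dim_info
  wi(c(3L, space$dims, 1L, 1L, 1L, 1L), 2)      # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, space$voxel_size, 1, 1, 1, 1))        # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); wraw(2)                            # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw("strokeatlas")
  writeBin(c(desc, raw(80 - length(desc))), con) # descrip
  wraw(24)                                      # aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code, sform_code=1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))                # quatern, qoffset
  vs <- space$voxel_size
  wf(c(vs[1], 0, 0, 0.5 * vs[1]))               # srow_x
  wf(c(0, vs[2], 0, 0.5 * vs[2]))               # srow_y
  wf(c(0, 0, vs[3], 0.5 * vs[3]))               # srow_z
  wraw(16)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  wraw(4)                                       # extension flag
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(data), con, size = dt$bitpix / 8, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = dt$bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` path (uncompressed, single-file).
#' @return list with `data` (array), `dims`, `voxel_size`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop("read_nifti: not a NIfTI-1 file (bad sizeof_hdr)")
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dim8[1]
  if (ndim < 3) stop("read_nifti: expected a 3D volume")
  dims <- dim8[2:4]
  if (ndim > 3 && any(dim8[5:(1 + ndim)] > 1))
    stop("read_nifti: expected a single 3D volume")
  seek(con, 70)
  dtcode <- readBin(con, "integer", 1, size = 2, endian = endian)
  bitpix <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti: bad magic string")
  n <- prod(dims)
  seek(con, vox_offset)
  name <- names(NIFTI_DTYPES)[vapply(NIFTI_DTYPES, function(d)
    d$code == dtcode, logical(1))]
  if (!length(name))
    stop(sprintf("read_nifti: unsupported datatype code %d", dtcode))
  data <- switch(name,
    uint8 = readBin(con, "integer", n, size = 1, signed = FALSE),
    int16 = readBin(con, "integer", n, size = 2, endian = endian),
    int32 = readBin(con, "integer", n, size = 4, endian = endian),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian)
  )
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dims), dims = as.integer(dims),
       voxel_size = pixdim[2:4], datatype = name)
}

#' Write a binary mask (contour file) as NIfTI-1
#' @param contour a `contour_file`.
#' @param path output path.
#' @export
write_mask <- function(contour, path) {
  stopifnot(is_contour_file(contour))
  write_nifti(as_mask_array(contour), contour$space, path, datatype = "uint8")
}

#' Read a binary mask as a contour file
#'
#' @param path `.nii` path.
#' @param space expected `psa_space`; dims and voxel sizes are checked
#'   against the file header. NULL builds a space from the header.
#' @param case_id case identifier; default the file name stem.
#' @param frame `"native"` or `"atlas"`.
#' @return a `contour_file`.
#' @export
read_mask <- function(path, space = NULL, case_id = NULL,
                      frame = c("native", "atlas")) {
  frame <- match.arg(frame)
  nii <- read_nifti(path)
  if (is.null(space)) {
    space <- atlas_space(nii$dims, nii$voxel_size)
  } else {
    if (!identical(nii$dims, space$dims))
      stop(sprintf("read_mask: %s dims (%s) do not match the declared space (%s)",
                   path, paste(nii$dims, collapse = "x"),
                   paste(space$dims, collapse = "x")))
    if (max(abs(nii$voxel_size - space$voxel_size)) > 1e-4)
      stop(sprintf("read_mask: %s voxel size does not match the declared space",
                   path))
  }
  if (is.null(case_id)) {
    case_id <- sub("\\.nii$", "", basename(path))
    case_id <- sub("_mask$", "", case_id)
  }
  contour_file(case_id, nii$data != 0, space, frame = frame)
}
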