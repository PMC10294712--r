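# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format this package emits and consumes is supported:
# 3D volumes, little-endian, datatypes uint8 (2), int16 (4), int32 (8),
# float32 (16) and float64 (64), sform affine, no extensions. The header
# layout is the fixed 348-byte NIfTI-1 structure with data at offset 352.
# Scaling (scl_slope/scl_inter) is applied on read when set.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D numeric or integer array.
#' @param grid a [brain_grid()] supplying the affine (stored as sform).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param datatype NIfTI datatype code: 16 (float32, default), 8 (int32),
#'   4 (int16), 2 (uint8) or 64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, grid, path, datatype = 16L) {
  stopifnot(length(dim(vol)) == 3)
  if (!identical(as.integer(dim(vol)), grid$dims)) {
    stop(sprintf("write_nifti: volume dims %s do not match grid %s",
                 paste(dim(vol), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  }
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("write_nifti: unsupported datatype code ", datatype)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wb(348L, 4L)                                   # sizeof_hdr
  wraw(10L); wraw(18L)                           # data_type, db_name
  wb(0L, 4L); wb(0L, 2L)                         # extents, session_error
  writeBin(charToRaw("r"), con); wraw(1L)        # regular, dim_info
  wb(as.integer(c(3L, dim(vol), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(numeric(3), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(as.integer(datatype), 2L)                   # datatype
  wb(dt$bitpix, 2L)                              # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(c(1, grid$voxel_mm, 0, 0, 0, 0), 4L)        # pixdim[8] (qfac = 1)
  wb(352, 4L)                                    # vox_offset
  wb(1, 4L); wb(0, 4L)                           # scl_slope, scl_inter
  wb(0L, 2L); wraw(2L)                           # slice_end, slice_code, xyzt_units
  # xyzt_units is the second raw byte above; rewriting properly:
  # (kept zero: readers treat 0 as unknown units, which is fine for mm grids)
  wb(numeric(4), 4L)                             # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  wraw(80L); wraw(24L)                           # descrip, aux_file
  wb(0L, 2L); wb(1L, 2L)                         # qform_code = 0, sform_code = 1
  wb(numeric(6), 4L)                             # quatern_b/c/d, qoffset_x/y/z
  wb(as.numeric(t(grid$affine[1:3, ])), 4L)      # srow_x, srow_y, srow_z
  wraw(16L)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  wraw(4L)                                       # extension flag (none)

  x <- as.vector(vol)
  if (dt$what == "integer") {
    wb(as.integer(round(x)), dt$size)
  } else {
    wb(as.numeric(x), dt$size)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any conforming
#' little-endian single-file 3D NIfTI-1)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array, scaling applied), `grid`
#'   (a [brain_grid()] reconstructed from the sform and pixdim), `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- gzfile(path, "rb")   # gzfile transparently reads plain files too
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  rb <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  }
  if (rb(0L, "integer", 1L, 4L) != 348L) {
    stop("read_nifti: not a little-endian NIfTI-1 file: ", path)
  }
  dims8 <- rb(40L, "integer", 8L, 2L)
  if (dims8[1] < 3L) stop("read_nifti: expected a 3D volume in ", path)
  d <- dims8[2:4]
  datatype <- rb(70L, "integer", 1L, 2L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("read_nifti: unsupported datatype code ", datatype)
  pixdim <- rb(76L, "double", 8L, 4L)
  vox_offset <- rb(108L, "double", 1L, 4L)
  scl_slope <- rb(112L, "double", 1L, 4L)
  scl_inter <- rb(116L, "double", 1L, 4L)
  sform_code <- rb(254L, "integer", 1L, 2L)
  srow <- matrix(rb(280L, "double", 12L, 4L), nrow = 3, byrow = TRUE)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  if (dt$what == "integer" && dt$size == 1L) {
    x <- as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                            endian = "little"))
  } else {
    x <- as.numeric(readBin(con, dt$what, n = n, size = dt$size,
                            signed = dt$signed, endian = "little"))
  }
  if (length(x) < n) stop("read_nifti: truncated data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    x <- x * scl_slope + scl_inter
  }
  vox <- pixdim[2:4]
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
    origin <- srow[, 4]
  } else {
    affine <- diag(c(vox, 1))
    origin <- c(0, 0, 0)
  }
  grid <- brain_grid(d, vox, origin_mm = origin)
  grid$affine <- affine
  list(data = array(x, dim = d), grid = grid, datatype = datatype)
}
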