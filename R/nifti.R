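#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 (`.nii`, `.nii.gz`) 3-D scalar volumes.
#' Only the subset of the format this package needs is supported: 3-D grids,
#' `float64` (default, lossless round trip), `float32` and `int16` storage,
#' little-endian or big-endian files, diagonal sform from the voxel spacing.
#' No NIfTI package ships with the target environment, hence this minimal
#' implementation; it is cross-checked against nibabel in the test suite.
#'
#' @param vol 3-D numeric array.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing in mm, length-3 numeric.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`.
#' @return `nifti_write` returns `path` invisibly; `nifti_read` returns a list
#'   with elements `data` (3-D array) and `spacing`.
#' @keywords internal
#' @export
nifti_write <- function(vol, path, spacing = c(1, 1, 1),
                        datatype = c("float64", "float32", "int16")) {
  datatype <- match.arg(datatype)
  if (length(dim(vol)) != 3L) stopf("nifti_write expects a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be 3 positive reals (mm)")
  dt <- switch(datatype,
               float64 = list(code = 64L, bitpix = 64L, size = 8L, mode = "double"),
               float32 = list(code = 16L, bitpix = 32L, size = 4L, mode = "double"),
               int16   = list(code = 4L,  bitpix = 16L, size = 2L, mode = "integer"))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_c <- function(nbytes) writeBin(raw(nbytes), con)

  w_i(348L, 4)                       # sizeof_hdr
  w_c(35)                            # data_type, db_name, extents, ...
  w_c(1)                             # dim_info
  w_i(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)  # dim[8]
  w_f(c(0, 0, 0))                    # intent_p1..p3
  w_i(0L, 2)                         # intent_code
  w_i(dt$code, 2)                    # datatype
  w_i(dt$bitpix, 2)                  # bitpix
  w_i(0L, 2)                         # slice_start
  w_f(c(1, spacing, 0, 0, 0, 0))     # pixdim[8]
  w_f(352)                           # vox_offset
  w_f(1); w_f(0)                     # scl_slope, scl_inter
  w_i(0L, 2); w_c(1)                 # slice_end, slice_code
  w_c(1)                             # xyzt_units (written below? keep raw 0)
  w_f(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  w_i(c(0L, 0L), 4)                  # glmax, glmin
  w_c(80); w_c(24)                   # descrip, aux_file
  w_i(0L, 2); w_i(1L, 2)             # qform_code, sform_code
  w_f(c(0, 0, 0, 0, 0, 0))           # quatern_b,c,d, qoffset_x,y,z
  w_f(c(spacing[1], 0, 0, 0))        # srow_x
  w_f(c(0, spacing[2], 0, 0))        # srow_y
  w_f(c(0, 0, spacing[3], 0))        # srow_z
  w_c(16)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  w_c(4)                             # extension flag bytes
  if (dt$mode == "integer") {
    writeBin(as.integer(round(as.vector(vol))), con, size = dt$size,
             endian = "little")
  } else {
    writeBin(as.numeric(as.vector(vol)), con, size = dt$size,
             endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_write
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stopf("truncated NIfTI header in %s", path)
  r_i <- function(off, size, n = 1L, endian) readBin(hdr[(off + 1L):(off + size * n)],
          "integer", n = n, size = size, endian = endian)
  r_f <- function(off, n = 1L, endian) readBin(hdr[(off + 1L):(off + 4L * n)],
          "double", n = n, size = 4L, endian = endian)
  endian <- "little"
  if (r_i(0L, 4L, 1L, "little") != 348L) {
    endian <- "big"
    if (r_i(0L, 4L, 1L, "big") != 348L) stopf("not a NIfTI-1 file: %s", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("unsupported NIfTI magic '%s'", magic)
  dims <- r_i(40L, 2L, 8L, endian)
  ndim <- dims[1]
  if (ndim < 3L) dims[(ndim + 2L):4L] <- 1L
  shape <- dims[2:4]
  if (ndim > 3L && any(dims[5:(ndim + 1L)] > 1L))
    stopf("only 3-D volumes supported (got %d-D) in %s", ndim, path)
  datatype <- r_i(70L, 2L, 1L, endian)
  pixdim <- r_f(76L, 8L, endian)
  vox_offset <- r_f(108L, 1L, endian)
  scl_slope <- r_f(112L, 1L, endian)
  scl_inter <- r_f(116L, 1L, endian)
  n <- prod(shape)
  if (vox_offset > 348) readBin(con, "raw", n = vox_offset - 348L)
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = endian)),
    "16" = readBin(con, "double", n = n, size = 4L, endian = endian),
    "64" = readBin(con, "double", n = n, size = 8L, endian = endian),
    stopf("unsupported NIfTI datatype code %d in %s", datatype, path))
  if (length(dat) != n) stopf("truncated NIfTI data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  list(data = array(dat, dim = shape), spacing = pixdim[2:4])
}
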