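# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for 3-D volumes.
#
# The pipeline only needs: one 3-D volume per file, NaN-capable float storage
# for contrast maps and weight maps, and integer storage for atlas labels.
# Headers are written little-endian with an identity-scaled grid; on read,
# byte order is detected from sizeof_hdr and scl_slope/scl_inter are honoured.

.nifti_dtypes <- list(
  uint8   = list(code =  2L, bitpix =  8L, what = "integer", size = 1L, signed = FALSE),
  int16   = list(code =  4L, bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code =  8L, bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3-D volume as a NIfTI-1 file
#'
#' Writes a single-file NIfTI-1 image (`.nii`, or gzip-compressed when the
#' path ends in `.gz`). The affine is an identity with unit voxel sizes:
#' synthetic cohorts live on an abstract grid, and the analysis only requires
#' that all volumes share a shape.
#'
#' @param vol 3-D numeric or integer array. `NA`/`NaN` values are stored as
#'   NaN (float types only).
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param datatype One of `"float32"` (default), `"float64"`, `"int32"`,
#'   `"int16"`, `"uint8"`.
#' @param descrip Short free-text description stored in the header.
#' @return `path`, invisibly.
#' @seealso [nifti_read()]
#' @export
nifti_write <- function(vol, path, datatype = "float32", descrip = "gpdecode") {
  if (length(dim(vol)) != 3L) stop("`vol` must be a 3-D array")
  dt <- .nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  if (dt$what == "integer" && anyNA(vol))
    stop("NA/NaN values cannot be stored in integer datatype '", datatype, "'")

  dims <- dim(vol)
  con <- .nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_chr <- function(x, n) {
    raw_x <- charToRaw(x)
    writeBin(c(raw_x[seq_len(min(length(raw_x), n))],
               raw(max(0L, n - length(raw_x)))), con)
  }

  w_i32(348L)                               # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)            # data_type, db_name (unused)
  w_i32(0L); w_i16(0L)                      # extents, session_error
  writeBin(as.raw(c(114L, 0L)), con)        # regular = 'r', dim_info
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))        # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)              # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)  # datatype, bitpix, slice_start
  w_f32(c(1, 1, 1, 1, 1, 1, 1, 1))          # pixdim
  w_f32(352); w_f32(1); w_f32(0)            # vox_offset, scl_slope, scl_inter
  w_i16(0L); writeBin(as.raw(c(0L, 10L)), con)  # slice_end, slice_code, xyzt_units (mm|s)
  w_f32(c(0, 0, 0, 0))                      # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                          # glmax, glmin
  w_chr(descrip, 80L); w_chr("", 24L)       # descrip, aux_file
  w_i16(0L); w_i16(1L)                      # qform_code, sform_code (aligned)
  w_f32(c(0, 0, 0, 0, 0, 0))                # quatern/qoffset
  w_f32(c(1, 0, 0, 0)); w_f32(c(0, 1, 0, 0)); w_f32(c(0, 0, 1, 0))  # srow
  w_chr("", 16L)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  writeBin(raw(4L), con)                        # extender
  if (dt$what == "integer") {
    writeBin(as.integer(vol), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vol), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image written by [nifti_write()] or any
#' conforming tool, returning the first 3-D volume as an array. Data are
#' rescaled by `scl_slope`/`scl_inter` when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3-D array (`double`, or `integer` for integer-typed files with
#'   identity scaling), with `dim` taken from the header.
#' @export
nifti_read <- function(path) {
  con <- .nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(what, n, size, off, endian, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1L, 4L, 0L, endian) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported: ", path)

  dims_all <- rd("integer", 8L, 2L, 40L, endian)
  ndim <- dims_all[1L]
  if (ndim < 3L) stop("expected a 3-D volume, got ", ndim, "-D: ", path)
  dims <- dims_all[2:4]
  extra <- if (ndim > 3L) prod(pmax(dims_all[5:(1L + ndim)], 1L)) else 1L
  if (extra != 1L) stop("multi-volume NIfTI not supported: ", path)

  code <- rd("integer", 1L, 2L, 70L, endian)
  dt_i <- which(vapply(.nifti_dtypes, function(d) d$code == code, logical(1)))
  if (!length(dt_i)) stop("unsupported NIfTI datatype code ", code, " in ", path)
  dt <- .nifti_dtypes[[dt_i]]
  vox_offset <- rd("double", 1L, 4L, 108L, endian)
  slope <- rd("double", 1L, 4L, 112L, endian)
  inter <- rd("double", 1L, 4L, 116L, endian)
  if (is.na(slope) || slope == 0) { slope <- 1; inter <- 0 }

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  dat <- readBin(con, dt$what, n = n_vox, size = dt$size,
                 endian = endian, signed = dt$signed)
  if (length(dat) < n_vox) stop("truncated NIfTI data in ", path)
  if (slope != 1 || inter != 0) dat <- dat * slope + inter
  array(dat, dim = dims)
}
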