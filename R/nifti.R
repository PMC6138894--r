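#' Minimal NIfTI-1 input/output
#'
#' A small, dependency-free NIfTI-1 reader and writer covering the subset of
#' the format this package needs: single-file `.nii` / `.nii.gz`, the common
#' numeric datatypes, `pixdim` voxel spacing, temporal spacing with second or
#' millisecond units, and `scl_slope`/`scl_inter` rescaling on read. Both
#' little- and big-endian files are read; files are always written
#' little-endian.
#'
#' @name nifti-io
#' @keywords internal
NULL

.nifti_dtypes <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `data` (numeric array with the header's
#'   dimensions), `pixdim` (numeric, `pixdim[2:8]` of the header, i.e. spatial
#'   then temporal spacing), `time_ms` (temporal spacing converted to
#'   milliseconds, or `NA` if absent), and `datatype` (name).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI: truncated header in ", path)

  rd <- function(raw, what, n, size, signed = TRUE, endian = "little") {
    readBin(raw, what, n = n, size = size, signed = signed, endian = endian)
  }
  endian <- "little"
  sizeof_hdr <- rd(hdr[1:4], "integer", 1L, 4L)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("malformed NIfTI: bad sizeof_hdr in ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI: bad magic in ", path)

  dim_field <- rd(hdr[41:56], "integer", 8L, 2L, endian = endian)
  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("malformed NIfTI: bad ndim in ", path)
  dims <- pmax(dim_field[2:(1 + ndim)], 1L)

  datatype <- rd(hdr[71:72], "integer", 1L, 2L, endian = endian)
  dt_name <- names(.nifti_dtypes)[vapply(.nifti_dtypes, function(d) d$code, 0L) == datatype]
  if (length(dt_name) != 1L) stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  dt <- .nifti_dtypes[[dt_name]]

  pixdim <- rd(hdr[77:108], "double", 8L, 4L, endian = endian)
  vox_offset <- rd(hdr[109:112], "double", 1L, 4L, endian = endian)
  scl_slope <- rd(hdr[113:116], "double", 1L, 4L, endian = endian)
  scl_inter <- rd(hdr[117:120], "double", 1L, 4L, endian = endian)
  xyzt_units <- as.integer(hdr[124])

  n_vox <- prod(dims)
  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox) stop("malformed NIfTI: truncated data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }

  time_unit <- bitwAnd(xyzt_units, 56L)   # 8 = s, 16 = ms, 24 = us
  time_ms <- if (ndim >= 4L && pixdim[5] > 0) {
    switch(as.character(time_unit),
           "8" = pixdim[5] * 1000, "16" = pixdim[5], "24" = pixdim[5] / 1000,
           pixdim[5])
  } else NA_real_

  list(data = array(vals, dim = dims), pixdim = pixdim[2:8],
       time_ms = time_ms, datatype = dt_name)
}

#' Write a NIfTI-1 file
#'
#' @param data numeric or integer array (up to 7 dimensions).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param pixdim numeric vector of per-dimension spacing; element 4 (if
#'   present) is the frame interval and is written in milliseconds.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"uint16"`,
#'   `"float32"`, `"float64"`.
#' @keywords internal
write_nifti <- function(data, path, pixdim = NULL, datatype = "float32") {
  dt <- .nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  if (length(dims) > 7L) stop("too many dimensions for NIfTI")
  dim8 <- c(length(dims), dims, rep(1L, 7L - length(dims)))
  pd <- rep(1, 8)
  if (!is.null(pixdim)) {
    pd[1 + seq_along(pixdim)] <- ifelse(is.na(pixdim), 1, pixdim)
  }

  con <- .nifti_open(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                      # sizeof_hdr
  wraw(36L)                         # data_type .. dim_info
  wi(dim8, 2L)                      # dim[8]
  wd(c(0, 0, 0), 4L)                # intent_p1..p3
  wi(0L, 2L)                        # intent_code
  wi(dt$code, 2L)                   # datatype
  wi(dt$bitpix, 2L)                 # bitpix
  wi(0L, 2L)                        # slice_start
  wd(pd, 4L)                        # pixdim[8]
  wd(352, 4L)                       # vox_offset
  wd(c(1, 0), 4L)                   # scl_slope, scl_inter
  wi(0L, 2L)                        # slice_end
  wraw(1L)                          # slice_code
  writeBin(as.raw(18L), con)        # xyzt_units: mm (2) | msec (16)
  wd(c(0, 0, 0, 0), 4L)             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  wraw(104L)                        # descrip + aux_file
  wi(c(0L, 0L), 2L)                 # qform_code, sform_code
  wd(rep(0, 6), 4L)                 # quatern + qoffset
  srow <- rbind(c(pd[2], 0, 0, 0), c(0, pd[3], 0, 0), c(0, 0, pd[4], 0))
  wd(as.vector(t(srow)), 4L)        # srow_x/y/z
  wraw(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4L)                          # extension indicator

  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
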