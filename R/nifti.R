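#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, or `.nii.gz` via a
#' gzip connection), little-endian, with voxel spacing carried in `pixdim` and
#' an axis-aligned sform. This is deliberately a small subset of the format:
#' enough to round-trip 3D scalar images and segmentation masks with
#' (possibly anisotropic) spacing. Orientation handling beyond the diagonal
#' sform is out of scope.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param x numeric or integer 3D array.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param datatype `"float32"` (default for images) or `"uint8"` (masks).
#' @return `read_nifti()` returns a list with elements `data` (3D array) and
#'   `spacing` (numeric length 3). `write_nifti()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_nifti(array(rnorm(8 * 8 * 4), c(8, 8, 4)), f, spacing = c(1, 1, 2.5))
#' v <- read_nifti(f)
#' dim(v$data); v$spacing
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), datatype = "float32") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("`x` must be a 3D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_config("spacing", "must be 3 positive finite numbers")
  }
  datatype <- match.arg(datatype, c("float32", "uint8"))
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok && file.exists(path)) unlink(path)
  })
  wb_i <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wb_f <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wb_raw <- function(n, str = NULL) {
    r <- raw(n)
    if (!is.null(str)) {
      b <- charToRaw(str)
      r[seq_along(b)] <- b
    }
    writeBin(r, con)
  }

  dims <- dim(x)
  wb_i(348L, 4)                       # sizeof_hdr
  wb_raw(10); wb_raw(18)              # data_type, db_name (unused)
  wb_i(0L, 4); wb_i(0L, 2)            # extents, session_error
  wb_raw(1, "r"); wb_raw(1)           # regular, dim_info
  wb_i(c(3L, dims, 1L, 1L, 1L, 1L), 2)      # dim[8]
  wb_f(c(0, 0, 0))                    # intent_p1..p3
  wb_i(0L, 2)                         # intent_code
  wb_i(dt_code, 2); wb_i(bitpix, 2); wb_i(0L, 2)   # datatype, bitpix, slice_start
  wb_f(c(1, spacing, 1, 1, 1, 1))     # pixdim[8]
  wb_f(352)                           # vox_offset
  wb_f(1); wb_f(0)                    # scl_slope, scl_inter
  wb_i(0L, 2); wb_raw(1); wb_raw(1, rawToChar(as.raw(2L)))  # slice_end/code, xyzt_units = mm
  wb_f(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wb_i(c(0L, 0L), 4)                  # glmax, glmin
  wb_raw(80, "milct phantom/preprocessed volume")
  wb_raw(24)                          # aux_file
  wb_i(0L, 2); wb_i(1L, 2)            # qform_code = 0, sform_code = 1
  wb_f(c(0, 0, 0, 0, 0, 0))           # quatern/qoffset
  wb_f(c(spacing[1], 0, 0, 0))        # srow_x
  wb_f(c(0, spacing[2], 0, 0))        # srow_y
  wb_f(c(0, 0, spacing[3], 0))        # srow_z
  wb_raw(16)                          # intent_name
  wb_raw(4, "n+1")                    # magic
  wb_raw(4)                           # extension flag
  if (datatype == "float32") {
    wb_f(as.vector(x))
  } else {
    v <- as.integer(round(as.vector(x)))
    if (any(v < 0L | v > 255L)) stop("uint8 data out of range [0, 255]", call. = FALSE)
    writeBin(as.raw(v), con)
  }
  ok <- TRUE
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(sprintf("truncated NIfTI header: %s", path), call. = FALSE)
  rd_i <- function(off, n, size, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], "integer",
            n = n, size = size, endian = "little", signed = signed)
  }
  rd_f <- function(off, n) {
    readBin(hdr[(off + 1):(off + n * 4)], "double", n = n, size = 4, endian = "little")
  }
  if (rd_i(0, 1, 4) != 348L) {
    stop(sprintf("not a little-endian NIfTI-1 file: %s", path), call. = FALSE)
  }
  dim8 <- rd_i(40, 8, 2)
  ndim <- dim8[1]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI dim field", call. = FALSE)
  dims <- pmax(dim8[2:(1 + max(ndim, 3L))], 1L)
  datatype <- rd_i(70, 1, 2)
  pixdim <- rd_f(76, 8)
  vox_offset <- rd_f(108, 1)
  scl_slope <- rd_f(112, 1)
  scl_inter <- rd_f(116, 1)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2"   = as.double(readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little")),
    "4"   = as.double(readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little")),
    "8"   = as.double(readBin(con, "integer", n = n, size = 4, signed = TRUE, endian = "little")),
    "16"  = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64"  = readBin(con, "double", n = n, size = 8, endian = "little"),
    "512" = as.double(readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little")),
    stop(sprintf("unsupported NIfTI datatype code %d", datatype), call. = FALSE)
  )
  if (length(data) < n) stop(sprintf("truncated NIfTI data: %s", path), call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(data = array(data, dim = dims[1:3]), spacing = pixdim[2:4])
}
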