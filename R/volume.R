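#' 3D scalar volume with voxel geometry
#'
#' `volume_image()` is the carrier for MR, PET, BVF and deformation data: a 3D
#' numeric array plus voxel spacing and world origin in millimetres. Voxel
#' indices are 0-based in world-coordinate arithmetic: the centre of voxel
#' `(i, j, k)` sits at `origin + c(i, j, k) * spacing`. Orientation is fixed
#' to RAS internally.
#'
#' @param data 3D numeric array (finite values).
#' @param spacing numeric triplet, mm per axis, strictly positive.
#' @param origin numeric triplet, mm.
#' @returns An object of class `volume_image` with fields `data`, `spacing`,
#'   `origin`, `orientation`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_input("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop_input("each axis must have extent >= 1")
  if (!all(is.finite(data))) stop_input("volume data must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("spacing must be a strictly positive mm triplet")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_input("origin must be a finite mm triplet")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = c("R", "A", "S")),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask aligned to a volume grid
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param spacing,origin geometry as in [volume_image()].
#' @returns An object of class `binary_mask` (data stored as logical array).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_input("mask data must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop_input("mask values must be 0/1")
    data <- array(data > 0.5, dim(data))
  }
  if (!is.logical(data)) stop_input("mask data must be logical or 0/1 numeric")
  if (anyNA(data)) stop_input("mask data must not contain NA")
  v <- volume_image(array(0, dim(data)), spacing, origin)  # reuse geometry checks
  structure(list(data = data, spacing = v$spacing, origin = v$origin,
                 orientation = v$orientation),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d set (%.1f%%), spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data), paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Check that two volumes/masks share one voxel grid
#'
#' Grid congruence means identical shape, spacing (to 1e-6 mm) and origin
#' (to 1e-6 mm). Every non-resampling operation in the package propagates
#' geometry unchanged and requires congruent inputs.
#'
#' @param a,b `volume_image` or `binary_mask` objects.
#' @param tol mm tolerance on spacing and origin.
#' @returns `TRUE` or `FALSE`.
#' @export
grid_congruent <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_congruent <- function(a, b, what = "inputs") {
  if (!grid_congruent(a, b))
    stop_input(sprintf("%s are not grid-congruent", what))
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' @param v a `volume_image` or `binary_mask`.
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @returns n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of mm coordinates.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, v$origin, `-`), 2, v$spacing, `/`)
}

# typed conditions -----------------------------------------------------------

stop_input <- function(msg, class = "trabequant_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_param <- function(msg) stop_input(msg, "trabequant_parameter_error")
stop_estim <- function(msg) stop_input(msg, "trabequant_estimation_error")
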