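#' Select the three central slices of an ROI
#'
#' Finds the slice N with the largest in-plane ROI area (ties broken toward
#' the lowest index) and returns it with its two neighbours, mirroring the
#' 3-plane protocol used for in-vivo morphometry.
#'
#' @param roi a [binary_mask()] spanning at least 3 slices.
#' @returns `list(slices = c(N-1, N, N+1) (1-based), areas_mm2 = per-slice
#'   ROI area over the whole volume)`.
#' @export
select_central_slices <- function(roi) {
  stopifnot(inherits(roi, "binary_mask"))
  nz <- dim(roi$data)[3]
  counts <- vapply(seq_len(nz), function(k) sum(roi$data[, , k]), numeric(1))
  if (sum(counts > 0) < 3L) stop_input("ROI spans fewer than 3 slices")
  px_area <- prod(roi$spacing[1:2])
  n <- which.max(counts)                    # first maximum
  if (n == 1L || n == nz)
    stop_input("largest-area slice is at the volume boundary; no neighbour slice")
  list(slices = c(n - 1L, n, n + 1L), areas_mm2 = counts * px_area)
}

#' Local mean thresholding of a BVF slice
#'
#' A pixel is classified bone iff its BVF strictly exceeds the mean BVF in a
#' square window centred on it, plus `offset`. Borders use reflective
#' padding. On a constant slice with zero offset nothing exceeds its local
#' mean, so everything resolves to marrow.
#'
#' @param slice2d numeric matrix of BVF values.
#' @param window_mm window side in mm (converted with `spacing`; forced odd,
#'   at least 3 px).
#' @param offset additive offset on the local mean.
#' @param spacing in-plane pixel size, mm.
#' @returns Logical matrix (TRUE = bone).
#' @export
local_threshold <- function(slice2d, window_mm = 4.7, offset = 0, spacing = 0.234) {
  stopifnot(is.matrix(slice2d), is.numeric(slice2d))
  w <- as.integer(round(window_mm / spacing))
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, 3L)
  if (w > min(dim(slice2d))) stop_param("threshold window larger than the slice")
  r <- (w - 1L) %/% 2L
  nr <- nrow(slice2d); nc <- ncol(slice2d)
  ridx <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  cidx <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  pad <- slice2d[ridx, cidx]
  # box mean via 2D integral image
  s <- rbind(0, apply(pad, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  win_sum <- s[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
    s[i1, j1 + 2L * r + 1L, drop = FALSE] -
    s[i1 + 2L * r + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  local_mean <- win_sum / (w * w)
  # strict comparison with an epsilon so exact ties (locally constant
  # regions) resolve to marrow instead of flipping on rounding noise
  slice2d - (local_mean + offset) > 1e-9 * max(1, max(abs(slice2d)))
}

# Discrete Euclidean disk of integer diameter d: pixel q belongs to the disk
# of centre c iff |q - c| <= d/2. Odd diameters are centred on the pixel
# grid; even diameters on the half grid (centres of 2x2 pixel blocks), which
# is what makes a width-w strip admit a diameter-w disk for every w.
# Offsets are relative to the centre pixel (odd d) or to the top-left pixel
# of the centre block (even d).
disk_offsets <- function(d) {
  if (d %% 2L == 1L) {
    r <- (d - 1L) %/% 2L   # a^2 + b^2 <= r^2 + r < (r+1)^2, so offsets stay within -r..r
    di <- rep(-r:r, times = 2L * r + 1L)
    dj <- rep(-r:r, each = 2L * r + 1L)
    keep <- di * di + dj * dj <= r * r + r   # (r + 0.5)^2 floored
  } else {
    m <- d %/% 2L
    rng <- (1L - m):m
    di <- rep(rng, times = length(rng))
    dj <- rep(rng, each = length(rng))
    keep <- (di - 0.5)^2 + (dj - 0.5)^2 <= m * m
  }
  cbind(di[keep], dj[keep])
}

# Largest admissible diameter per centre, from squared distances to the
# nearest background point. Integer centres: the odd disk of half-width
# m + 0.5 fits iff m^2 + m < d2 (d2 is an integer). Half-grid centres: the
# even disk of radius m fits iff m^2 < d2 (d2 is integer + 0.5).
max_odd_diameter <- function(d2) {
  m <- floor((-1 + sqrt(pmax(4 * (d2 - 1) + 1, 0))) / 2)
  2L * as.integer(m) + 1L
}
max_even_diameter <- function(d2) {
  2L * as.integer(floor(sqrt(pmax(d2 - 0.5, 0))))
}

#' Aperture map of a 2D phase (largest-inscribed-disk diameter)
#'
#' For every pixel p of the phase, `AM(p)` is `d_max(p) * spacing` mm, where
#' `d_max(p)` is the largest integer diameter of a discrete Euclidean disk
#' (see [disk definition below]) lying entirely inside the phase and
#' containing p. Everything outside `phase_mask` -- including pixels beyond
#' the image border -- counts as background, so disks are clipped to the
#' mask (and to the ROI, when the phase was intersected with one).
#'
#' Disks exist for every integer diameter d: pixel q belongs to the disk of
#' centre c iff `|q - c| <= d/2`, with odd-d disks centred on pixels and
#' even-d disks on the half grid (2x2 block centres). This makes a strip of
#' width w pixels admit a diameter-w disk for every w -- essential at
#' in-vivo resolution where trabecular spacing is ~2 pixels.
#'
#' The implementation computes exact squared Euclidean distance transforms
#' to the background on the pixel grid and on the half grid, derives each
#' candidate centre's maximal diameter, and propagates disks in decreasing
#' diameter order (first write wins). It is exact with respect to the
#' discrete-disk definition; [aperture_map_naive()] is the independent
#' brute-force oracle used to verify this.
#'
#' @param phase_mask logical matrix (TRUE = phase).
#' @param spacing in-plane pixel size, mm.
#' @returns Numeric matrix of diameters in mm; 0 outside the phase. An empty
#'   phase yields an all-zero map with a warning.
#' @export
aperture_map <- function(phase_mask, spacing = 1) {
  stopifnot(is.matrix(phase_mask), is.logical(phase_mask))
  nr <- nrow(phase_mask); nc <- ncol(phase_mask)
  am <- matrix(0L, nr, nc)
  if (!any(phase_mask)) {
    warning("aperture_map: empty phase")
    return(am * spacing)
  }
  # candidate disks: (centre, diameter) for both grids
  d2i <- edt_sq_2d(phase_mask)
  inph <- which(phase_mask)
  cand_i <- cbind(((inph - 1L) %% nr) + 1L, ((inph - 1L) %/% nr) + 1L,
                  max_odd_diameter(d2i[inph]))
  cand_e <- NULL
  if (nr > 1L && nc > 1L) {
    d2o <- edt_sq_2d_offset(phase_mask)
    dmax_e <- max_even_diameter(d2o)
    sel <- which(dmax_e >= 2L)
    if (length(sel)) {
      nro <- nr - 1L
      cand_e <- cbind(((sel - 1L) %% nro) + 1L, ((sel - 1L) %/% nro) + 1L,
                      dmax_e[sel])
    }
  }
  cand <- rbind(cand_i, cand_e)
  cand <- cand[order(cand[, 3], decreasing = TRUE), , drop = FALSE]
  offs_cache <- list()
  for (n in seq_len(nrow(cand))) {
    ci <- cand[n, 1]; cj <- cand[n, 2]; d <- cand[n, 3]
    key <- as.character(d)
    offs <- offs_cache[[key]]
    if (is.null(offs)) { offs <- disk_offsets(d); offs_cache[[key]] <- offs }
    lin <- (ci + offs[, 1]) + (cj + offs[, 2] - 1L) * nr  # disk is in-phase, hence in-image
    sel <- lin[am[lin] == 0L]
    if (length(sel)) am[sel] <- d
  }
  am * spacing
}

#' Brute-force aperture map (independent oracle)
#'
#' Reference implementation of the same quantity as [aperture_map()], used to
#' verify it: for every centre (pixel grid and half grid) it grows the
#' diameter while the explicit disk remains inside the phase -- checking
#' every disk pixel by membership, with no distance transform -- then takes,
#' for every pixel, the maximum diameter over all covering disks. Disks of
#' non-maximal diameter at a given centre are subsets of the maximal one, so
#' only maximal disks need painting. O(n^2 d^2) per slice; intended for
#' small test slices.
#'
#' @inheritParams aperture_map
#' @returns Numeric matrix of diameters in mm.
#' @export
aperture_map_naive <- function(phase_mask, spacing = 1) {
  stopifnot(is.matrix(phase_mask), is.logical(phase_mask))
  nr <- nrow(phase_mask); nc <- ncol(phase_mask)
  am <- matrix(0, nr, nc)
  if (!any(phase_mask)) {
    warning("aperture_map_naive: empty phase")
    return(am)
  }
  fits <- function(ci, cj, d) {
    offs <- disk_offsets(d)
    ii <- ci + offs[, 1]; jj <- cj + offs[, 2]
    all(ii >= 1L & ii <= nr & jj >= 1L & jj <= nc) &&
      all(phase_mask[cbind(ii, jj)])
  }
  paint <- function(ci, cj, d) {
    if (d < 1L) return(invisible())
    offs <- disk_offsets(d)
    lin <- cbind(ci + offs[, 1], cj + offs[, 2])
    am[lin] <<- pmax(am[lin], d)
    invisible()
  }
  # odd diameters, pixel-grid centres
  centers <- which(phase_mask, arr.ind = TRUE)
  for (n in seq_len(nrow(centers))) {
    ci <- centers[n, 1]; cj <- centers[n, 2]
    d <- 1L
    while (fits(ci, cj, d + 2L)) d <- d + 2L
    paint(ci, cj, d)
  }
  # even diameters, half-grid centres (indexed by their top-left pixel)
  for (ci in seq_len(max(nr - 1L, 0L))) for (cj in seq_len(max(nc - 1L, 0L))) {
    if (!fits(ci, cj, 2L)) next
    d <- 2L
    while (fits(ci, cj, d + 2L)) d <- d + 2L
    paint(ci, cj, d)
  }
  am * spacing
}

#' Trabecular metrics for one ROI
#'
#' Runs the per-slice morphometry protocol on a BVF map: select the three
#' central slices of the ROI, binarize each with the local mean threshold,
#' then per replicate slice compute BVF = bone pixels / ROI pixels, Tb.Th =
#' mean bone aperture over bone pixels, Tb.Sp = mean marrow aperture over
#' marrow pixels inside the ROI (disks clipped to the ROI), and Tb.N =
#' BVF / Tb.Th. Reported means are the means over usable replicates, with
#' the reported mean Tb.N defined as mean BVF / mean Tb.Th so the
#' definitional identity holds on means as well as per replicate.
#'
#' @param bvf_map a BVF [volume_image()] (values in `[0,1]`).
#' @param roi a congruent [binary_mask()].
#' @param cfg a [study_config()] (window, offset).
#' @returns An object of class `morpho_metrics`: list with `replicates`
#'   (data.frame slice/bvf/tb_th/tb_sp/tb_n/usable) and `means` (named
#'   numeric bvf/tb_th/tb_sp/tb_n), plus `n_usable`.
#' @export
metrics_for_roi <- function(bvf_map, roi, cfg = study_config()) {
  stopifnot(inherits(bvf_map, "volume_image"), inherits(roi, "binary_mask"))
  stopifnot_congruent(bvf_map, roi, "BVF map and ROI")
  if (abs(bvf_map$spacing[1] - bvf_map$spacing[2]) > 1e-6)
    stop_param("in-plane spacing must be isotropic for 2D morphometry")
  sel <- select_central_slices(roi)
  px <- bvf_map$spacing[1]
  reps <- lapply(sel$slices, function(k) {
    roi2d <- roi$data[, , k]
    n_roi <- sum(roi2d)
    if (n_roi == 0)
      return(data.frame(slice = k, bvf = NA, tb_th = NA, tb_sp = NA, tb_n = NA,
                        usable = FALSE))
    bone <- local_threshold(bvf_map$data[, , k],
                            window_mm = cfg$local_threshold_window_mm,
                            offset = cfg$local_threshold_offset,
                            spacing = px) & roi2d
    marrow <- roi2d & !bone
    bvf <- sum(bone) / n_roi
    if (!any(bone) || !any(marrow))
      return(data.frame(slice = k, bvf = bvf, tb_th = NA, tb_sp = NA, tb_n = NA,
                        usable = FALSE))
    am_b <- aperture_map(bone, spacing = px)
    am_m <- aperture_map(marrow, spacing = px)
    tb_th <- mean(am_b[bone])
    tb_sp <- mean(am_m[marrow])
    data.frame(slice = k, bvf = bvf, tb_th = tb_th, tb_sp = tb_sp,
               tb_n = bvf / tb_th, usable = TRUE)
  })
  reps <- do.call(rbind, reps)
  ok <- reps$usable
  if (sum(ok) < 2L)
    stop_input("fewer than 2 usable replicate slices for this ROI")
  means <- c(bvf = mean(reps$bvf[ok]), tb_th = mean(reps$tb_th[ok]),
             tb_sp = mean(reps$tb_sp[ok]))
  means["tb_n"] <- means[["bvf"]] / means[["tb_th"]]
  structure(list(replicates = reps, means = means, n_usable = sum(ok)),
            class = "morpho_metrics")
}

#' @export
print.morpho_metrics <- function(x, ...) {
  cat(sprintf("<morpho_metrics> BVF %.3f  Tb.Th %.3f mm  Tb.Sp %.3f mm  Tb.N %.3f /mm (%d replicates)\n",
              x$means["bvf"], x$means["tb_th"], x$means["tb_sp"],
              x$means["tb_n"], x$n_usable))
  invisible(x)
}

#' Morphometry for every ROI of a set
#'
#' @param bvf_map a BVF [volume_image()].
#' @param rois an `roi_set` from [build_roi_set()], or a named list of masks.
#' @param cfg a [study_config()].
#' @returns Long data.frame: `roi`, `metric`, `replicate`, `value`, plus the
#'   per-ROI means in attribute `means`.
#' @export
metrics_for_roi_set <- function(bvf_map, rois, cfg = study_config()) {
  masks <- if (inherits(rois, "roi_set")) rois$masks else rois
  out <- list(); means <- list()
  for (nm in names(masks)) {
    m <- metrics_for_roi(bvf_map, masks[[nm]], cfg)
    means[[nm]] <- m$means
    reps <- m$replicates[m$replicates$usable, ]
    for (metric in c("bvf", "tb_th", "tb_sp", "tb_n"))
      out[[length(out) + 1L]] <- data.frame(
        roi = nm, metric = metric, replicate = seq_len(nrow(reps)),
        value = reps[[metric]])
  }
  res <- do.call(rbind, out)
  attr(res, "means") <- means
  res
}
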