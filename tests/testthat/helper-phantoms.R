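# Shared in-code fixtures. Everything is generated; nothing is read from disk
# except the packaged reference tables.

# small binary disk image (two-valued, optionally noisy)
disk_image <- function(n = 64, r = 22, lo = 50, hi = 200, sigma = 0, seed = 1) {
  truth <- (row(matrix(0, n, n)) - n / 2)^2 + (col(matrix(0, n, n)) - n / 2)^2 <= r^2
  img <- matrix(lo, n, n)
  img[truth] <- hi
  if (sigma > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(n * n, 0, sigma), n, n)
  }
  list(img = img, truth = truth)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small ellipsoid mask in a 3D grid
ellipsoid_mask <- function(dims, center, semi, spacing = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  inside <- ((idx[, 1] - center[1]) / semi[1])^2 +
    ((idx[, 2] - center[2]) / semi[2])^2 +
    ((idx[, 3] - center[3]) / semi[3])^2 <= 1
  binary_mask(array(inside, dims), spacing)
}

rot_z <- function(theta) {
  R <- diag(3)
  R[1, 1] <- cos(theta); R[1, 2] <- -sin(theta)
  R[2, 1] <- sin(theta); R[2, 2] <- cos(theta)
  R
}

# the acceptance-grade plate-lattice pipeline (also reused by unit tests);
# memoised because generation takes a few seconds
acceptance_lattice_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- phantom_spec("plate_lattice", thickness = 0.25, spacing = 0.45,
                         extent_mm = c(9.8, 9.8, 7.5),
                         highres_voxel = c(0.0234, 0.0234, 0.03))
    lat <- generate_lattice(spec)
    mri <- simulate_gre(lat$mask, acquisition_spec(snr = 25, seed = 7))
    bvf <- compute_bvf_map(mri, 20, 200)
    d <- dim(bvf$data)
    roi <- array(FALSE, d)
    roi[4:(d[1] - 3), 4:(d[2] - 3), 2:4] <- TRUE
    roi[4:6, , c(2, 4)] <- FALSE          # taper so the central slice is unique
    metrics <- metrics_for_roi(bvf, binary_mask(roi, mri$spacing), study_config())
    cache <<- list(spec = spec, lattice = lat, mri = mri, bvf = bvf,
                   metrics = metrics)
    cache
  }
})

# deterministic congruent volume/mask pair
toy_volume <- function(seed = 1, dims = c(6, 5, 4), spacing = c(0.5, 0.5, 2)) {
  set.seed(seed)
  volume_image(array(rnorm(prod(dims)), dims), spacing, origin = c(1, -2, 3))
}
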