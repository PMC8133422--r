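test_that("Chan-Vese recovers a noiseless two-valued disk exactly", {
  d <- disk_image(n = 64, r = 22)
  m <- chan_vese_segment(d$img, polarity = "bright")
  expect_equal(dice(m$data[, , 1], d$truth), 1)
  expect_true(attr(m, "converged"))
})

test_that("Chan-Vese energy trace is non-increasing on arbitrary inputs", {
  for (s in 1:4) {
    set.seed(s)
    img <- matrix(rnorm(32 * 32), 32, 32)
    m <- suppressWarnings(chan_vese_segment(img, chan_vese_params(max_iterations = 40)))
    tr <- attr(m, "energy_trace")
    expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("Chan-Vese segments a noisy disk with Dice >= 0.95", {
  d <- disk_image(n = 64, r = 22, sigma = 20, seed = 3)
  m <- chan_vese_segment(d$img, polarity = "bright")
  expect_gte(dice(m$data[, , 1], d$truth), 0.95)
})

test_that("Chan-Vese attains the exhaustive global minimum on tiny grids", {
  # 3x4 two-valued noisy image: enumerate all 2^12 labellings
  set.seed(7)
  img <- matrix(c(0.1, 0.9)[1 + (runif(12) > 0.5)], 3, 4) + rnorm(12, 0, 0.05)
  v <- volume_image(array((img - min(img)) / diff(range(img)), c(3, 4, 1)))
  mu <- 0.05
  energy <- function(lab) {
    lab <- matrix(lab, 3, 4)
    c1 <- if (any(lab)) mean(v$data[, , 1][lab]) else 0
    c2 <- if (any(!lab)) mean(v$data[, , 1][!lab]) else 0
    edges <- sum(lab[-1, ] != lab[-3, ]) + sum(lab[, -1] != lab[, -4])
    mu * edges + sum((v$data[, , 1][lab] - c1)^2) + sum((v$data[, , 1][!lab] - c2)^2)
  }
  best <- Inf
  for (code in 0:(2^12 - 1)) {
    lab <- as.logical(bitwAnd(code, 2^(0:11)))
    e <- energy(lab)
    if (e < best) best <- e
  }
  m <- chan_vese_segment(v, chan_vese_params(mu = mu, init = "threshold"))
  got <- min(tail(attr(m, "energy_trace"), 1))
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("constant images are rejected", {
  expect_error(chan_vese_segment(matrix(5, 8, 8)), class = "trabequant_input_error")
})

test_that("fill_and_close fills annuli, is idempotent and a superset", {
  n <- 40
  rr <- (row(matrix(0, n, n)) - 20)^2 + (col(matrix(0, n, n)) - 20)^2
  annulus <- rr <= 15^2 & rr >= 9^2
  m <- binary_mask(array(annulus, c(n, n, 1)))
  filled <- fill_and_close(m)
  expect_identical(filled$data[, , 1], rr <= 15^2)
  expect_true(all(filled$data >= m$data))
  expect_identical(fill_and_close(filled)$data, filled$data)
})

test_that("strip_cortical peels in-plane by the disk radius", {
  n <- 100
  rr <- sqrt((row(matrix(0, n, n)) - 50)^2 + (col(matrix(0, n, n)) - 50)^2)
  disk40 <- binary_mask(array(rr <= 40, c(n, n, 1)))
  peeled <- strip_cortical(disk40, 10L)
  got_r <- sqrt(sum(peeled$data) / pi)
  expect_lt(abs(got_r - 30), 1)
  expect_true(all(peeled$data <= disk40$data))
  expect_identical(strip_cortical(disk40, 0L)$data, disk40$data)
  tiny <- binary_mask(array(rr <= 5, c(n, n, 1)))
  expect_error(strip_cortical(tiny, 10L), class = "trabequant_empty_roi_error")
})

test_that("phantom cortical shell is eliminated by 10 px stripping", {
  spec <- phantom_spec("plate_lattice", 0.4, 0.6, extent_mm = c(8, 8, 2),
                       highres_voxel = 0.1, cortical_shell_mm = 2)
  lat <- generate_lattice(spec)
  mri <- simulate_gre(lat$mask, acquisition_spec(voxel_mm = c(0.2, 0.2, 0.5), snr = Inf))
  whole <- binary_mask(array(TRUE, dim(mri$data)), mri$spacing)
  stripped <- strip_cortical(whole, 10L)   # 10 px * 0.2 mm = 2 mm
  # no stripped voxel lies in the shell (outer 2 mm in-plane)
  d <- dim(stripped$data)
  shell_px <- 10L
  expect_true(all(!stripped$data[1:shell_px, , ]))
  expect_true(all(!stripped$data[, 1:shell_px, ]))
  expect_true(all(!stripped$data[(d[1] - shell_px + 1):d[1], , ]))
})

test_that("subset chain: strip_cortical(m) is a subset of fill_and_close(m)", {
  for (s in 1:5) {
    set.seed(s)
    base <- matrix(runif(30 * 30) > 0.4, 30, 30)
    base[c(1, 30), ] <- FALSE; base[, c(1, 30)] <- FALSE
    m <- binary_mask(array(base, c(30, 30, 1)))
    stripped <- tryCatch(strip_cortical(m, 2L), error = function(e) NULL)
    if (is.null(stripped)) next
    expect_true(all(stripped$data <= fill_and_close(m)$data))
  }
})

test_that("partition_patella splits a box into three equal bands along z", {
  box <- array(FALSE, c(8, 8, 30))
  box[3:6, 3:6, ] <- TRUE
  m <- binary_mask(box, spacing = c(1, 1, 1))
  p <- partition_patella(m)
  per_slice <- function(msk) vapply(1:30, function(k) sum(msk$data[, , k]), numeric(1))
  expect_identical(which(per_slice(p$ROI1b) > 0), 1:10)   # lower third
  expect_identical(which(per_slice(p$ROI1c) > 0), 11:20)
  expect_identical(which(per_slice(p$ROI1a) > 0), 21:30)  # upper third
  # partition property
  expect_equal(sum(p$ROI1a$data) + sum(p$ROI1b$data) + sum(p$ROI1c$data),
               sum(p$ROI1$data))
  expect_false(any(p$ROI1a$data & p$ROI1b$data))
})

test_that("partition bands are translation invariant and axis-aware", {
  # tilted ellipsoid: bands orthogonal to the principal axis
  dims <- c(40, 40, 12)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  u <- (idx[, 1] - 20) * cos(pi / 6) + (idx[, 2] - 20) * sin(pi / 6)
  w <- -(idx[, 1] - 20) * sin(pi / 6) + (idx[, 2] - 20) * cos(pi / 6)
  tilted <- (u / 16)^2 + (w / 6)^2 + ((idx[, 3] - 6) / 4)^2 <= 1
  m <- binary_mask(array(tilted, dims))
  p <- partition_patella(m)
  fracs <- c(sum(p$ROI1a$data), sum(p$ROI1b$data), sum(p$ROI1c$data)) / sum(m$data)
  expect_true(all(fracs > 0.15))  # three substantial bands (ellipsoid ends are thin)
  # translation invariance of band sizes
  sh <- array(FALSE, dims)
  sh[3:40, 2:40, ] <- array(tilted, dims)[1:38, 1:39, ]
  p2 <- partition_patella(binary_mask(sh))
  expect_equal(sum(p2$ROI1a$data), sum(p$ROI1a$data), tolerance = 0.02)
  # multiple components rejected with sizes listed
  two <- array(FALSE, c(10, 10, 4)); two[1:2, 1:2, 1] <- TRUE; two[8:9, 8:9, 3] <- TRUE
  expect_error(partition_patella(binary_mask(two)), "components")
})

test_that("build_roi_set assembles the 8-label scheme with its invariants", {
  dims <- c(40, 40, 16)
  pat <- ellipsoid_mask(dims, c(12, 12, 8), c(6, 6, 5))
  fem <- ellipsoid_mask(dims, c(30, 12, 8), c(6, 6, 5))
  tib <- ellipsoid_mask(dims, c(21, 30, 8), c(8, 6, 5))
  rs <- build_roi_set(list(patella = pat, femur = fem, tibia = tib),
                      list(attachment_axis = 1L, attachment_side = "low",
                           attachment_band_mm = 6))
  expect_setequal(names(rs$masks),
                  c("ROI1", "ROI1a", "ROI1b", "ROI1c", "ROI2", "ROI3", "ROI3a", "ROI3b"))
  expect_true(all(rs$masks$ROI1a$data <= rs$masks$ROI1$data))
  expect_true(all(rs$masks$ROI3a$data <= rs$masks$ROI3$data))
  expect_true(all(rs$masks$ROI3b$data <= rs$masks$ROI3$data))
  expect_false(any(rs$masks$ROI3a$data & rs$masks$ROI3b$data))
  expect_error(build_roi_set(list(femur = fem, tibia = tib)), "patella")
  expect_error(build_roi_set(list(patella = pat, femur = pat, tibia = tib)),
               "overlap")
})
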