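test_that("compute_suv implements the body-weight convention", {
  # dose spread uniformly over the body: C = dose/weight per mL -> SUV = 1
  conc <- 210 * 1000 / (70 * 1000)    # kBq/mL
  act <- volume_image(array(conc, c(4, 4, 4)), c(2, 2, 2))
  suv <- compute_suv(act, 210, 70)
  expect_true(all(suv$data == 1))
  expect_true(all(compute_suv(volume_image(array(0, c(2, 2, 2))), 210, 70)$data == 0))
  expect_error(compute_suv(act, 0, 70), class = "trabequant_parameter_error")
  expect_error(compute_suv(act, 210, -1), class = "trabequant_parameter_error")
  # linearity
  act2 <- volume_image(3 * act$data, act$spacing)
  expect_equal(compute_suv(act2, 210, 70)$data, 3 * suv$data)
})

test_that("roi_suv_stats: mean/max/flag with inclusive threshold", {
  suv <- volume_image(array(c(2, 3, rep(1, 6)), c(2, 2, 2)))
  roi <- binary_mask(array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2)))
  st <- roi_suv_stats(suv, roi, threshold = 2.5)
  expect_equal(st$suv_mean, 2.5)
  expect_equal(st$suv_max, 3)
  expect_true(st$hypermetabolic)            # inclusive >=
  expect_gte(st$suv_max, st$suv_mean)
  const <- roi_suv_stats(volume_image(array(1.7, c(2, 2, 2))),
                         binary_mask(array(TRUE, c(2, 2, 2))))
  expect_equal(const$suv_sd, 0)
  expect_equal(const$suv_mean, const$suv_max)
  expect_error(roi_suv_stats(suv, binary_mask(array(FALSE, c(2, 2, 2)))),
               class = "trabequant_input_error")
})

test_that("SUV phantom reproduces the reference before/after contrast", {
  # ROI3a-like: SUVmean 2.8 before (flagged), 1.3 after (not flagged)
  mkphantom <- function(peak) {
    sp <- pet_phantom_spec(background_suv = 0.9,
                           foci = list(list(center = c(11.25, 11.25, 11.25), radius_mm = 15,
                                            peak_suv = peak)),
                           voxel_mm = c(1.5, 1.5, 1.5), extent_mm = c(24, 24, 24))
    sim <- simulate_pet(sp)
    compute_suv(sim$activity, sim$dose_MBq, sim$body_weight_kg)
  }
  dims <- c(16, 16, 16)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  core <- array(rowSums(sweep(idx, 2, c(8, 8, 8))^2) <= 2^2, dims)  # peak voxel is index 8
  roi <- binary_mask(core, c(1.5, 1.5, 1.5))
  before <- roi_suv_stats(mkphantom(3.1), roi, label = "ROI3a")
  after <- roi_suv_stats(mkphantom(1.4), roi, label = "ROI3a")
  expect_true(before$hypermetabolic)
  expect_false(after$hypermetabolic)
})

test_that("affine_transform validates its invariants", {
  expect_error(affine_transform(diag(3)), class = "trabequant_parameter_error")
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(affine_transform(bad), class = "trabequant_parameter_error")
  refl <- diag(c(-1, 1, 1, 1))
  expect_error(affine_transform(refl), class = "trabequant_parameter_error")
  expect_s3_class(affine_from_parts(rot_z(0.2), c(1, 2, 3)), "affine_transform")
})

test_that("estimate_bone_affine recovers identity, translation, rotation+scale", {
  el <- ellipsoid_mask(c(40, 34, 30), c(20, 17, 15), c(14, 9, 6))
  same <- estimate_bone_affine(el, el)
  expect_lt(max(abs(unclass(same) - diag(4))), 1e-6)
  # pure translation (moment matching is exact)
  arr <- el$data
  sh <- array(FALSE, dim(arr))
  sh[6:40, 1:31, 3:30] <- arr[1:35, 4:34, 1:28]   # shift by (5, -3, 2)
  m2 <- binary_mask(sh)
  tr <- estimate_bone_affine(m2, el)
  expect_lt(max(abs(unclass(tr)[1:3, 4] - c(5, -3, 2))), 0.1)
  # rotation by 10 deg + scale 1.05 about the centroid
  L <- 1.05 * rot_z(10 * pi / 180)
  dims <- dim(arr)
  idx <- sweep(arrayInd(seq_len(prod(dims)), dims), 2, c(20, 17, 15))
  back <- idx %*% t(solve(L))
  warped <- (back[, 1] / 14)^2 + (back[, 2] / 9)^2 + (back[, 3] / 6)^2 <= 1
  m3 <- binary_mask(array(warped, dims))
  est <- estimate_bone_affine(m3, el)
  Lr <- unclass(est)[1:3, 1:3]
  sc <- det(Lr)^(1 / 3)
  expect_lt(abs(sc - 1.05) / 1.05, 0.01)
  cosang <- (sum(diag(crossprod(Lr / sc, rot_z(10 * pi / 180)))) - 1) / 2
  ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
  expect_lt(ang, 0.5)
  # degenerate (planar) distribution falls back with a warning
  flat <- array(FALSE, c(10, 10, 3)); flat[3:8, 3:8, 2] <- TRUE
  expect_warning(estimate_bone_affine(binary_mask(flat), binary_mask(flat)),
                 "degenerate")
})

test_that("poly-affine fusion: single translation and all-identity components", {
  b <- binary_mask(array(TRUE, c(12, 12, 12)))
  tr <- affine_from_parts(diag(3), c(3, -2, 1.5))
  f <- fuse_polyaffine(polyaffine_model(list(bone = b), list(bone = tr)))
  expect_lt(max(abs(f$u[, , , 1] - 3)), 1e-3)
  expect_lt(max(abs(f$u[, , , 2] + 2)), 1e-3)
  expect_lt(max(abs(f$u[, , , 3] - 1.5)), 1e-3)
  # all-identity components -> zero field
  f0 <- fuse_polyaffine(polyaffine_model(
    list(a = b, b = b),
    list(a = affine_transform(diag(4)), b = affine_transform(diag(4)))))
  expect_true(all(f0$u == 0))
  # negative-determinant component rejected at construction
  expect_error(polyaffine_model(list(a = b), list(a = diag(c(-1, 1, 1, 1)))),
               class = "trabequant_parameter_error")
})

test_that("log-Euclidean mean of two constant-weight rotations", {
  d2 <- c(16, 16, 4)
  b1 <- binary_mask(array(TRUE, d2))
  f <- fuse_polyaffine(polyaffine_model(
    list(a = b1, b = b1),
    list(a = affine_from_parts(rot_z(20 * pi / 180)), b = affine_transform(diag(4))),
    sigma_mm = 3))
  idx <- arrayInd(seq_len(prod(d2)), d2) - 1
  disp <- idx %*% t(rot_z(10 * pi / 180)) - idx
  got <- cbind(as.vector(f$u[, , , 1]), as.vector(f$u[, , , 2]), as.vector(f$u[, , , 3]))
  expect_lt(max(abs(got - disp)), 1e-3)
})

test_that("matrix log/exp round-trip on affine transforms", {
  Ms <- list(affine_from_parts(rot_z(0.4) %*% diag(c(1.1, 0.95, 1.02)), c(5, -2, 1)),
             affine_from_parts(diag(3), c(0, 0, 0)),
             affine_from_parts(diag(c(2, 0.5, 1)), c(-3, 4, 0)))
  for (M in Ms) {
    L <- trabequant:::mat_log(unclass(M))
    expect_lt(max(abs(trabequant:::mat_exp(L) - unclass(M))), 1e-10)
    expect_true(all(abs(L[4, ]) < 1e-10))
  }
})

test_that("warp_volume: zero field is identity; translation moves a spot", {
  set.seed(8)
  v <- volume_image(array(rnorm(16^3), c(16, 16, 16)))
  b <- binary_mask(array(TRUE, c(16, 16, 16)))
  f0 <- fuse_polyaffine(polyaffine_model(list(a = b), list(a = affine_transform(diag(4)))))
  w0 <- warp_volume(v, f0)
  expect_equal(w0$data, v$data, tolerance = 1e-12)
  # delta spot under pull-back warp by translation t appears at x - t
  spot <- array(0, c(16, 16, 16)); spot[9, 9, 9] <- 1
  vs <- volume_image(spot)
  ft <- fuse_polyaffine(polyaffine_model(list(a = b),
                                         list(a = affine_from_parts(diag(3), c(2, 0, 0)))))
  ws <- warp_volume(vs, ft)
  expect_equal(which(ws$data == max(ws$data), arr.ind = TRUE)[1, ],
               c(dim1 = 7, dim2 = 9, dim3 = 9), ignore_attr = TRUE)
  # out-of-field voxels are counted and set to background
  expect_gt(attr(ws, "n_outside"), 0)
})

test_that("warp round trip A then A^-1 is inverse-consistent on a smooth volume", {
  n <- 20
  g <- seq(0, 2 * pi, length.out = n)
  smooth <- outer(outer(sin(g), cos(g / 2), `+`), sin(g / 3), `+`)
  v <- volume_image(smooth)
  b <- binary_mask(array(TRUE, c(n, n, n)))
  A <- affine_from_parts(rot_z(6 * pi / 180), c(1, 0.5, -0.4))
  fA <- fuse_polyaffine(polyaffine_model(list(a = b), list(a = A)))
  fAi <- fuse_polyaffine(polyaffine_model(list(a = b),
                                          list(a = affine_transform(solve(unclass(A))))))
  rt <- warp_volume(warp_volume(v, fA), fAi)
  inner <- 5:16
  err <- max(abs(rt$data[inner, inner, inner] - v$data[inner, inner, inner]))
  expect_lt(err / diff(range(v$data)), 0.02)
})
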