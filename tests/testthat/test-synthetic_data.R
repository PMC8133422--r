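test_that("plate lattice has the closed-form ground truth", {
  lat <- generate_lattice(phantom_spec("plate_lattice", 0.25, 0.45,
                                       extent_mm = c(2.8, 2.8, 1.4),
                                       highres_voxel = 0.05))
  expect_equal(lat$truth$bvf, 0.25 / 0.7)
  expect_equal(lat$truth$tb_th, 0.25)
  expect_equal(lat$truth$tb_sp, 0.45)
  expect_equal(lat$truth$tb_n, 1 / 0.7)
  expect_equal(lat$truth$tb_n, lat$truth$bvf / lat$truth$tb_th, tolerance = 1e-12)
  # t = s gives bvf 1/2
  sym <- generate_lattice(phantom_spec("plate_lattice", 0.4, 0.4,
                                       extent_mm = c(3.2, 3.2, 1.6),
                                       highres_voxel = 0.1))
  expect_equal(sym$truth$bvf, 0.5)
  expect_equal(mean(sym$mask$data), 0.5, tolerance = 0.01)
  expect_error(phantom_spec("plate_lattice", 0.5, 0.7, extent_mm = c(1, 1, 1),
                            highres_voxel = 0.1),
               class = "trabequant_parameter_error")
  expect_error(phantom_spec("plate_lattice", 0.2, 0.4, highres_voxel = 0.1),
               class = "trabequant_parameter_error")  # > thickness/4
})

test_that("voxelized lattice volume fraction matches the closed form within 1%", {
  # commensurate extent: 4 periods of 0.7 mm
  lat <- generate_lattice(phantom_spec("plate_lattice", 0.25, 0.45,
                                       extent_mm = c(2.8, 2.8, 1.4),
                                       highres_voxel = 0.025))
  expect_lt(abs(mean(lat$mask$data) / lat$truth$bvf - 1), 0.01)
  # 0.025 mm divides both the rod width (0.3) and the period (0.8) exactly
  rod <- generate_lattice(phantom_spec("rod_lattice", 0.3, 0.5,
                                       extent_mm = c(3.2, 3.2, 1.6),
                                       highres_voxel = 0.025))
  expect_lt(abs(mean(rod$mask$data) / rod$truth$bvf - 1), 0.02)
})

test_that("gaussian field phantom hits the target fraction and is deterministic", {
  spec <- phantom_spec("gaussian_field", thickness = 0.3, spacing = 0.7,
                       extent_mm = c(6, 6, 0.5), highres_voxel = 0.075, seed = 11)
  g1 <- generate_gaussian_field(spec, measure_truth = FALSE)
  expect_lt(abs(mean(g1$mask$data) - 0.3), 0.005)
  g2 <- generate_gaussian_field(spec, measure_truth = FALSE)
  expect_identical(g1$mask$data, g2$mask$data)
  # doubling the correlation length increases the oracle mean aperture
  spec2 <- phantom_spec("gaussian_field", thickness = 0.6, spacing = 1.4,
                        extent_mm = c(6, 6, 0.5), highres_voxel = 0.15, seed = 11)
  t1 <- generate_gaussian_field(spec, measure_truth = TRUE)$truth
  t2 <- generate_gaussian_field(spec2, measure_truth = TRUE)$truth
  expect_gt(t2$tb_th, t1$tb_th)
})

test_that("simulate_gre mixes phases linearly and respects grid divisibility", {
  # all-bone at infinite snr -> constant bone intensity
  allbone <- binary_mask(array(TRUE, c(8, 8, 8)), c(0.1, 0.1, 0.1))
  acq <- acquisition_spec(voxel_mm = c(0.2, 0.2, 0.4), bone_intensity = 30,
                          marrow_intensity = 180, snr = Inf)
  v <- simulate_gre(allbone, acq)
  expect_true(all(v$data == 30))
  # half-filled voxels -> exact mean of the two intensities
  half <- array(FALSE, c(8, 8, 8)); half[, , seq(1, 8, 2)] <- TRUE
  vh <- simulate_gre(binary_mask(half, c(0.1, 0.1, 0.1)), acq)
  expect_true(all(abs(vh$data - 105) < 1e-12))
  # incompatible grids rejected
  bad <- acquisition_spec(voxel_mm = c(0.25, 0.2, 0.4), snr = Inf)
  expect_error(simulate_gre(binary_mask(half, c(0.1, 0.1, 0.1)), bad),
               class = "trabequant_input_error")
  # determinism under a fixed seed
  acqn <- acquisition_spec(voxel_mm = c(0.2, 0.2, 0.4), snr = 10, seed = 3)
  expect_identical(simulate_gre(allbone, acqn)$data, simulate_gre(allbone, acqn)$data)
})

test_that("rician noise keeps marrow brighter than bone on average", {
  lat <- generate_lattice(phantom_spec("plate_lattice", 0.4, 0.6,
                                       extent_mm = c(4, 4, 2), highres_voxel = 0.1))
  mri <- simulate_gre(lat$mask, acquisition_spec(voxel_mm = c(0.2, 0.2, 0.5),
                                                 snr = 15, seed = 2))
  bone_frac <- simulate_gre(lat$mask, acquisition_spec(voxel_mm = c(0.2, 0.2, 0.5), snr = Inf))
  expect_gt(mean(mri$data[bone_frac$data > 150]), mean(mri$data[bone_frac$data < 60]))
})

test_that("simulate_pet inverts the SUV definition", {
  # uniform background: SUV identically 1 after compute_suv
  sp <- pet_phantom_spec(background_suv = 1, voxel_mm = c(2, 2, 2),
                         extent_mm = c(20, 20, 20), body_weight_kg = 70, dose_MBq = 210)
  sim <- simulate_pet(sp)
  suv <- compute_suv(sim$activity, sim$dose_MBq, sim$body_weight_kg)
  expect_equal(max(abs(suv$data - 1)), 0, tolerance = 1e-12)
  # a focus centred on a voxel centre reaches its configured peak exactly
  spf <- pet_phantom_spec(background_suv = 1,
                          foci = list(list(center = c(15.5, 15.5, 15.5), radius_mm = 6,
                                           peak_suv = 4)),
                          voxel_mm = c(1, 1, 1), extent_mm = c(30, 30, 30))
  simf <- simulate_pet(spf)
  suvf <- compute_suv(simf$activity, simf$dose_MBq, simf$body_weight_kg)
  expect_equal(max(suvf$data), 4, tolerance = 0.01)
  expect_error(pet_phantom_spec(foci = list(list(center = c(5, 5, 5),
                                                 radius_mm = 2, peak_suv = 0.5))),
               class = "trabequant_parameter_error")
})

test_that("hypermetabolic classification flags only the hot focus (2.8 vs 1.0)", {
  sp <- pet_phantom_spec(background_suv = 1,
                         foci = list(list(center = c(10.5, 10.5, 10.5), radius_mm = 12,
                                          peak_suv = 2.8)),
                         voxel_mm = c(1, 1, 1), extent_mm = c(30, 30, 30))
  sim <- simulate_pet(sp)
  suv <- compute_suv(sim$activity, sim$dose_MBq, sim$body_weight_kg)
  dims <- dim(suv$data)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  # voxel centres sit at index - 0.5 mm; tight ball around the peak
  focus <- array(rowSums(sweep(idx, 2, c(11, 11, 11))^2) <= 2^2, dims)
  far <- array(rowSums(sweep(idx, 2, c(27, 27, 27))^2) <= 3^2, dims)
  stats <- classify_hypermetabolic(suv, list(focus = binary_mask(focus, c(1, 1, 1)),
                                             background = binary_mask(far, c(1, 1, 1))))
  expect_true(stats$hypermetabolic[stats$roi == "focus"])
  expect_false(stats$hypermetabolic[stats$roi == "background"])
})

test_that("cohort generator recovers configured effects and degenerates correctly", {
  cs <- reference_control_stats()
  # SDs 0: percent differences exactly (effect - 1) * 100
  cs0 <- cs; cs0$sd <- 0
  eff <- data.frame(roi = "ROI2", metric = "bvf", before = 0.8, after = 1.1)
  co <- generate_cohort(cohort_spec(control_stats = cs0, effects = eff, seed = 4))
  rows <- compare_cohort(co)
  r2 <- rows[rows$roi == "ROI2" & rows$metric == "bvf", ]
  expect_equal(r2$pct_before, -20, tolerance = 1e-9)
  expect_equal(r2$pct_after, 10, tolerance = 1e-9)
  # null effects: percent differences centred at 0 across seeds
  csn <- cs[cs$roi == "ROI1" & cs$metric == "bvf", ]
  pct <- vapply(1:60, function(s)
    compare_cohort(generate_cohort(cohort_spec(control_stats = csn, seed = s)))$pct_before,
    numeric(1))
  expect_lt(abs(mean(pct)), 3 * sd(pct) / sqrt(length(pct)) + 0.5)
  # determinism
  sp <- cohort_spec(control_stats = csn, seed = 9)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
})
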