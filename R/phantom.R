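#' Trabecular phantom specification
#'
#' Describes a high-resolution two-phase trabecular phantom with analytic (or
#' self-measured) ground truth. `plate_lattice` is a periodic stack of
#' parallel plates of width `thickness` separated by `spacing` (closed-form
#' truth); `rod_lattice` is a square grid of rods; `gaussian_field` is a
#' smoothed thresholded random field whose target bone fraction is
#' `thickness / (thickness + spacing)` and whose correlation length is set by
#' `thickness`.
#'
#' @param kind one of `"plate_lattice"`, `"rod_lattice"`, `"gaussian_field"`.
#' @param thickness trabecular thickness t, mm.
#' @param spacing trabecular spacing s, mm.
#' @param extent_mm physical extent, mm triplet.
#' @param highres_voxel high-resolution voxel size, mm (scalar or triplet);
#'   must be at most `thickness / 4` so the truth is well resolved.
#' @param orientation unit normal of the plates (plate lattice only);
#'   default in-plane `+x` so thickness is measurable in 2D slices.
#' @param cortical_shell_mm thickness of a solid bone shell added on the four
#'   in-plane faces (0 = none).
#' @param seed integer RNG seed (gaussian_field only).
#' @returns An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("plate_lattice", "rod_lattice", "gaussian_field"),
                         thickness = 0.25, spacing = 0.45,
                         extent_mm = c(10, 10, 4.5),
                         highres_voxel = 0.03,
                         orientation = c(1, 0, 0),
                         cortical_shell_mm = 0,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (thickness <= 0 || spacing <= 0) stop_param("thickness and spacing must be positive")
  hv <- rep_len(as.numeric(highres_voxel), 3L)
  if (any(hv <= 0)) stop_param("highres_voxel must be positive")
  if (max(hv) > thickness / 4 + 1e-12)
    stop_param("highres_voxel must be <= thickness/4 so truth is well-resolved")
  if (length(extent_mm) != 3L || any(extent_mm <= 0))
    stop_param("extent_mm must be a positive triplet")
  if (kind != "gaussian_field" && min(extent_mm[1:2]) < thickness + spacing)
    stop_param("extent smaller than one lattice period")
  orientation <- as.numeric(orientation)
  if (length(orientation) != 3L || sum(orientation^2) == 0)
    stop_param("orientation must be a nonzero 3-vector")
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(kind = kind, thickness = thickness, spacing = spacing,
                 extent_mm = as.numeric(extent_mm), highres_voxel = hv,
                 orientation = orientation,
                 cortical_shell_mm = as.numeric(cortical_shell_mm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ground_truth <- function(bvf, tb_th, tb_sp) {
  stopifnot(bvf > 0, tb_th > 0, tb_sp > 0)
  structure(list(bvf = bvf, tb_th = tb_th, tb_sp = tb_sp,
                 tb_n = bvf / tb_th),
            class = "ground_truth")
}

phantom_grid <- function(spec) {
  dims <- pmax(1L, as.integer(round(spec$extent_mm / spec$highres_voxel)))
  centers <- lapply(1:3, function(ax) ((seq_len(dims[ax]) - 1) + 0.5) * spec$highres_voxel[ax])
  list(dims = dims, centers = centers)
}

add_cortical_shell <- function(mask_arr, spec) {
  if (spec$cortical_shell_mm <= 0) return(mask_arr)
  n_x <- as.integer(round(spec$cortical_shell_mm / spec$highres_voxel[1]))
  n_y <- as.integer(round(spec$cortical_shell_mm / spec$highres_voxel[2]))
  d <- dim(mask_arr)
  if (n_x > 0) { mask_arr[1:n_x, , ] <- TRUE; mask_arr[(d[1] - n_x + 1):d[1], , ] <- TRUE }
  if (n_y > 0) { mask_arr[, 1:n_y, ] <- TRUE; mask_arr[, (d[2] - n_y + 1):d[2], ] <- TRUE }
  mask_arr
}

#' Generate a periodic lattice phantom with closed-form ground truth
#'
#' Plate lattice: bone wherever the coordinate along the plate normal falls in
#' the first `t` of each `t + s` period, so `bvf = t/(t+s)`, `Tb.Th = t`,
#' `Tb.Sp = s`, `Tb.N = 1/(t+s)`. Rod lattice: square rods along z on a
#' `t + s` grid (`bvf = t^2/(t+s)^2`). Voxelization samples voxel centres, so
#' the discretization error on thickness is at most one high-res voxel.
#'
#' @param spec a [phantom_spec()] of kind `plate_lattice` or `rod_lattice`.
#' @returns `list(mask = binary_mask (high-res), truth = ground_truth)`.
#' @export
generate_lattice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$kind %in% c("plate_lattice", "rod_lattice"))
    stop_param("spec$kind must be plate_lattice or rod_lattice")
  g <- phantom_grid(spec)
  t <- spec$thickness; s <- spec$spacing; period <- t + s
  if (spec$kind == "plate_lattice") {
    # signed coordinate along the plate normal for every voxel centre
    u <- outer(outer(g$centers[[1]] * spec$orientation[1],
                     g$centers[[2]] * spec$orientation[2], `+`),
               g$centers[[3]] * spec$orientation[3], `+`)
    bone <- (u %% period) < t
    truth <- ground_truth(t / period, t, s)
  } else {
    in_rod_x <- (g$centers[[1]] %% period) < t
    in_rod_y <- (g$centers[[2]] %% period) < t
    bone <- array(outer(in_rod_x, in_rod_y, `&`), g$dims)
    truth <- ground_truth((t / period)^2, t, s)
  }
  bone <- add_cortical_shell(array(bone, g$dims), spec)
  list(mask = binary_mask(bone, spec$highres_voxel), truth = truth)
}

#' Generate a thresholded Gaussian random-field phantom
#'
#' White noise is smoothed with a Gaussian of standard deviation
#' `spec$thickness` (mm) and thresholded at the empirical quantile that yields
#' the requested bone fraction `t/(t+s)` exactly (to one voxel). Because no
#' closed form exists for the aperture of such a field, `Tb.Th`/`Tb.Sp` in the
#' returned truth are *self-declared*: measured on the central slice of the
#' high-res mask with the brute-force aperture oracle
#' ([aperture_map_naive()]).
#'
#' @param spec a [phantom_spec()] of kind `gaussian_field`.
#' @param measure_truth if `FALSE`, skip the (slow) oracle measurement and
#'   report only the analytic bone fraction.
#' @returns `list(mask, truth)` as in [generate_lattice()].
#' @export
generate_gaussian_field <- function(spec, measure_truth = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "gaussian_field") stop_param("spec$kind must be gaussian_field")
  g <- phantom_grid(spec)
  target_bvf <- spec$thickness / (spec$thickness + spec$spacing)
  field <- with_seed(spec$seed, array(stats::rnorm(prod(g$dims)), g$dims))
  sigma_px <- spec$thickness / spec$highres_voxel
  field <- smooth_gaussian(field, sigma_px)
  thr <- stats::quantile(field, 1 - target_bvf, names = FALSE, type = 7)
  bone <- field > thr
  bone <- add_cortical_shell(bone, spec)
  mask <- binary_mask(bone, spec$highres_voxel)
  tb_th <- tb_sp <- NA_real_
  if (measure_truth) {
    k <- max(1L, g$dims[3] %/% 2L)
    sl <- bone[, , k]
    px <- spec$highres_voxel[1]
    am_b <- aperture_map_naive(sl, spacing = px)
    am_m <- aperture_map_naive(!sl, spacing = px)
    tb_th <- mean(am_b[sl]); tb_sp <- mean(am_m[!sl])
  }
  truth <- structure(list(bvf = target_bvf, tb_th = tb_th, tb_sp = tb_sp,
                          tb_n = if (is.na(tb_th)) NA_real_ else target_bvf / tb_th),
                     class = "ground_truth")
  list(mask = mask, truth = truth)
}

#' GRE acquisition specification
#'
#' @param voxel_mm acquisition voxel, mm triplet (default the 7T knee
#'   protocol: 0.234 x 0.234 x 1.5).
#' @param bone_intensity,marrow_intensity pure-phase signal levels; marrow
#'   must be brighter than bone (GRE contrast).
#' @param noise_model `"rician"` (magnitude images, default) or `"gaussian"`.
#' @param snr signal-to-noise ratio, defined as `marrow_intensity / sigma`;
#'   `Inf` disables noise.
#' @param seed RNG seed for the noise draw.
#' @returns An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(voxel_mm = c(0.234, 0.234, 1.5),
                             bone_intensity = 20, marrow_intensity = 200,
                             noise_model = c("rician", "gaussian"),
                             snr = 25, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (marrow_intensity <= bone_intensity)
    stop_param("marrow_intensity must exceed bone_intensity (GRE contrast)")
  if (!(snr > 0)) stop_param("snr must be positive")
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop_param("voxel_mm must be a positive triplet")
  structure(list(voxel_mm = as.numeric(voxel_mm),
                 bone_intensity = bone_intensity,
                 marrow_intensity = marrow_intensity,
                 noise_model = noise_model, snr = snr,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate a GRE acquisition of a high-resolution phantom
#'
#' Partial volume is modelled exactly: each acquisition voxel takes the box
#' average `f` of the high-res bone mask it covers (the high-res voxel must
#' divide the acquisition voxel in each axis, within 1%), and the noise-free
#' intensity is `bone*f + marrow*(1-f)`. Rician noise then replaces I by
#' `sqrt((I+n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`,
#' `sigma = marrow_intensity/snr`; the Gaussian model adds `n1` only.
#'
#' @param highres a high-res [binary_mask()] (bone = TRUE).
#' @param acq an [acquisition_spec()].
#' @returns A [volume_image()] on the acquisition grid (trailing high-res
#'   voxels that do not fill a whole acquisition voxel are dropped).
#' @export
simulate_gre <- function(highres, acq) {
  stopifnot(inherits(highres, "binary_mask"), inherits(acq, "acquisition_spec"))
  ratio <- acq$voxel_mm / highres$spacing
  r <- as.integer(round(ratio))
  if (any(r < 1L) || any(abs(ratio - r) > 0.01 * r))
    stop_input("high-res voxel does not divide acquisition voxel (within 1%)")
  d <- dim(highres$data)
  n <- d %/% r
  if (any(n < 1L)) stop_input("phantom smaller than one acquisition voxel")
  a <- highres$data[seq_len(n[1] * r[1]), seq_len(n[2] * r[2]), seq_len(n[3] * r[3]), drop = FALSE]
  f <- box_average(a * 1, r)
  intensity <- acq$bone_intensity * f + acq$marrow_intensity * (1 - f)
  if (is.finite(acq$snr)) {
    sigma <- acq$marrow_intensity / acq$snr
    intensity <- with_seed(acq$seed, {
      n1 <- array(stats::rnorm(length(intensity), 0, sigma), dim(intensity))
      if (acq$noise_model == "rician") {
        n2 <- array(stats::rnorm(length(intensity), 0, sigma), dim(intensity))
        sqrt((intensity + n1)^2 + n2^2)
      } else intensity + n1
    })
  }
  volume_image(intensity, acq$voxel_mm, origin = highres$origin)
}

# Exact box averaging of a 3D array by integer factors r (dims must be
# multiples of r).
box_average <- function(a, r) {
  d <- dim(a); n <- d %/% r
  stopifnot(all(n * r == d))
  a6 <- array(a, c(r[1], n[1], r[2], n[2], r[3], n[3]))
  a6 <- aperm(a6, c(1, 3, 5, 2, 4, 6))
  dim(a6) <- c(prod(r), prod(n))
  array(colMeans(a6), n)
}

#' PET phantom specification
#'
#' @param background_suv uniform background SUV.
#' @param foci list of `list(center = mm triplet, radius_mm, peak_suv)`;
#'   overlapping foci take the voxel-wise maximum.
#' @param voxel_mm PET voxel, mm triplet.
#' @param extent_mm field of view, mm triplet.
#' @param body_weight_kg,dose_MBq subject metadata carried with the volume.
#' @param noise_cv multiplicative Gaussian noise coefficient of variation
#'   (0 = noise-free).
#' @param seed RNG seed.
#' @returns An object of class `pet_phantom_spec`.
#' @export
pet_phantom_spec <- function(background_suv = 1,
                             foci = list(),
                             voxel_mm = c(2, 2, 2),
                             extent_mm = c(60, 60, 60),
                             body_weight_kg = 70,
                             dose_MBq = 210,
                             noise_cv = 0,
                             seed = 1L) {
  if (background_suv < 0) stop_param("background_suv must be >= 0")
  for (f in foci) {
    if (f$peak_suv < background_suv)
      stop_param("focus peak_suv must be >= background_suv")
    if (f$radius_mm <= 0) stop_param("focus radius must be positive")
    if (any(f$center < 0 | f$center > extent_mm))
      stop_param("focus centre outside extent")
  }
  structure(list(background_suv = background_suv, foci = foci,
                 voxel_mm = as.numeric(voxel_mm), extent_mm = as.numeric(extent_mm),
                 body_weight_kg = body_weight_kg, dose_MBq = dose_MBq,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "pet_phantom_spec")
}

#' Simulate a PET activity volume with known SUV structure
#'
#' Builds the SUV field (background plus Gaussian foci: at a focus centre the
#' SUV equals `peak_suv`, falling off with standard deviation `radius/3` so a
#' focus is contained within its stated radius), converts it to an activity
#' concentration in kBq/mL such that [compute_suv()] inverts it exactly for
#' the stated dose and weight, then applies optional multiplicative noise.
#'
#' @param spec a [pet_phantom_spec()].
#' @returns `list(activity = volume_image (kBq/mL), dose_MBq, body_weight_kg,
#'   suv_truth = volume_image)` .
#' @export
simulate_pet <- function(spec) {
  stopifnot(inherits(spec, "pet_phantom_spec"))
  dims <- pmax(1L, as.integer(round(spec$extent_mm / spec$voxel_mm)))
  cx <- lapply(1:3, function(ax) ((seq_len(dims[ax]) - 1) + 0.5) * spec$voxel_mm[ax])
  suv <- array(spec$background_suv, dims)
  for (f in spec$foci) {
    s <- f$radius_mm / 3
    d2 <- outer(outer((cx[[1]] - f$center[1])^2, (cx[[2]] - f$center[2])^2, `+`),
                (cx[[3]] - f$center[3])^2, `+`)
    bump <- spec$background_suv +
      (f$peak_suv - spec$background_suv) * exp(-d2 / (2 * s^2))
    suv <- pmax(suv, array(bump, dims))
  }
  # activity concentration consistent with the body-weight SUV convention:
  # SUV = C[kBq/mL] * weight[g] / dose[kBq]  =>  C = SUV * dose/weight
  conc <- suv * (spec$dose_MBq * 1000) / (spec$body_weight_kg * 1000)
  if (spec$noise_cv > 0)
    conc <- with_seed(spec$seed,
      conc * (1 + array(stats::rnorm(length(conc), 0, spec$noise_cv), dims)))
  conc <- pmax(conc, 0)
  list(activity = volume_image(array(conc, dims), spec$voxel_mm),
       dose_MBq = spec$dose_MBq, body_weight_kg = spec$body_weight_kg,
       suv_truth = volume_image(array(suv, dims), spec$voxel_mm))
}

#' Synthetic cohort specification
#'
#' Emulates the structure of the reference study's group comparison: a control
#' group (default 7 subjects), one patient measured before and after
#' treatment, 3 replicate measurements per subject for each of the 4 metrics
#' in each of the 8 ROIs. Replicates are drawn i.i.d. around the control mean
#' with the stated SD (no subject-level random effect, so the replicate-level
#' pooled t-test is exactly calibrated); patient draws are scaled
#' multiplicatively by the before/after effect sizes. Metrics are drawn
#' independently; Tb.N = BVF/Tb.Th holds exactly for image-derived metrics
#' but only statistically here (see the methods vignette).
#'
#' @param n_controls number of control subjects (>= 2).
#' @param control_stats data.frame with columns `roi`, `metric`, `mean`, `sd`;
#'   defaults to the bundled reference control values.
#' @param effects data.frame with columns `roi`, `metric`, `before`, `after`
#'   (multiplicative effect sizes; absent cells default to 1).
#' @param replicates measurements per subject per cell (>= 1).
#' @param family `"lognormal"` (positive metrics, exact-mean
#'   parameterization, default) or `"normal"`.
#' @param seed RNG seed.
#' @returns An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 7L,
                        control_stats = NULL,
                        effects = NULL,
                        replicates = 3L,
                        family = c("lognormal", "normal"),
                        seed = 1L) {
  family <- match.arg(family)
  if (n_controls < 2L) stop_param("n_controls must be >= 2")
  if (replicates < 1L) stop_param("replicates must be >= 1")
  if (is.null(control_stats)) control_stats <- reference_control_stats()
  need <- c("roi", "metric", "mean", "sd")
  if (!all(need %in% names(control_stats))) stop_param("control_stats must have roi, metric, mean, sd")
  if (any(control_stats$sd < 0)) stop_param("SDs must be >= 0")
  if (any(control_stats$mean <= 0)) stop_param("control means must be positive")
  if (is.null(effects))
    effects <- data.frame(roi = character(), metric = character(),
                          before = numeric(), after = numeric())
  structure(list(n_controls = as.integer(n_controls),
                 control_stats = control_stats, effects = effects,
                 replicates = as.integer(replicates), family = family,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_family <- function(n, m, s, family) {
  if (s == 0) return(rep(m, n))
  if (family == "normal") return(stats::rnorm(n, m, s))
  sigma <- sqrt(log1p((s / m)^2))           # exact-mean log-normal
  m * exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Generate a synthetic control/patient cohort
#'
#' @param spec a [cohort_spec()].
#' @returns Long data.frame with columns `subject`, `group`
#'   (`control`/`before`/`after`), `roi`, `metric`, `replicate`, `value`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cs <- spec$control_stats
  eff <- spec$effects
  with_seed(spec$seed, {
    out <- vector("list", nrow(cs))
    for (i in seq_len(nrow(cs))) {
      roi <- cs$roi[i]; metric <- cs$metric[i]
      m <- cs$mean[i]; s <- cs$sd[i]
      e <- eff[eff$roi == roi & eff$metric == metric, ]
      e_b <- if (nrow(e)) e$before[1] else 1
      e_a <- if (nrow(e)) e$after[1] else 1
      ctrl <- draw_family(spec$n_controls * spec$replicates, m, s, spec$family)
      pb <- draw_family(spec$replicates, m * e_b, s * e_b, spec$family)
      pa <- draw_family(spec$replicates, m * e_a, s * e_a, spec$family)
      out[[i]] <- data.frame(
        subject = c(rep(paste0("C", seq_len(spec$n_controls)),
                        each = spec$replicates), rep("P", 2 * spec$replicates)),
        group = c(rep("control", length(ctrl)),
                  rep("before", spec$replicates), rep("after", spec$replicates)),
        roi = roi, metric = metric,
        replicate = c(rep(seq_len(spec$replicates), spec$n_controls),
                      seq_len(spec$replicates), seq_len(spec$replicates)),
        value = c(ctrl, pb, pa))
    }
    do.call(rbind, out)
  })
}
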