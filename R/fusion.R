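#' Standardized uptake value map
#'
#' Body-weight SUV convention with unit tissue density:
#' \deqn{SUV(x) = \frac{C(x)\,[kBq/mL] \cdot weight\,[g]}{dose\,[kBq]}}
#' so a dose distributed uniformly over the whole body gives SUV = 1
#' everywhere, and SUV scales linearly with activity.
#'
#' @param activity a [volume_image()] of activity concentration in kBq/mL.
#' @param dose_MBq injected dose, MBq (> 0).
#' @param weight_kg body weight, kg (> 0).
#' @returns A `volume_image` of class `c("suv_map", "volume_image")` with
#'   attributes `dose_MBq` and `weight_kg`.
#' @export
compute_suv <- function(activity, dose_MBq, weight_kg) {
  stopifnot(inherits(activity, "volume_image"))
  if (!is.finite(dose_MBq) || dose_MBq <= 0) stop_param("dose_MBq must be positive")
  if (!is.finite(weight_kg) || weight_kg <= 0) stop_param("weight_kg must be positive")
  suv <- activity$data * (weight_kg * 1000) / (dose_MBq * 1000)
  out <- volume_image(suv, activity$spacing, activity$origin)
  class(out) <- c("suv_map", class(out))
  attr(out, "dose_MBq") <- dose_MBq
  attr(out, "weight_kg") <- weight_kg
  out
}

#' SUV statistics over an ROI, with hypermetabolic flag
#'
#' @param suv an SUV map ([compute_suv()]).
#' @param roi a non-empty congruent [binary_mask()].
#' @param threshold hypermetabolic threshold; a region is flagged when its
#'   SUVmean is `>= threshold` (inclusive, per the "2.5 or higher"
#'   convention).
#' @param label optional ROI label carried into the output.
#' @returns One-row data.frame: `roi`, `suv_mean`, `suv_sd`, `suv_max`,
#'   `hypermetabolic`.
#' @export
roi_suv_stats <- function(suv, roi, threshold = 2.5, label = "ROI") {
  stopifnot(inherits(suv, "volume_image"), inherits(roi, "binary_mask"))
  stopifnot_congruent(suv, roi, "SUV map and ROI")
  if (!any(roi$data)) stop_input("ROI is empty")
  vals <- suv$data[roi$data]
  m <- mean(vals)
  data.frame(roi = label, suv_mean = m,
             suv_sd = if (length(vals) > 1) stats::sd(vals) else 0,
             suv_max = max(vals),
             hypermetabolic = m >= threshold)
}

#' @rdname roi_suv_stats
#' @param rois an `roi_set` or named list of masks.
#' @export
classify_hypermetabolic <- function(suv, rois, threshold = 2.5) {
  masks <- if (inherits(rois, "roi_set")) rois$masks else rois
  do.call(rbind, lapply(names(masks), function(nm)
    roi_suv_stats(suv, masks[[nm]], threshold, label = nm)))
}

#' Affine transform in homogeneous mm coordinates
#'
#' @param m 4x4 matrix; last row must be (0,0,0,1) and the linear part must
#'   have positive determinant (so the principal matrix logarithm exists).
#' @returns An object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop_param("affine must be 4x4")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop_param("last row of an affine must be (0,0,0,1)")
  if (det(m[1:3, 1:3]) <= 0)
    stop_param("linear part must have positive determinant")
  structure(m, class = "affine_transform")
}

#' @rdname affine_transform
#' @param translation,linear convenience constructor parts.
#' @export
affine_from_parts <- function(linear = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- linear
  m[1:3, 4] <- translation
  affine_transform(m)
}

# ---- dense matrix exp/log for small (4x4) matrices -------------------------

mat_exp <- function(M) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  A <- M / 2^s
  E <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in 1:30) {
    term <- term %*% A / k
    E <- E + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

mat_sqrt <- function(M, tol = 1e-14, maxit = 60L) {
  # Denman-Beavers iteration (principal square root)
  Y <- M; Z <- diag(nrow(M))
  for (i in seq_len(maxit)) {
    Yn <- 0.5 * (Y + solve(Z))
    Zn <- 0.5 * (Z + solve(Y))
    if (max(abs(Yn - Y)) < tol) { Y <- Yn; break }
    Y <- Yn; Z <- Zn
  }
  Y
}

mat_log <- function(M, tol = 1e-13) {
  # inverse scaling and squaring; principal branch (requires det(linear) > 0
  # and no eigenvalues on the closed negative real axis)
  I <- diag(nrow(M))
  k <- 0L
  A <- M
  while (max(abs(A - I)) > 0.25 && k < 60L) {
    A <- mat_sqrt(A)
    k <- k + 1L
  }
  X <- A - I
  L <- matrix(0, nrow(M), ncol(M)); P <- X
  for (n in 1:60) {
    L <- L + (-1)^(n + 1) * P / n
    P <- P %*% X
    if (max(abs(P)) < tol) break
  }
  L * 2^k
}

#' Estimate an affine transform between two bone masks by moment matching
#'
#' Matches centroids (translation), principal axes and per-axis spreads
#' (linear part): with eigendecompositions of the voxel-coordinate
#' covariances \eqn{\Sigma = U S^2 U^T}, the linear map is
#' \eqn{L = U_f D U_m^T} with \eqn{D = diag(s_f / s_m)} (eigenvectors
#' ordered by decreasing eigenvalue, sign-fixed, right-handed). Exact for
#' translations; recovers modest rotations and anisotropic scalings of
#' non-degenerate shapes. When the mass distribution is degenerate (planar
#' or linear: smallest eigenvalue < 1e-8 of the largest), falls back to a
#' similarity transform (isotropic scale from total variance) with a
#' warning.
#'
#' @param fixed,moving non-empty [binary_mask()] objects.
#' @returns An [affine_transform()] mapping moving -> fixed world
#'   coordinates, with attribute `residual` (relative Frobenius covariance
#'   mismatch after alignment).
#' @export
estimate_bone_affine <- function(fixed, moving) {
  stopifnot(inherits(fixed, "binary_mask"), inherits(moving, "binary_mask"))
  if (!any(fixed$data) || !any(moving$data)) stop_input("masks must be non-empty")
  pts <- function(m) voxel_to_world(m, which(m$data, arr.ind = TRUE) - 1)
  Pf <- pts(fixed); Pm <- pts(moving)
  mu_f <- colMeans(Pf); mu_m <- colMeans(Pm)
  Sf <- crossprod(sweep(Pf, 2, mu_f)) / nrow(Pf)
  Sm <- crossprod(sweep(Pm, 2, mu_m)) / nrow(Pm)
  ef <- eigen(Sf, symmetric = TRUE); em <- eigen(Sm, symmetric = TRUE)
  degen <- min(em$values) < 1e-8 * max(em$values) ||
    min(ef$values) < 1e-8 * max(ef$values)
  if (degen) {
    warning("degenerate mass distribution; falling back to similarity transform")
    s <- sqrt(sum(diag(Sf)) / sum(diag(Sm)))
    L <- s * diag(3)
  } else {
    fix_basis <- function(e) {
      U <- e$vectors
      for (j in 1:3) {
        piv <- which.max(abs(U[, j]))
        if (U[piv, j] < 0) U[, j] <- -U[, j]
      }
      if (det(U) < 0) U[, 3] <- -U[, 3]
      U
    }
    Uf <- fix_basis(ef); Um <- fix_basis(em)
    D <- diag(sqrt(ef$values / em$values))
    L <- Uf %*% D %*% t(Um)
  }
  t_vec <- mu_f - L %*% mu_m
  aligned <- L %*% Sm %*% t(L)
  res <- norm(aligned - Sf, "F") / norm(Sf, "F")
  out <- affine_from_parts(L, t_vec)
  attr(out, "residual") <- res
  out
}

#' Poly-affine model: per-bone affines with spatial weights
#'
#' Weight fields default to the indicator of each bone mask smoothed by a
#' Gaussian of `sigma_mm`, normalized voxel-wise to sum to 1 wherever any
#' raw weight is positive.
#'
#' @param bones named list of [binary_mask()] on the target grid.
#' @param affines named list of [affine_transform()] (same names).
#' @param sigma_mm weight smoothing standard deviation, mm.
#' @returns An object of class `polyaffine_model`.
#' @export
polyaffine_model <- function(bones, affines, sigma_mm = 5) {
  if (!length(affines)) stop_param("at least one affine component required")
  if (!setequal(names(bones), names(affines)))
    stop_param("bones and affines must share names")
  ref <- bones[[1]]
  comps <- lapply(names(affines), function(nm) {
    stopifnot_congruent(ref, bones[[nm]], "bone masks")
    A <- affine_transform(unclass(affines[[nm]]))
    w <- smooth_gaussian(bones[[nm]]$data * 1, sigma_mm / ref$spacing)
    list(label = nm, affine = A, weight = w)
  })
  structure(list(components = comps, sigma_mm = sigma_mm,
                 spacing = ref$spacing, origin = ref$origin,
                 dims = dim(ref$data)),
            class = "polyaffine_model")
}

#' Fuse per-bone affines into a dense deformation field (log-Euclidean)
#'
#' Builds the stationary velocity field
#' \eqn{v(x) = \sum_i w_i(x)\,(\log M_i)\,\tilde x} from the normalized
#' smoothed weights and the principal logarithms of the component affines,
#' then exponentiates it by scaling and squaring of the displacement field
#' (`2^K` self-compositions, K chosen so the maximum half-step displacement
#' is below half the smallest voxel). Where the weights are spatially
#' constant the result equals the matrix exponential of the weighted log
#' mean, to integration tolerance; voxels where every raw weight is zero map
#' to identity.
#'
#' @param model a [polyaffine_model()].
#' @param grid optional `volume_image`/`binary_mask` defining the target
#'   grid; defaults to the model's own grid.
#' @returns An object of class `deformation_field`: list with `u` (4D array,
#'   last axis = displacement component, mm), `spacing`, `origin`, `dims`.
#' @export
fuse_polyaffine <- function(model, grid = NULL) {
  stopifnot(inherits(model, "polyaffine_model"))
  dims <- model$dims; spacing <- model$spacing; origin <- model$origin
  if (!is.null(grid)) { dims <- dim(grid$data); spacing <- grid$spacing; origin <- grid$origin }
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims) - 1
  X <- sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)

  wsum <- array(0, dims)
  for (cp in model$components) wsum <- wsum + cp$weight
  v <- matrix(0, n, 3)
  for (cp in model$components) {
    Lg <- mat_log(unclass(cp$affine))
    vi <- X %*% t(Lg[1:3, 1:3])
    vi <- sweep(vi, 2, Lg[1:3, 4], `+`)
    wn <- ifelse(wsum > 0, cp$weight / wsum, 0)
    v <- v + as.vector(wn) * vi
  }

  max_disp <- sqrt(max(rowSums(v^2)))
  K <- 0L
  if (max_disp > 0) {
    # stability: half-step displacement below half the smallest voxel
    K_stab <- max(0L, ceiling(log2(max_disp / (0.5 * min(spacing)))))
    # accuracy: the Euler initialization of scaling-and-squaring has error
    # ~ 0.5 * Lambda * |v| * 2^-K (Lambda = velocity Jacobian bound);
    # keep it below the 1e-3-voxel integration tolerance
    lambda <- 0
    for (comp in 1:3) {
      va <- array(v[, comp], dims)
      for (ax in 1:3) if (dims[ax] > 1L)
        lambda <- max(lambda,
                      max(abs(shift_array(va, ax, 1L, fill = NA) - va), na.rm = TRUE) / spacing[ax])
    }
    tol <- 1e-3 * min(spacing)
    err0 <- 0.5 * 3 * lambda * max_disp * exp(min(3 * lambda, 2))
    K_acc <- if (err0 > tol) ceiling(log2(err0 / tol)) else 0L
    K <- min(max(K_stab, K_acc), 30L)
  }
  u <- v / 2^K
  ux <- array(u[, 1], dims); uy <- array(u[, 2], dims); uz <- array(u[, 3], dims)
  for (step in seq_len(K)) {
    # u <- u + u o (id + u)
    q <- cbind((X[, 1] + as.vector(ux) - origin[1]) / spacing[1],
               (X[, 2] + as.vector(uy) - origin[2]) / spacing[2],
               (X[, 3] + as.vector(uz) - origin[3]) / spacing[3])
    ux2 <- as.vector(ux) + interp_trilinear(ux, q, clamp = TRUE)
    uy2 <- as.vector(uy) + interp_trilinear(uy, q, clamp = TRUE)
    uz2 <- as.vector(uz) + interp_trilinear(uz, q, clamp = TRUE)
    ux <- array(ux2, dims); uy <- array(uy2, dims); uz <- array(uz2, dims)
  }
  u4 <- array(c(ux, uy, uz), c(dims, 3L))
  structure(list(u = u4, spacing = spacing, origin = origin, dims = dims),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<deformation_field> %s grid, |u| mean %.3g mm, max %.3g mm\n",
              paste(x$dims, collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates q (n x 3). clamp = TRUE extrapolates linearly from the border
# cells (exact for affine fields, used by the velocity-field integrator);
# otherwise out-of-grid queries return `outside`.
interp_trilinear <- function(arr, q, clamp = FALSE, outside = 0) {
  d <- dim(arr)
  oob <- q[, 1] < 0 | q[, 1] > d[1] - 1 | q[, 2] < 0 | q[, 2] > d[2] - 1 |
    q[, 3] < 0 | q[, 3] > d[3] - 1
  i0 <- floor(q)
  for (ax in 1:3) i0[, ax] <- pmin(pmax(i0[, ax], 0), max(d[ax] - 2, 0))
  fr <- q - i0                      # outside [0,1] beyond the border cells
  if (!clamp) fr <- pmin(pmax(fr, 0), 1)
  i0 <- i0 + 1                      # 1-based lower corner
  i1 <- pmin(i0 + 1, matrix(d, nrow(q), 3, byrow = TRUE))
  g <- function(a, b, c) arr[cbind(a, b, c)]
  v000 <- g(i0[,1], i0[,2], i0[,3]); v100 <- g(i1[,1], i0[,2], i0[,3])
  v010 <- g(i0[,1], i1[,2], i0[,3]); v110 <- g(i1[,1], i1[,2], i0[,3])
  v001 <- g(i0[,1], i0[,2], i1[,3]); v101 <- g(i1[,1], i0[,2], i1[,3])
  v011 <- g(i0[,1], i1[,2], i1[,3]); v111 <- g(i1[,1], i1[,2], i1[,3])
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  out <- (1-fx)*(1-fy)*(1-fz)*v000 + fx*(1-fy)*(1-fz)*v100 +
    (1-fx)*fy*(1-fz)*v010 + fx*fy*(1-fz)*v110 +
    (1-fx)*(1-fy)*fz*v001 + fx*(1-fy)*fz*v101 +
    (1-fx)*fy*fz*v011 + fx*fy*fz*v111
  if (!clamp) out[oob] <- outside
  attr(out, "n_outside") <- sum(oob)
  out
}

interp_nearest <- function(arr, q, outside = 0) {
  d <- dim(arr)
  oob <- q[, 1] < 0 | q[, 1] > d[1] - 1 | q[, 2] < 0 | q[, 2] > d[2] - 1 |
    q[, 3] < 0 | q[, 3] > d[3] - 1
  qc <- round(q) + 1
  for (ax in 1:3) qc[, ax] <- pmin(pmax(qc[, ax], 1), d[ax])
  out <- arr[qc]
  out[oob] <- outside
  attr(out, "n_outside") <- sum(oob)
  out
}

#' Warp a volume through a deformation field (pull-back)
#'
#' `out(x) = v(x + u(x))`: for every target voxel the displaced world point
#' is sampled in the source volume, linearly for intensity data and
#' nearest-neighbour for masks. Points falling outside the source grid get
#' the background value; their count is reported in attribute `n_outside`.
#'
#' @param v source [volume_image()] (or [binary_mask()] with
#'   `interp = "nearest"`).
#' @param field a `deformation_field` on the target grid.
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill value outside the source grid.
#' @returns A [volume_image()] on the target grid.
#' @export
warp_volume <- function(v, field, interp = c("linear", "nearest"), background = 0) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "deformation_field"))
  n <- prod(field$dims)
  idx <- arrayInd(seq_len(n), field$dims) - 1
  X <- sweep(sweep(idx, 2, field$spacing, `*`), 2, field$origin, `+`)
  Xs <- X + cbind(as.vector(field$u[, , , 1]), as.vector(field$u[, , , 2]),
                  as.vector(field$u[, , , 3]))
  q <- sweep(sweep(Xs, 2, v$origin, `-`), 2, v$spacing, `/`)
  src <- if (inherits(v, "binary_mask")) v$data * 1 else v$data
  vals <- if (interp == "linear") interp_trilinear(src, q, outside = background)
  else interp_nearest(src, q, outside = background)
  out <- volume_image(array(as.numeric(vals), field$dims), field$spacing, field$origin)
  attr(out, "n_outside") <- attr(vals, "n_outside")
  out
}
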