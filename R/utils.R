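# Shared numerics: array shifts, separable Gaussian smoothing, exact squared
# Euclidean distance transforms, and scoped RNG. No image-processing package
# ships with the target R installation, so these are implemented here.

# Shift an array along one axis by `by` (positive = toward higher indices),
# padding with `fill`.
shift_array <- function(a, axis, by, fill = 0) {
  d <- dim(a); n <- d[axis]
  if (by == 0) return(a)
  out <- array(fill, d)
  idx_src <- rep(list(quote(expr = )), length(d))
  idx_dst <- idx_src
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (by + 1):n; idx_src[[axis]] <- 1:(n - by) }
  else        { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  do.call(`[<-`, c(list(out), idx_dst,
                   list(do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
}

gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 2D/3D array; sigma in pixels per axis
# (recycled). Zero padding at the borders.
smooth_gaussian <- function(a, sigma_px) {
  d <- dim(a)
  sigma_px <- rep_len(sigma_px, length(d))
  for (ax in seq_along(d)) {
    k <- gaussian_kernel_1d(sigma_px[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    acc <- array(0, d)
    for (l in seq_along(k))
      acc <- acc + k[l] * shift_array(a, ax, l - 1L - r)
    a <- acc
  }
  a
}

# 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher): given
# parabolas (x - pos_j)^2 + val_j with finite heights at positions pos
# (strictly increasing), evaluate min_j at the (increasing) query points
# `at`. Positions may be integers while queries sit on the half grid.
dt1d_env <- function(pos, val, at) {
  m <- length(pos)
  if (m == 0L) return(rep(Inf, length(at)))
  v <- integer(m); z <- numeric(m + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  if (m > 1L) for (qi in 2:m) {
    q <- pos[qi]
    repeat {
      p <- pos[v[k]]
      s <- ((val[qi] + q^2) - (val[v[k]] + p^2)) / (2 * q - 2 * p)
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- qi; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(length(at))
  k <- 1L
  for (i in seq_along(at)) {
    x <- at[i]
    while (z[k + 1L] < x) k <- k + 1L
    d[i] <- (x - pos[v[k]])^2 + val[v[k]]
  }
  d
}

# Exact squared Euclidean distance (in pixels) from every TRUE pixel of a 2D
# logical matrix to the nearest FALSE pixel, with everything outside the image
# treated as background. Background pixels get 0.
edt_sq_2d <- function(mask) {
  edt_sq_grid(mask, offset = 0)
}

# Same, but measured from the half-grid points c = (i + 0.5, j + 0.5),
# i in 1..nrow-1, j in 1..ncol-1 (the centres of every 2x2 pixel block);
# returns an (nrow-1) x (ncol-1) matrix.
edt_sq_2d_offset <- function(mask) {
  edt_sq_grid(mask, offset = 0.5)
}

edt_sq_grid <- function(mask, offset) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  np_r <- nr + 2L; np_c <- nc + 2L
  at_c <- if (offset == 0) 2:(np_c - 1L) else (2:(np_c - 2L)) + 0.5
  at_r <- if (offset == 0) 2:(np_r - 1L) else (2:(np_r - 2L)) + 0.5
  # pass 1: per row, distance^2 to background columns, at query columns
  g <- matrix(Inf, np_r, length(at_c))
  for (i in seq_len(np_r)) {
    bg <- which(!padded[i, ])
    if (length(bg)) g[i, ] <- dt1d_env(bg, numeric(length(bg)), at_c)
  }
  # pass 2: per query column, envelope over rows
  out <- matrix(0, length(at_r), length(at_c))
  for (j in seq_along(at_c)) {
    fin <- which(is.finite(g[, j]))
    out[, j] <- dt1d_env(fin, g[fin, j], at_r)
  }
  out
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stream index, kept below 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647)
}

# sample mean/sd helpers used by the reporting layer
mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))
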