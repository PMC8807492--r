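# Internal array helpers shared by the phantom generator and the denoiser.

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift an array along one axis by `offset`, clamping indices at the borders
# (replicate padding).
shift_clamped <- function(arr, axis, offset) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(a) seq_len(d[a]))
  idx[[axis]] <- pmin(pmax(idx[[axis]] + offset, 1L), d[axis])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# Separable Gaussian smoothing with replicate edge handling; works for 2D
# matrices and 3D arrays. sigma may be scalar (applied in-plane and, for 3D,
# along the slice axis too) or one value per axis.
gaussian_smooth <- function(arr, sigma) {
  d <- dim(arr)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(d))
  out <- arr
  for (axis in seq_along(d)) {
    if (sigma[axis] <= 0 || d[axis] == 1L) next
    k <- gauss_kernel1d(sigma[axis])
    r <- (length(k) - 1L) %/% 2L
    acc <- array(0, dim = d)
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_clamped(out, axis, j - r - 1L)
    out <- acc
  }
  out
}

# Band-limited unit-variance field: smoothed white noise standardized over the
# whole grid. Used for tissue heterogeneity and displacement fields.
bandlimited_field <- function(shape, corr_sigma) {
  f <- array(stats::rnorm(prod(shape)), dim = shape)
  f <- gaussian_smooth(f, corr_sigma)
  (f - mean(f)) / stats::sd(as.vector(f))
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
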