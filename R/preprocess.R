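#' Denoise an intensity volume
#'
#' Edge-preserving or Gaussian noise filtering applied to the whole raster;
#' the validity mask and spacing are untouched. `strength = 0` is the
#' identity. Gaussian filtering uses `strength` as the kernel standard
#' deviation in pixels; non-local means uses it as the filtering bandwidth
#' `h` in intensity units.
#'
#' @param vol An [intensity_volume()].
#' @param method `"gaussian"` (default) or `"nlm"` (non-local means, 2D
#'   per-slice, 5x5 search window, 3x3 patches).
#' @param strength Nonnegative filter strength (see above).
#' @return A denoised [intensity_volume()].
#' @export
denoise <- function(vol, method = c("gaussian", "nlm"), strength = 0.5) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  method <- match.arg(method)
  if (strength < 0) stop("`strength` must be >= 0")
  if (strength == 0) return(vol)
  d <- dim(vol$data)
  out <- if (method == "gaussian") {
    sig <- rep(strength, length(d))
    gaussian_smooth(vol$data, sig)
  } else {
    if (length(d) == 2L) {
      nlm_denoise_2d(vol$data, strength, 2L, 1L)
    } else {
      arr <- vol$data
      for (z in seq_len(d[3]))
        arr[, , z] <- nlm_denoise_2d(vol$data[, , z], strength, 2L, 1L)
      arr
    }
  }
  intensity_volume(out, vol$spacing, vol$mask)
}

# order-2 polynomial basis over normalized coordinates
poly_basis <- function(coords) {
  nd <- ncol(coords)
  cols <- list(rep(1, nrow(coords)))
  for (a in seq_len(nd)) cols[[length(cols) + 1L]] <- coords[, a]
  for (a in seq_len(nd))
    for (b in a:nd) cols[[length(cols) + 1L]] <- coords[, a] * coords[, b]
  do.call(cbind, cols)
}

grid_coords <- function(d) {
  idx <- arrayInd(seq_len(prod(d)), d)
  sweep(sweep(idx, 2, (d + 1) / 2, "-"), 2, pmax(d - 1, 1) / 2, "/")
}

#' Estimate and remove a multiplicative bias field
#'
#' Fits a smooth, strictly positive multiplicative intensity field to the
#' masked positive pixels by a robust (Tukey-reweighted) order-2 polynomial
#' regression of log-intensity on image coordinates, the standard homomorphic
#' surface-fit approach to MR intensity inhomogeneity. The field is
#' normalized to mean 1 over the mask so the global intensity scale is
#' preserved, and the image is divided by it.
#'
#' @param vol An [intensity_volume()] with at least one masked positive pixel.
#' @param iterations Robust reweighting iterations.
#' @return A list with `volume` (corrected [intensity_volume()]) and `field`
#'   (the estimated field, same shape as the image, mean 1 over the mask).
#' @export
correct_bias_field <- function(vol, iterations = 10L) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  d <- dim(vol$data)
  sel <- vol$mask & vol$data > 0
  if (!any(sel)) stop("bias field indeterminate: no masked positive pixels")
  co <- grid_coords(d)
  Xall <- poly_basis(co)
  X <- Xall[as.vector(sel), , drop = FALSE]
  y <- log(vol$data[sel])
  w <- rep(1, length(y))
  for (it in seq_len(iterations)) {
    fit <- stats::lm.wfit(X, y, w)
    r <- y - X %*% fit$coefficients
    s <- stats::mad(r)
    if (s <= 0) break
    u <- abs(r) / (4.685 * s)
    w <- as.vector(ifelse(u < 1, (1 - u^2)^2, 0))
    if (sum(w > 0) < ncol(X)) { w <- rep(1, length(y)); break }
  }
  beta <- stats::lm.wfit(X, y, w)$coefficients
  beta[is.na(beta)] <- 0
  field <- array(exp(Xall %*% beta), dim = d)
  field <- field / mean(field[vol$mask])
  corrected <- vol$data / field
  list(volume = intensity_volume(corrected, vol$spacing, vol$mask),
       field = field)
}

# linear (or nearest) interpolation of an array along one axis onto new
# physical positions; positions are pixel-center coordinates.
interp_axis <- function(arr, axis, old_pos, new_pos, nearest = FALSE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  fi <- approx(old_pos, seq_along(old_pos), xout = new_pos, rule = 2)$y
  if (nearest) {
    out <- m[round(fi), , drop = FALSE]
  } else {
    i0 <- pmax(1L, pmin(length(old_pos) - 1L, floor(fi)))
    w <- fi - i0
    out <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1L, , drop = FALSE] * w
  }
  nd <- d; nd[axis] <- length(new_pos)
  b <- array(out, dim = nd[perm])
  aperm(b, order(perm))
}

#' Resample to isotropic voxel spacing
#'
#' Linear interpolation of intensities (nearest neighbor for the validity
#' mask) onto a grid with equal spacing on all axes, preserving the physical
#' extent within one voxel. The default target is the smallest input spacing,
#' i.e. upsampling with the minimum interpolation factor.
#'
#' @param vol An [intensity_volume()].
#' @param target_spacing Target spacing in micrometres (scalar, > 0).
#' @return A resampled [intensity_volume()].
#' @export
resample_isotropic <- function(vol, target_spacing = NULL) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  if (is.null(target_spacing)) target_spacing <- min(vol$spacing)
  if (target_spacing <= 0) stop("`target_spacing` must be > 0")
  d <- dim(vol$data)
  if (all(abs(vol$spacing - target_spacing) < 1e-9)) return(vol)
  dat <- vol$data
  msk <- vol$mask + 0
  for (axis in seq_along(d)) {
    n <- dim(dat)[axis]
    sp <- vol$spacing[axis]
    if (abs(sp - target_spacing) < 1e-9) next
    old_pos <- (seq_len(n) - 1) * sp
    n_new <- round((n - 1) * sp / target_spacing) + 1L
    new_pos <- (seq_len(n_new) - 1) * target_spacing
    dat <- interp_axis(dat, axis, old_pos, new_pos)
    msk <- interp_axis(msk, axis, old_pos, new_pos, nearest = TRUE)
  }
  intensity_volume(dat, rep(target_spacing, length(d)), msk > 0.5)
}

#' Mean +/- 3 SD intensity outlier filtering
#'
#' Computes the mean and standard deviation of the masked intensities and
#' removes pixels falling outside the three-sigma band from the validity mask
#' (IBSI-style resegmentation: exclusion, not clipping). Intensities are left
#' untouched; if the masked distribution is constant the mask is unchanged.
#'
#' @param vol An [intensity_volume()] with a nonempty mask.
#' @return An [intensity_volume()] with the updated mask.
#' @export
filter_outliers <- function(vol) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  if (!any(vol$mask)) stop("mask is empty")
  v <- vol$data[vol$mask]
  mu <- mean(v); s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(vol)
  keep <- vol$data >= mu - 3 * s & vol$data <= mu + 3 * s
  intensity_volume(vol$data, vol$spacing, vol$mask & keep)
}

masked_summary <- function(vol) {
  v <- vol$data[vol$mask]
  c(n = length(v), mean = mean(v), sd = stats::sd(v),
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_)
}

#' Full preprocessing chain
#'
#' Applies, in order: noise filtering, multiplicative bias-field correction,
#' interpolation to isotropic voxel size, and mean +/- 3 SD intensity outlier
#' filtering. Each stage's masked-intensity summary is recorded so specimen
#' exclusion situations remain auditable.
#'
#' @param vol An [intensity_volume()].
#' @param denoise_method,denoise_strength Passed to [denoise()].
#' @param bias_correction Logical; skip bias-field estimation if `FALSE`.
#' @param target_spacing Passed to [resample_isotropic()].
#' @param verbose Print per-stage summaries.
#' @return A list with `volume` (the preprocessed [intensity_volume()]),
#'   `bias_field` (estimated field or `NULL`) and `stages` (a data.frame of
#'   per-stage masked summaries).
#' @export
preprocess <- function(vol, denoise_method = "gaussian",
                       denoise_strength = 0.5, bias_correction = TRUE,
                       target_spacing = NULL, verbose = FALSE) {
  stages <- list(input = masked_summary(vol))
  vol <- denoise(vol, denoise_method, denoise_strength)
  stages$denoise <- masked_summary(vol)
  field <- NULL
  if (bias_correction) {
    bc <- correct_bias_field(vol)
    vol <- bc$volume
    field <- bc$field
    stages$bias <- masked_summary(vol)
  }
  vol <- resample_isotropic(vol, target_spacing)
  stages$resample <- masked_summary(vol)
  vol <- filter_outliers(vol)
  stages$outliers <- masked_summary(vol)
  stages <- data.frame(stage = names(stages),
                       do.call(rbind, stages), row.names = NULL)
  if (verbose) print(stages)
  list(volume = vol, bias_field = field, stages = stages)
}
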