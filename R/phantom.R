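#' Phantom generator configuration
#'
#' Parameters of the synthetic MR-microscopy phantom. The phantom emulates the
#' qualitative contrasts of ex vivo MRM of high-grade serous ovarian cancer
#' implants: bright, fairly uniform tumor lobules clustered inside a tissue
#' envelope ("cauliflower" morphology), darker and spatially heterogeneous
#' stroma between the lobules, an optional peripheral fat rim, small
#' zero-signal structures (glandular lumens, psammoma bodies), a smooth
#' multiplicative bias field, and Rician or Gaussian noise. A perfectly
#' co-registered ground-truth label map is produced alongside the image.
#'
#' @param image_shape Integer vector, 2 (slice) or 3 (stack) entries; each
#'   in-plane axis must be at least 32 px.
#' @param voxel_spacing Micrometres per axis; the default mirrors a
#'   90 x 90 (x 180) um acquisition grid.
#' @param n_lobules Maximum number of tumor lobules; placement stops early
#'   once `target_stroma_fraction` is reached.
#' @param lobule_radius_range Min/max lobule semi-axis, pixels.
#' @param target_stroma_fraction Desired stroma / (stroma + tumor) area
#'   fraction inside the tissue envelope.
#' @param tumor_mean_SI,stroma_mean_SI,fat_mean_SI Mean signal intensity per
#'   tissue, arbitrary units; defaults satisfy tumor > stroma (tumor appears
#'   bright, stroma darker).
#' @param tumor_texture_scale,stroma_texture_scale Dimensionless heterogeneity
#'   amplitudes (relative SI fluctuation); defaults satisfy stroma > tumor so
#'   stroma is the texturally heterogeneous compartment.
#' @param texture_corr_length Correlation length of the heterogeneity fields,
#'   pixels.
#' @param fat_rim_frac Fraction of the envelope's normalized radius occupied
#'   by the peripheral fat rim; 0 disables fat.
#' @param n_voids Number of zero-signal structures.
#' @param void_radius_range Min/max void radius, pixels.
#' @param bias_field_amplitude Fractional amplitude of the multiplicative bias
#'   field; 0 disables it.
#' @param bias_field_type `"blob"` (broad Gaussian) or `"ramp"` (linear).
#' @param noise_sigma Noise standard deviation, intensity units.
#' @param noise_model `"rician"` (magnitude MR data, default) or `"gaussian"`.
#' @param misalignment_amplitude Maximum displacement (pixels) applied to the
#'   label map after generation; 0 keeps the pair perfectly registered.
#' @param seed Integer RNG seed; identical seed + config give bit-identical
#'   phantoms.
#' @return A `phantom_config` list.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(image_shape = c(128L, 128L),
                           voxel_spacing = NULL,
                           n_lobules = 200L,
                           lobule_radius_range = c(6, 12),
                           target_stroma_fraction = 0.5,
                           tumor_mean_SI = 100,
                           stroma_mean_SI = 60,
                           fat_mean_SI = 80,
                           tumor_texture_scale = 0.05,
                           stroma_texture_scale = 0.35,
                           texture_corr_length = 1.2,
                           fat_rim_frac = 0.12,
                           n_voids = 6L,
                           void_radius_range = c(1.5, 3),
                           bias_field_amplitude = 0.2,
                           bias_field_type = c("blob", "ramp"),
                           noise_sigma = 2,
                           noise_model = c("rician", "gaussian"),
                           misalignment_amplitude = 0,
                           seed = 1L) {
  image_shape <- as.integer(image_shape)
  nd <- length(image_shape)
  if (!(nd %in% c(2L, 3L))) stop("`image_shape` must have 2 or 3 entries")
  if (any(image_shape[1:2] < 32L))
    stop("in-plane axes must be at least 32 px")
  if (is.null(voxel_spacing))
    voxel_spacing <- if (nd == 2L) c(90, 90) else c(90, 90, 180)
  means <- c(tumor_mean_SI, stroma_mean_SI, fat_mean_SI)
  if (any(means < 0)) stop("mean signal intensities must be >= 0")
  if (max(lobule_radius_range) >= min(image_shape[1:2]) / 2)
    stop("lobule radius exceeds half the in-plane image size")
  if (target_stroma_fraction <= 0 || target_stroma_fraction >= 1)
    stop("`target_stroma_fraction` must be in (0,1)")
  cfg <- list(image_shape = image_shape,
              voxel_spacing = as.numeric(voxel_spacing),
              n_lobules = as.integer(n_lobules),
              lobule_radius_range = as.numeric(lobule_radius_range),
              target_stroma_fraction = target_stroma_fraction,
              tumor_mean_SI = tumor_mean_SI,
              stroma_mean_SI = stroma_mean_SI,
              fat_mean_SI = fat_mean_SI,
              tumor_texture_scale = tumor_texture_scale,
              stroma_texture_scale = stroma_texture_scale,
              texture_corr_length = texture_corr_length,
              fat_rim_frac = fat_rim_frac,
              n_voids = as.integer(n_voids),
              void_radius_range = as.numeric(void_radius_range),
              bias_field_amplitude = bias_field_amplitude,
              bias_field_type = match.arg(bias_field_type),
              noise_sigma = noise_sigma,
              noise_model = match.arg(noise_model),
              misalignment_amplitude = misalignment_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# In-plane pixel-center coordinate grids as matrices (row, col).
plane_coords <- function(shape2) {
  list(x = matrix(seq_len(shape2[1]), shape2[1], shape2[2]),
       y = matrix(seq_len(shape2[2]), shape2[1], shape2[2], byrow = TRUE))
}

# One 2D slice of labels; `zfrac` in [-1,1] scales lobule/void cross-sections
# for 3D stacks (ellipsoid sections).
phantom_slice_labels <- function(shape2, lobules, voids, fat_rim_frac) {
  lab <- matrix(0L, shape2[1], shape2[2])
  co <- plane_coords(shape2)
  cx <- (shape2[1] + 1) / 2; cy <- (shape2[2] + 1) / 2
  a <- 0.42 * shape2[1]; b <- 0.42 * shape2[2]
  re <- sqrt(((co$x - cx) / a)^2 + ((co$y - cy) / b)^2)
  inside <- re <= 1
  lab[inside] <- 2L                                   # stroma by default
  if (fat_rim_frac > 0) lab[inside & re > 1 - fat_rim_frac] <- 3L
  for (lb in lobules) {
    if (lb$r2 <= 0) next
    dx <- co$x - lb$cx; dy <- co$y - lb$cy
    u <- dx * cos(lb$th) + dy * sin(lb$th)
    v <- -dx * sin(lb$th) + dy * cos(lb$th)
    hit <- (u / lb$r1)^2 + (v / lb$r2)^2 <= 1 & lab == 2L
    lab[hit] <- 1L
  }
  for (vd in voids) {
    if (vd$r <= 0) next
    hit <- (co$x - vd$cx)^2 + (co$y - vd$cy)^2 <= vd$r^2 & lab %in% c(1L, 2L)
    lab[hit] <- 4L
  }
  lab
}

#' Generate a synthetic MRM phantom with ground-truth labels
#'
#' Draws tumor lobules as random rotated ellipses inside an elliptical tissue
#' envelope until the target stromal fraction is reached; the remaining
#' envelope is stroma, with an optional peripheral fat rim and zero-signal
#' voids. Tissue intensities are the configured means modulated by
#' band-limited heterogeneity fields (stroma more heterogeneous than tumor by
#' default), then a smooth multiplicative bias field and noise are applied to
#' the image only. The label map is exactly co-registered unless
#' `misalignment_amplitude > 0`.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `image` ([intensity_volume()]), `labels`
#'   ([label_map()]), `bias_field` (the true multiplicative field, same shape
#'   as the image) and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(image_shape = c(64, 64), seed = 3))
#' mean(ph$image$data[ph$labels$labels == 1]) >
#'   mean(ph$image$data[ph$labels$labels == 2])
#' @export
generate_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) stop("`config` must be a phantom_config")
  with_seed(config$seed, {
    shp <- config$image_shape
    nd <- length(shp)
    shape2 <- shp[1:2]
    nz <- if (nd == 3L) shp[3] else 1L

    # lobule placement with a stopping rule on the stromal fraction
    cx <- (shape2[1] + 1) / 2; cy <- (shape2[2] + 1) / 2
    a <- 0.42 * shape2[1]; b <- 0.42 * shape2[2]
    lobules <- list()
    probe <- phantom_slice_labels(shape2, lobules, list(), config$fat_rim_frac)
    for (k in seq_len(config$n_lobules)) {
      ts <- sum(probe == 2L); tt <- sum(probe == 1L)
      if (tt + ts > 0 && ts / (tt + ts) <= config$target_stroma_fraction) break
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.8
      lb <- list(cx = cx + rad * a * cos(ang), cy = cy + rad * b * sin(ang),
                 r1 = stats::runif(1, config$lobule_radius_range[1],
                                   config$lobule_radius_range[2]),
                 r2 = stats::runif(1, config$lobule_radius_range[1],
                                   config$lobule_radius_range[2]),
                 th = stats::runif(1, 0, pi),
                 cz = stats::runif(1, 1, nz),
                 rz = if (nz == 1L) 1 else stats::runif(1, max(2, nz / 3), nz))
      lobules[[length(lobules) + 1L]] <- lb
      probe <- phantom_slice_labels(shape2, lobules, list(), config$fat_rim_frac)
    }
    voids <- lapply(seq_len(config$n_voids), function(k) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.75
      list(cx = cx + rad * a * cos(ang), cy = cy + rad * b * sin(ang),
           r = stats::runif(1, config$void_radius_range[1],
                            config$void_radius_range[2]),
           cz = stats::runif(1, 1, nz))
    })

    # assemble the label stack (ellipsoid sections for 3D)
    lab <- array(0L, dim = if (nd == 3L) shp else c(shape2, 1L))
    for (z in seq_len(nz)) {
      lz <- lapply(lobules, function(lb) {
        s <- 1 - ((z - lb$cz) / lb$rz)^2
        sc <- if (s > 0) sqrt(s) else 0
        list(cx = lb$cx, cy = lb$cy, r1 = lb$r1 * sc, r2 = lb$r2 * sc, th = lb$th)
      })
      vz <- lapply(voids, function(vd) {
        s <- 1 - ((z - vd$cz) / max(1.5, nz / 2))^2
        list(cx = vd$cx, cy = vd$cy, r = vd$r * if (s > 0) sqrt(s) else 0)
      })
      lab[, , z] <- phantom_slice_labels(shape2, lz, vz, config$fat_rim_frac)
    }
    if (nd == 2L) lab <- array(lab[, , 1L], dim = shape2)

    # intensities: mean SI modulated by band-limited heterogeneity
    img <- array(0, dim = dim(lab))
    cl <- config$texture_corr_length
    mk_field <- function() bandlimited_field(dim(lab), cl)
    for (tis in list(list(code = 1L, mu = config$tumor_mean_SI,
                          sc = config$tumor_texture_scale),
                     list(code = 2L, mu = config$stroma_mean_SI,
                          sc = config$stroma_texture_scale),
                     list(code = 3L, mu = config$fat_mean_SI, sc = 0.05))) {
      sel <- lab == tis$code
      if (!any(sel)) next
      f <- if (tis$sc > 0) mk_field() else array(0, dim = dim(lab))
      img[sel] <- pmax(0, tis$mu * (1 + tis$sc * f[sel]))
    }

    # multiplicative bias field (image only), mean 1 over tissue
    tissue <- lab != 0L
    if (config$bias_field_amplitude > 0) {
      if (config$bias_field_type == "blob") {
        co <- plane_coords(shape2)
        bcx <- stats::runif(1, 0.25, 0.75) * shape2[1]
        bcy <- stats::runif(1, 0.25, 0.75) * shape2[2]
        s <- 0.6 * min(shape2)
        g2 <- exp(-((co$x - bcx)^2 + (co$y - bcy)^2) / (2 * s^2))
        bf <- array(rep(1 + config$bias_field_amplitude * (2 * g2 - 1), nz),
                    dim = dim(lab))
      } else {
        ramp <- (seq_len(shape2[1]) - 1) / (shape2[1] - 1) - 0.5
        bf <- array(1 + config$bias_field_amplitude * 2 *
                      matrix(ramp, shape2[1], shape2[2]), dim = dim(lab))
      }
      bf <- bf / mean(bf[tissue])
    } else {
      bf <- array(1, dim = dim(lab))
    }
    img <- img * bf

    # acquisition noise
    if (config$noise_sigma > 0) {
      n1 <- array(stats::rnorm(length(img), 0, config$noise_sigma), dim = dim(img))
      if (config$noise_model == "gaussian") {
        img <- img + n1
      } else {
        n2 <- array(stats::rnorm(length(img), 0, config$noise_sigma), dim = dim(img))
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }

    labels <- label_map(lab, config$voxel_spacing)
    if (config$misalignment_amplitude > 0)
      labels <- inject_misalignment(labels, config$misalignment_amplitude,
                                    seed = config$seed + 1L)
    list(image = intensity_volume(img, config$voxel_spacing, mask = tissue),
         labels = labels,
         bias_field = bf,
         config = config)
  })
}

#' Warp a label map by a smooth random displacement field
#'
#' Stress-test surrogate for imperfect histology-to-MR co-registration: the
#' label raster is resampled (nearest neighbor) through a band-limited random
#' in-plane displacement field whose maximum magnitude is approximately
#' `amplitude` pixels. `amplitude = 0` returns the input unchanged.
#'
#' @param labmap A [label_map()].
#' @param amplitude Maximum displacement, pixels (>= 0).
#' @param seed Integer RNG seed.
#' @return A [label_map()] with the same shape, spacing and label dictionary.
#' @export
inject_misalignment <- function(labmap, amplitude, seed = 1L) {
  if (!is_labmap(labmap)) stop("`labmap` must be a label_map")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(labmap)
  with_seed(seed, {
    d <- dim(labmap$labels)
    nd <- length(d)
    shape2 <- d[1:2]
    dx <- bandlimited_field(shape2, corr_sigma = 8)
    dy <- bandlimited_field(shape2, corr_sigma = 8)
    mx <- max(abs(dx), abs(dy))
    dx <- dx / mx * amplitude
    dy <- dy / mx * amplitude
    co <- plane_coords(shape2)
    sx <- pmin(pmax(round(co$x - dx), 1), shape2[1])
    sy <- pmin(pmax(round(co$y - dy), 1), shape2[2])
    flat <- cbind(as.vector(sx), as.vector(sy))
    warp_slice <- function(sl) {
      matrix(sl[flat], shape2[1], shape2[2])
    }
    out <- if (nd == 2L) {
      warp_slice(labmap$labels)
    } else {
      arr <- labmap$labels
      for (z in seq_len(d[3])) arr[, , z] <- warp_slice(labmap$labels[, , z])
      arr
    }
    label_map(out, labmap$spacing, labmap$dict)
  })
}
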