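# Independent brute-force references used as oracles. These deliberately do
# not call the package's windowed/vectorized code paths.

# dense symmetric GLCM counts for one pixel's window and one offset
ref_glcm_counts <- function(lev, cx, cy, radius, dx, dy, G) {
  n <- nrow(lev); m <- ncol(lev)
  x0 <- max(1, cx - radius); x1 <- min(n, cx + radius)
  y0 <- max(1, cy - radius); y1 <- min(m, cy + radius)
  C <- matrix(0, G, G)
  for (a in x0:x1) for (b in y0:y1) {
    la <- lev[a, b]
    if (is.na(la)) next
    a2 <- a + dx; b2 <- b + dy
    if (a2 < x0 || a2 > x1 || b2 < y0 || b2 > y1) next
    lb <- lev[a2, b2]
    if (is.na(lb)) next
    C[la + 1, lb + 1] <- C[la + 1, lb + 1] + 1
    C[lb + 1, la + 1] <- C[lb + 1, la + 1] + 1
  }
  C
}

# 13 features from a normalized GLCM, straight from the formulas
ref_features <- function(P) {
  G <- nrow(P)
  iv <- 0:(G - 1)
  I <- matrix(iv, G, G); J <- t(I)
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  mux <- sum(I * P); muy <- sum(J * P)
  sx <- sqrt(sum((I - mux)^2 * P)); sy <- sqrt(sum((J - muy)^2 * P))
  psum <- sapply(0:(2 * G - 2), function(k) sum(P[(I + J) == k]))
  pdif <- sapply(0:(G - 1), function(k) sum(P[abs(I - J) == k]))
  mud <- sum((0:(G - 1)) * pdif)
  c(energy = sum(P^2),
    contrast = sum((I - J)^2 * P),
    entropy = -sum(P * lg(P)),
    homogeneity = sum(P / (1 + (I - J)^2)),
    dissimilarity = sum(abs(I - J) * P),
    correlation = if (sx * sy > 0) sum((I - mux) * (J - muy) * P) / (sx * sy) else 0,
    variance = sum((I - mux)^2 * P),
    sum_average = sum((0:(2 * G - 2)) * psum),
    sum_entropy = -sum(psum * lg(psum)),
    difference_variance = sum(((0:(G - 1)) - mud)^2 * pdif),
    difference_entropy = -sum(pdif * lg(pdif)),
    autocorrelation = sum(I * J * P),
    cluster_tendency = sum((I + J - mux - muy)^2 * P))
}

# full naive per-pixel texture maps (2D, direction-averaged)
ref_texture_maps <- function(lev, G, radius = 3, offsets = rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) {
  n <- nrow(lev); m <- ncol(lev)
  fn <- haralick_feature_names()
  maps <- array(NA_real_, dim = c(n, m, length(fn)))
  for (cx in 1:n) for (cy in 1:m) {
    if (is.na(lev[cx, cy])) next
    acc <- NULL; ndir <- 0
    for (o in seq_len(nrow(offsets))) {
      C <- ref_glcm_counts(lev, cx, cy, radius, offsets[o, 1], offsets[o, 2], G)
      if (sum(C) == 0) next
      f <- ref_features(C / sum(C))
      acc <- if (is.null(acc)) f else acc + f
      ndir <- ndir + 1
    }
    if (ndir > 0) maps[cx, cy, ] <- acc / ndir
  }
  dimnames(maps) <- list(NULL, NULL, fn)
  maps
}

# quantized_volume from a bare integer level matrix (NA = invalid)
qv_from_levels <- function(lev, G, spacing = c(90, 90)) {
  structure(list(levels = array(as.integer(lev), dim = dim(lev)), G = as.integer(G),
                 mask = !is.na(lev), spacing = spacing,
                 bounds = c(min = 0, max = G - 1)),
            class = "quantized_volume")
}

# small default phantom used across tests
test_phantom <- function(seed = 1, shape = c(96, 96), ...) {
  generate_phantom(phantom_config(image_shape = shape, seed = seed, ...))
}

# phantom -> (stack, prop) pair via the standard chain
phantom_maps <- function(ph, G = 64, radius = 3) {
  pp <- preprocess(ph$image)
  q <- quantize(pp$volume, G = G)
  stack <- texture_map(q, radius = radius, si = pp$volume)
  rl <- resample_labels(ph$labels, dim(pp$volume$data), pp$volume$spacing)
  prop <- stromal_proportion(rl, radius = 3)
  list(stack = stack, prop = prop)
}
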