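#' Names of the 13 Haralick features
#'
#' Order used throughout the package for feature vectors, map stacks, tables
#' and reports.
#'
#' @return Character vector of length 13.
#' @export
haralick_feature_names <- function() {
  c("energy", "contrast", "entropy", "homogeneity", "dissimilarity",
    "correlation", "variance", "sum_average", "sum_entropy",
    "difference_variance", "difference_entropy", "autocorrelation",
    "cluster_tendency")
}

#' Gray-level quantization
#'
#' Fixed-bin-number quantization of the masked intensities to `G` gray levels
#' over the masked `[min, max]` range:
#' `level = floor(G * (x - min) / (max - min))`, with `x = max` mapped to
#' `G - 1`. The dynamic range is reduced to 64 levels by default. Quantization
#' bounds are global over the mask (computed after outlier filtering when the
#' standard chain is used), not per window, so inter-regional signal contrast
#' is preserved. Invalid pixels are left unquantized (`NA`).
#'
#' @param vol An [intensity_volume()] with a nonempty mask.
#' @param G Number of gray levels (>= 2), default 64.
#' @return A `quantized_volume`: list with `levels` (integer array, `NA`
#'   outside the mask), `G`, `mask`, `spacing` and `bounds` (the min/max
#'   used).
#' @export
quantize <- function(vol, G = 64L) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  if (!any(vol$mask)) stop("mask is empty")
  G <- as.integer(G)
  if (G < 2L) stop("`G` must be >= 2")
  v <- vol$data[vol$mask]
  lo <- min(v); hi <- max(v)
  lev <- array(NA_integer_, dim = dim(vol$data))
  if (hi == lo) {
    warning("constant masked intensities: all levels set to 0")
    lev[vol$mask] <- 0L
  } else {
    x <- vol$data[vol$mask]
    l <- floor(G * (x - lo) / (hi - lo))
    l[l >= G] <- G - 1L
    lev[vol$mask] <- as.integer(l)
  }
  structure(list(levels = lev, G = G, mask = vol$mask,
                 spacing = vol$spacing, bounds = c(min = lo, max = hi)),
            class = "quantized_volume")
}

# distance-1 direction sets (row, col, slice offsets)
glcm_offsets <- function(mode = c("2d-4dir", "3d-13dir"), distance = 1L) {
  mode <- match.arg(mode)
  o <- if (mode == "2d-4dir") {
    rbind(c(0, 1, 0), c(1, 1, 0), c(1, 0, 0), c(1, -1, 0))
  } else {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
          c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
          c(0, 1, 1), c(0, 1, -1),
          c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  }
  o * as.integer(distance)
}

#' Windowed gray-level co-occurrence matrix
#'
#' Builds the symmetric GLCM for one pixel: all co-occurring valid pixel
#' pairs, for each offset and its reverse, whose both members lie inside the
#' `(2*radius + 1)`-sized window centered on `center` and inside the mask,
#' normalized to joint probabilities p(i,j).
#'
#' @param q A `quantized_volume` from [quantize()].
#' @param center Integer pixel index (row, col) or (row, col, slice).
#' @param radius Window radius in pixels (default 3: a 7x7 window).
#' @param offsets Integer matrix of direction vectors (rows = directions,
#'   columns = row/col/slice offsets); defaults to the 4 in-plane directions
#'   at distance 1. All offsets are pooled into one matrix here; use
#'   [texture_map()] for per-direction feature averaging.
#' @return A `G x G` matrix of joint probabilities, with attribute `n_pairs`
#'   (ordered pair count). An all-zero matrix if no valid pair exists.
#' @export
glcm_window <- function(q, center, radius = 3L, offsets = NULL) {
  if (!inherits(q, "quantized_volume")) stop("`q` must be a quantized_volume")
  if (radius < 1L) stop("`radius` must be >= 1")
  d <- dim(q$levels)
  nd <- length(d)
  if (length(center) != nd) stop("`center` must match image dimensionality")
  if (any(center < 1L) || any(center > d)) stop("`center` is outside the image")
  if (is.null(offsets)) offsets <- glcm_offsets("2d-4dir")
  if (ncol(offsets) == 2L) offsets <- cbind(offsets, 0L)
  win <- c(radius, radius, if (any(offsets[, 3] != 0)) radius else 0L)
  c3 <- c(center, 1L)[1:3]
  d3 <- c(d, 1L)[1:3]
  lo <- pmax(c3 - win, 1L)
  hi <- pmin(c3 + win, d3)
  lev <- if (nd == 2L) array(q$levels, dim = c(d, 1L)) else q$levels
  p <- matrix(0, q$G, q$G)
  n_pairs <- 0L
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
      la <- lev[x, y, z]
      if (is.na(la)) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < lo[1] || x2 > hi[1] || y2 < lo[2] || y2 > hi[2] ||
          z2 < lo[3] || z2 > hi[3]) next
      lb <- lev[x2, y2, z2]
      if (is.na(lb)) next
      p[la + 1L, lb + 1L] <- p[la + 1L, lb + 1L] + 1
      p[lb + 1L, la + 1L] <- p[lb + 1L, la + 1L] + 1
      n_pairs <- n_pairs + 2L
    }
  }
  if (n_pairs > 0L) p <- p / n_pairs
  attr(p, "n_pairs") <- n_pairs
  p
}

#' Haralick features of a co-occurrence matrix
#'
#' Computes the 13 scalar texture statistics of a normalized symmetric GLCM
#' `p(i, j)` with 0-based gray-level indices: energy, contrast, entropy (in
#' bits, base-2 logarithms, with `0 * log 0 = 0`), homogeneity,
#' dissimilarity, correlation (0 when either marginal is degenerate),
#' variance (about the mean of the joint index distribution), sum average,
#' sum entropy, difference variance, difference entropy, autocorrelation and
#' cluster tendency.
#'
#' @param p Square matrix of joint probabilities summing to 1.
#' @return Named numeric vector of length 13 (see
#'   [haralick_feature_names()]).
#' @export
haralick_features <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop("`p` must be a square matrix")
  if (abs(sum(p) - 1) > 1e-6) stop("`p` must be normalized (sum to 1)")
  G <- nrow(p)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  plog <- function(x) ifelse(x > 0, x * log2(x), 0)
  mu_x <- sum(i * p); mu_y <- sum(j * p)
  s_x <- sqrt(sum((i - mu_x)^2 * p)); s_y <- sqrt(sum((j - mu_y)^2 * p))
  ks <- 0:(2 * G - 2)
  p_sum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(G - 1)
  p_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  mu_d <- sum(kd * p_diff)
  corr <- if (s_x * s_y > 0) sum((i - mu_x) * (j - mu_y) * p) / (s_x * s_y) else 0
  c(energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    entropy = -sum(plog(p)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    dissimilarity = sum(abs(i - j) * p),
    correlation = corr,
    variance = sum((i - mu_x)^2 * p),
    sum_average = sum(ks * p_sum),
    sum_entropy = -sum(plog(p_sum)),
    difference_variance = sum((kd - mu_d)^2 * p_diff),
    difference_entropy = -sum(plog(p_diff)),
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * p))
}

#' Per-pixel Haralick texture maps
#'
#' For every valid pixel, builds the windowed GLCM per direction, computes the
#' 13 Haralick features from each direction's normalized matrix, and averages
#' the features over the directions that produced at least one pair
#' (direction-averaged aggregation, giving orientation-invariant maps).
#' Pixels whose window yields no valid pair in any direction are masked out.
#' The default mode matches per-slice 2D analysis with the four in-plane
#' directions at distance 1 inside a radius-3 (7x7) window; `"3d-13dir"`
#' uses the 13 unique 3D directions and a cubic window.
#'
#' @param q A `quantized_volume`.
#' @param radius Window radius, pixels (default 3).
#' @param mode `"2d-4dir"` (default) or `"3d-13dir"`.
#' @param distance Offset distance in pixels (default 1).
#' @param si Optional intensity array (or [intensity_volume()]) supplying the
#'   signal-intensity map of the stack; defaults to the gray levels.
#' @return A `texture_map_stack`: list with `maps` (named list: `SI` plus the
#'   13 features, arrays with `NA` outside the joint mask), `mask`, `spacing`,
#'   `radius`, `mode`, `distance` and `G`.
#' @export
texture_map <- function(q, radius = 3L, mode = c("2d-4dir", "3d-13dir"),
                        distance = 1L, si = NULL) {
  if (!inherits(q, "quantized_volume")) stop("`q` must be a quantized_volume")
  if (!any(q$mask)) stop("mask is empty")
  mode <- match.arg(mode)
  d <- dim(q$levels)
  nd <- length(d)
  if (mode == "3d-13dir" && nd != 3L)
    stop("3d-13dir mode requires a 3D stack")
  offs <- glcm_offsets(mode, distance)
  win <- c(radius, radius, if (mode == "3d-13dir") radius else 0L)
  dims3 <- if (nd == 2L) c(d, 1L) else d
  res <- texture_map_cpp(as.integer(q$levels), as.integer(dims3),
                         q$G, as.integer(win),
                         matrix(as.integer(offs), ncol = 3L))
  fn <- haralick_feature_names()
  maps <- stats::setNames(lapply(seq_along(fn), function(k)
    array(res[[k]], dim = d)), fn)
  valid <- array(res[[length(fn) + 1L]], dim = d)
  if (is.null(si)) si <- q$levels
  if (is_vol(si)) si <- si$data
  if (!identical(dim(si), d)) stop("`si` grid does not match the stack")
  si_map <- array(as.numeric(si), dim = d)
  si_map[!valid] <- NA_real_
  maps <- c(list(SI = si_map), maps)
  structure(list(maps = maps, mask = valid, spacing = q$spacing,
                 radius = as.integer(radius), mode = mode,
                 distance = as.integer(distance), G = q$G),
            class = "texture_map_stack")
}

#' @export
print.texture_map_stack <- function(x, ...) {
  cat(sprintf("<texture_map_stack> %s px, %d maps, %d valid px, mode %s (radius %d, distance %d, G=%d)\n",
              paste(dim(x$mask), collapse = "x"), length(x$maps),
              sum(x$mask), x$mode, x$radius, x$distance, x$G))
  invisible(x)
}
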