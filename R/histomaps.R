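# label priority used for majority-vote ties: stroma > tumor > fat > void >
# background
label_priority <- function() c(2L, 1L, 3L, 4L, 0L)

#' Resample a label raster onto a coarser grid by majority vote
#'
#' Bridges a fine histology-resolution label raster (whole-slide scale) to
#' the MR pixel grid: each target pixel takes the most frequent source label
#' among the source pixels whose centers it covers, with ties broken by the
#' fixed priority stroma > tumor > fat > void > background. Both grids are
#' assumed to share the physical origin at the image corner.
#'
#' @param wsi A [label_map()] (2D, or 3D resampled slice-by-slice in-plane).
#' @param target_shape Integer target grid shape (same dimensionality).
#' @param target_spacing Micrometres per target axis.
#' @return A [label_map()] on the target grid. Target pixels covering no
#'   source pixel are background.
#' @export
resample_labels <- function(wsi, target_shape, target_spacing) {
  if (!is_labmap(wsi)) stop("`wsi` must be a label_map")
  d <- dim(wsi$labels)
  nd <- length(d)
  target_shape <- as.integer(target_shape)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_shape) != nd || length(target_spacing) != nd)
    stop("target grid dimensionality mismatch")
  if (identical(target_shape, d) &&
      all(abs(target_spacing - wsi$spacing) < 1e-9))
    return(wsi)

  vote_slice <- function(src, sps, nxt, nyt, spt) {
    nxs <- nrow(src); nys <- ncol(src)
    ix <- matrix(seq_len(nxs), nxs, nys)
    iy <- matrix(seq_len(nys), nxs, nys, byrow = TRUE)
    tx <- ceiling((ix - 0.5) * sps[1] / spt[1])
    ty <- ceiling((iy - 0.5) * sps[2] / spt[2])
    inside <- tx >= 1 & tx <= nxt & ty >= 1 & ty <= nyt
    if (!any(inside)) stop("source and target physical extents are disjoint")
    key <- tx[inside] + (ty[inside] - 1L) * nxt
    lab <- src[inside]
    ncell <- nxt * nyt
    best_cnt <- integer(ncell)
    winner <- integer(ncell)            # background default
    for (l in rev(label_priority())) {  # low priority first; ties overwritten
      sel <- lab == l
      if (!any(sel)) next
      cnt <- tabulate(key[sel], nbins = ncell)
      upd <- cnt >= best_cnt & cnt > 0L
      winner[upd] <- l
      best_cnt[upd] <- cnt[upd]
    }
    matrix(winner, nxt, nyt)
  }

  if (nd == 2L) {
    out <- vote_slice(wsi$labels, wsi$spacing, target_shape[1],
                      target_shape[2], target_spacing)
  } else {
    if (target_shape[3] != d[3])
      stop("3D label resampling is in-plane only: slice counts must match")
    out <- array(0L, dim = target_shape)
    for (z in seq_len(d[3]))
      out[, , z] <- vote_slice(wsi$labels[, , z], wsi$spacing[1:2],
                               target_shape[1], target_shape[2],
                               target_spacing[1:2])
  }
  label_map(out, target_spacing, wsi$dict)
}

# in-plane integer offsets of the Euclidean disk of the given pixel radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

shift_zero <- function(mat, dx, dy) {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(0, n, m)
  xs <- max(1, 1 + dx):min(n, n + dx)
  ys <- max(1, 1 + dy):min(m, m + dy)
  if (length(xs) < 1 || length(ys) < 1) return(out)
  out[xs, ys] <- mat[xs - dx, ys - dy]
  out
}

#' Per-pixel stromal proportion map
#'
#' Assigns every pixel the local stromal proportion: 100 times the number of
#' stroma pixels divided by the number of stroma-plus-tumor pixels inside the
#' Euclidean disk of the given radius centered on it (29 pixels at the
#' default radius 3). Fat, void and background pixels count in neither
#' numerator nor denominator; pixels whose disk contains no tumor or stroma
#' at all are masked out. For 3D stacks the disk is applied in-plane,
#' slice by slice.
#'
#' @param labmap A [label_map()].
#' @param radius Disk radius in pixels (default 3).
#' @return A `stromal_proportion_map`: list with `proportion` (array of
#'   percentages in `[0, 100]`, `NA` where undefined), `mask`, `spacing` and
#'   `radius`.
#' @export
stromal_proportion <- function(labmap, radius = 3) {
  if (!is_labmap(labmap)) stop("`labmap` must be a label_map")
  if (radius < 1) stop("`radius` must be >= 1")
  offs <- disk_offsets(radius)
  d <- dim(labmap$labels)
  nd <- length(d)
  one_slice <- function(lab) {
    s_ind <- (lab == 2L) + 0
    t_ind <- (lab == 1L) + 0
    s_cnt <- matrix(0, nrow(lab), ncol(lab))
    t_cnt <- matrix(0, nrow(lab), ncol(lab))
    for (k in seq_len(nrow(offs))) {
      s_cnt <- s_cnt + shift_zero(s_ind, offs$dx[k], offs$dy[k])
      t_cnt <- t_cnt + shift_zero(t_ind, offs$dx[k], offs$dy[k])
    }
    denom <- s_cnt + t_cnt
    prop <- matrix(NA_real_, nrow(lab), ncol(lab))
    ok <- denom > 0
    prop[ok] <- 100 * s_cnt[ok] / denom[ok]
    prop
  }
  if (nd == 2L) {
    prop <- one_slice(labmap$labels)
  } else {
    prop <- array(NA_real_, dim = d)
    for (z in seq_len(d[3])) prop[, , z] <- one_slice(labmap$labels[, , z])
  }
  mask <- !is.na(prop)
  if (!any(mask))
    warning("no pixel has tumor or stroma in its neighborhood; map is empty")
  structure(list(proportion = prop, mask = mask, spacing = labmap$spacing,
                 radius = radius),
            class = "stromal_proportion_map")
}

#' @export
print.stromal_proportion_map <- function(x, ...) {
  cat(sprintf("<stromal_proportion_map> %s px, radius %g, %d valid px\n",
              paste(dim(x$proportion), collapse = "x"), x$radius,
              sum(x$mask)))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' Spatial overlap between two binary masks: `2 |A intersect B| / (|A| + |B|)`,
#' in `[0, 1]`. Two empty masks are defined to overlap perfectly
#' (coefficient 1).
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return The Dice coefficient, a scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}
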