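#' Build the pixel feature table
#'
#' Flattens a texture map stack and a stromal proportion map (aligned grids)
#' into a table of valid pixels: coordinates, tumor id, signal intensity, the
#' 13 Haralick features, the local stromal proportion and the stroma-rich /
#' stroma-poor class at the given threshold. This table feeds both the binned
#' correlation analysis and the pixel classifier.
#'
#' @param stack A `texture_map_stack` from [texture_map()].
#' @param prop A `stromal_proportion_map` from [stromal_proportion()] on the
#'   same grid.
#' @param tumor_id Identifier recorded per row (one table per specimen;
#'   tables from several specimens can be `rbind`ed).
#' @param threshold Percent stroma separating rich from poor (default 50);
#'   pixels exactly at the threshold get class `NA`.
#' @return A data.frame with columns `tumor`, coordinate columns, `SI`, the
#'   13 features, `proportion` and `class` (factor rich/poor).
#' @export
pixel_feature_table <- function(stack, prop, tumor_id = 1L, threshold = 50) {
  if (!inherits(stack, "texture_map_stack")) stop("`stack` must be a texture_map_stack")
  if (!inherits(prop, "stromal_proportion_map")) stop("`prop` must be a stromal_proportion_map")
  assert_same_grid(dim(stack$mask), dim(prop$proportion), "feature/proportion grids")
  keep <- stack$mask & prop$mask
  if (!any(keep)) stop("no pixel is valid in both maps")
  idx <- which(keep)
  co <- arrayInd(idx, dim(stack$mask))
  colnames(co) <- c("x", "y", "z")[seq_len(ncol(co))]
  feat <- vapply(stack$maps, function(m) m[idx], numeric(length(idx)))
  df <- data.frame(tumor = tumor_id, co, feat, check.names = FALSE)
  df$proportion <- prop$proportion[idx]
  df$class <- label_pixels_vec(df$proportion, threshold)
  df
}

prop_bins <- function() {
  list(breaks = seq(0, 100, by = 10), centers = seq(5, 95, by = 10))
}

# bin index 1..10 for proportions in [0,100]: [0,10), ..., [90,100]
prop_bin_index <- function(p) {
  pmin(floor(p / 10), 9) + 1L
}

#' Bin pixel values by stromal proportion
#'
#' Divides the stromal-proportion axis into ten 10-percentage-point bins
#' (`[0,10), ..., [90,100]`) and averages each requested column within each
#' bin. Empty bins are flagged and later excluded from correlation.
#'
#' @param table A [pixel_feature_table()] (or any data.frame with a
#'   `proportion` column).
#' @param columns Character vector of columns to average; defaults to `SI`
#'   plus the 13 Haralick features.
#' @return A list with `centers` (10 bin centers, percent), `counts` (pixels
#'   per bin) and `means` (bins x columns matrix, `NA` for empty bins).
#' @export
bin_by_proportion <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(c("SI", haralick_feature_names()), names(table))
  if (!("proportion" %in% names(table))) stop("`table` lacks a proportion column")
  b <- prop_bins()
  idx <- prop_bin_index(table$proportion)
  counts <- tabulate(idx, nbins = 10L)
  means <- matrix(NA_real_, 10L, length(columns),
                  dimnames = list(NULL, columns))
  for (cn in columns) {
    s <- vapply(split(table[[cn]], factor(idx, levels = 1:10)),
                function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
    means[, cn] <- s
  }
  list(centers = b$centers, counts = counts, means = means)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Standard product-moment correlation between two vectors with the
#' two-sided p-value from the t distribution on `n - 2` degrees of freedom.
#' With fewer than 3 points or zero variance in either vector the
#' correlation is undefined and reported as `NA` (not zero).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Binned texture-versus-stroma association report
#'
#' The pixel-wise association analysis: stromal proportion is binned into ten
#' 10-point increments, the mean signal intensity and mean value of each of
#' the 13 Haralick features are computed per bin, and the Pearson correlation
#' between bin centers and bin means is evaluated per feature with its
#' p-value (significance at 0.05, no multiple-testing correction by default;
#' `adjust = "BH"` applies Benjamini-Hochberg). Empty bins are dropped;
#' features with fewer than 3 nonempty bins are reported with `NA`
#' correlation and a diagnostic.
#'
#' @param stack A `texture_map_stack`.
#' @param prop A `stromal_proportion_map` on the same grid.
#' @param table Optionally, a precomputed [pixel_feature_table()] (overrides
#'   `stack`/`prop`; use it to pool several specimens).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `binned_association`: list with `report` (data.frame: feature,
#'   r, p, n_bins, significant), `bins` (output of [bin_by_proportion()])
#'   and `n_pixels`.
#' @export
association_report <- function(stack = NULL, prop = NULL, table = NULL,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(table)) {
    if (is.null(stack) || is.null(prop))
      stop("provide `table` or both `stack` and `prop`")
    table <- pixel_feature_table(stack, prop)
  }
  columns <- intersect(c("SI", haralick_feature_names()), names(table))
  bins <- bin_by_proportion(table, columns)
  nonempty <- bins$counts > 0
  if (sum(nonempty) < 3)
    warning("fewer than 3 nonempty proportion bins; correlations undefined")
  rows <- lapply(columns, function(cn) {
    pr <- pearson(bins$centers[nonempty], bins$means[nonempty, cn])
    data.frame(feature = cn, r = pr$r, p = pr$p, n_bins = pr$n)
  })
  rep <- do.call(rbind, rows)
  if (adjust == "BH") rep$p <- stats::p.adjust(rep$p, method = "BH")
  rep$significant <- !is.na(rep$p) & rep$p < 0.05
  structure(list(report = rep, bins = bins, n_pixels = nrow(table)),
            class = "binned_association")
}

#' @export
print.binned_association <- function(x, ...) {
  cat(sprintf("<binned_association> %d pixels, %d nonempty bins\n",
              x$n_pixels, sum(x$bins$counts > 0)))
  print(transform(x$report, r = round(r, 3), p = signif(p, 3)))
  invisible(x)
}
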