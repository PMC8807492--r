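#' @useDynLib stromatex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var approx mad cor pt p.adjust setNames
#' @importFrom utils write.csv read.csv modifyList
"_PACKAGE"

#' Tissue label dictionary
#'
#' Integer codes used throughout the package for histology-derived label
#' rasters: background (0), tumor (1), stroma (2), fat (3) and void (4,
#' zero-signal structures such as glandular lumens and psammoma bodies).
#'
#' @return Named integer vector mapping label names to codes.
#' @export
stromatex_labels <- function() {
  c(background = 0L, tumor = 1L, stroma = 2L, fat = 3L, void = 4L)
}

#' Intensity volume container
#'
#' A grayscale 2D slice or 3D stack of MR signal intensity with voxel spacing
#' metadata (micrometres per axis) and a boolean validity mask marking the
#' analyzable tissue pixels. All preprocessing and texture operations consume
#' and produce this container.
#'
#' @param data Numeric 2D matrix or 3D array of signal intensity
#'   (arbitrary units).
#' @param spacing Numeric vector, one strictly positive value per axis, in
#'   micrometres.
#' @param mask Logical array with the same shape as `data`; `TRUE` marks valid
#'   tissue pixels. Defaults to all `TRUE`.
#' @return An object of class `intensity_volume`: a list with elements
#'   `data`, `spacing` and `mask`.
#' @export
intensity_volume <- function(data, spacing, mask = NULL) {
  if (is.matrix(data)) data <- array(as.numeric(data), dim = dim(data))
  if (!is.array(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stop("`data` must be a 2D or 3D numeric array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != length(dim(data)))
    stop("`spacing` must have one entry per axis of `data`")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("`mask` and `data` shapes differ")
  storage.mode(mask) <- "logical"
  structure(list(data = data, spacing = spacing, mask = mask),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- x$data[x$mask]
  cat(sprintf("<intensity_volume> %s px, spacing %s um, %d/%d valid\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$mask), length(x$mask)))
  if (length(d))
    cat(sprintf("  masked intensity: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
                mean(d), stats::sd(d), min(d), max(d)))
  invisible(x)
}

#' Label map container
#'
#' An integer raster of tissue labels over a pixel grid with spacing metadata.
#' Labels must come from a label dictionary (by default
#' [stromatex_labels()]: background/tumor/stroma/fat/void).
#'
#' @param labels Integer 2D matrix or 3D array of label codes.
#' @param spacing Numeric vector of voxel spacings, micrometres per axis.
#' @param dict Named integer vector of permitted codes.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing, dict = stromatex_labels()) {
  if (is.matrix(labels)) labels <- array(as.integer(labels), dim = dim(labels))
  if (!is.array(labels) || !(length(dim(labels)) %in% c(2L, 3L)))
    stop("`labels` must be a 2D or 3D integer array")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != length(dim(labels)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive, one value per axis")
  bad <- setdiff(unique(as.vector(labels)), unname(dict))
  if (length(bad))
    stop("labels outside the dictionary: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = spacing, dict = dict),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s px, spacing %s um\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  tab <- table(factor(as.vector(x$labels), levels = unname(x$dict),
                      labels = names(x$dict)))
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
  invisible(x)
}

# shared internal checks ------------------------------------------------

assert_same_grid <- function(a_dim, b_dim, what = "grids") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(what, " are misaligned: ", paste(a_dim, collapse = "x"),
         " vs ", paste(b_dim, collapse = "x"))
  invisible(TRUE)
}

is_vol <- function(x) inherits(x, "intensity_volume")
is_labmap <- function(x) inherits(x, "label_map")
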