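# Minimal NIfTI-1 reader/writer (single-file uncompressed .nii, little
# endian). Covers what the pipeline needs: 2D/3D rasters as uint8, int16,
# int32, float32 or float64, with voxel spacing in pixdim (micrometres by
# this package's convention, noted in descrip). No NIfTI R package is
# assumed to be available.

nifti_dtypes <- data.frame(
  name = c("uint8", "int16", "int32", "float32", "float64"),
  code = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

#' Write an array as a NIfTI-1 file
#'
#' @param data 2D/3D numeric, integer or logical array.
#' @param spacing Voxel spacing per axis (micrometres).
#' @param path Output path, extension `.nii`.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; the default picks `float32` for numeric and `uint8` for
#'   integer/logical data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, spacing, path, datatype = NULL) {
  if (!grepl("\\.nii$", path)) stop("unsupported extension (only .nii): ", path)
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) stop("`data` must be 2D or 3D")
  if (is.null(datatype))
    datatype <- if (is.double(data)) "float32" else "uint8"
  dt <- nifti_dtypes[match(datatype, nifti_dtypes$name), ]
  if (is.na(dt$code)) stop("unknown datatype: ", datatype)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), len))],
               raw(len - min(length(raw), len))), con)
  }
  wi(348, 4)                                   # sizeof_hdr
  wc("", 10); wc("", 18)                       # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)    # extents..dim_info
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(dim8, 2)                                  # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                     # intent_p*, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0, 2)   # datatype, bitpix, slice_start
  wf(c(1, spacing, rep(1, 7 - length(spacing))))  # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)               # slice_end, slice_code, units
  wf(c(0, 0, 0, 0))                            # cal_max..toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  wc("stromatex: spacing in micrometres", 80)  # descrip
  wc("", 24)                                   # aux_file
  wi(c(0, 0), 2)                               # qform_code, sform_code
  wf(rep(0, 6))                                # quatern, qoffset
  wf(c(spacing[1], 0, 0, 0))                   # srow_x
  wf(c(0, spacing[2], 0, 0))                   # srow_y
  wf(c(0, 0, if (length(spacing) > 2) spacing[3] else 1, 0))  # srow_z
  wc("", 16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                        # no extensions
  v <- as.vector(data)
  if (dt$name %in% c("float32", "float64")) {
    writeBin(as.numeric(v), con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any plain .nii)
#'
#' @param path Path to an uncompressed single-file `.nii`.
#' @return List with `data` (array) and `spacing` (numeric per axis).
#' @export
read_nifti <- function(path) {
  if (!grepl("\\.nii$", path)) stop("unsupported extension (only .nii): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  if (sz != 348) stop("not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dim8 <- readBin(hdr[41:56], "integer", 8, size = 2, endian = "little")
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  dtcode <- readBin(hdr[71:72], "integer", 1, size = 2, endian = "little")
  dt <- nifti_dtypes[match(dtcode, nifti_dtypes$code), ]
  if (is.na(dt$bitpix)) stop("unsupported NIfTI datatype code ", dtcode)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = "little")
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  v <- if (dt$name %in% c("float32", "float64")) {
    readBin(con, "numeric", n, size = dt$bitpix / 8L, endian = "little")
  } else {
    readBin(con, "integer", n, size = dt$bitpix / 8L, endian = "little",
            signed = dt$name != "uint8")
  }
  list(data = array(v, dim = d), spacing = pixdim[2:(1 + nd)])
}

mask_path <- function(path) sub("\\.nii$", "_mask.nii", path)

#' Write / read an intensity volume with its validity mask
#'
#' The image is stored as float32 and the mask as a uint8 sidecar
#' (`*_mask.nii`); spacing metadata survives the round trip.
#'
#' @param vol An [intensity_volume()].
#' @param path `.nii` path.
#' @return `path` (write) or an [intensity_volume()] (read).
#' @export
write_image <- function(vol, path) {
  if (!is_vol(vol)) stop("`vol` must be an intensity_volume")
  write_nifti(vol$data, vol$spacing, path, "float32")
  write_nifti(vol$mask + 0L, vol$spacing, mask_path(path), "uint8")
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  im <- read_nifti(path)
  mp <- mask_path(path)
  mask <- if (file.exists(mp)) array(read_nifti(mp)$data > 0, dim(im$data))
          else NULL
  intensity_volume(im$data, im$spacing, mask)
}

#' Write / read a label map with its JSON label dictionary
#'
#' The raster is stored as uint8 and the label dictionary as a JSON sidecar
#' (`*.labels.json`), so the name-to-code mapping round-trips with the data.
#'
#' @param labmap A [label_map()].
#' @param path `.nii` path.
#' @return `path` (write) or a [label_map()] (read).
#' @export
write_labels <- function(labmap, path) {
  if (!is_labmap(labmap)) stop("`labmap` must be a label_map")
  write_nifti(labmap$labels, labmap$spacing, path, "uint8")
  jsonlite::write_json(as.list(labmap$dict),
                       sub("\\.nii$", ".labels.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  im <- read_nifti(path)
  jp <- sub("\\.nii$", ".labels.json", path)
  dict <- if (file.exists(jp)) {
    l <- jsonlite::read_json(jp)
    stats::setNames(as.integer(unlist(l)), names(l))
  } else stromatex_labels()
  label_map(array(as.integer(im$data), dim(im$data)), im$spacing, dict)
}
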