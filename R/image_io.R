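# Reading and writing strip images, channel collapse, saturation detection.

#' Construct a raster image
#'
#' A `raster_image` is a single analysis channel of a strip photograph: an
#' integer pixel matrix (row 1 = top of the strip, the flow axis runs along
#' rows) together with its bit depth and the spectral channel it came from.
#'
#' @param pixels Integer matrix of non-negative pixel values, rows x columns.
#' @param bit_depth Integer, 8 or 16.
#' @param channel_label One of `"green"`, `"red"`, `"gray"`. The duplex assay
#'   images one strip through two emission bandpass filters; the label keeps
#'   track of which filter a matrix belongs to.
#' @param source_id File path or simulator tag identifying the image.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, bit_depth, channel_label = "gray",
                         source_id = "<memory>") {
  if (!is.matrix(pixels)) lfa_usage_error("'pixels' must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) {
    lfa_format_error(sprintf("unsupported bit depth %s (must be 8 or 16)",
                             bit_depth))
  }
  if (!channel_label %in% c("green", "red", "gray")) {
    lfa_usage_error(sprintf(
      "channel_label must be 'green', 'red' or 'gray', got '%s'", channel_label))
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    lfa_geometry_error("image must have at least one row and one column")
  }
  pixels <- structure(as.integer(round(pixels)), dim = dim(pixels))
  maxval <- 2L^as.integer(bit_depth) - 1L
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > maxval) {
    lfa_range_error(sprintf(
      "pixel values must be integers in [0, %d] for bit depth %d",
      maxval, bit_depth))
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 channel_label = channel_label, source_id = source_id),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %dx%d, %d-bit, channel '%s', source '%s'>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel_label,
              x$source_id))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

image_max_value <- function(image) 2L^image$bit_depth - 1L

#' Load a strip image from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale or RGB image and collapses it to a single
#' analysis channel. Emission-filtered fluorescence captures carry their
#' signal in one colour channel, so the default for RGB input is per-channel
#' selection; `luminance` computes the integer ITU-R BT.601 weighted sum
#' `round(0.299 R + 0.587 G + 0.114 B)` as a fallback for colorimetric
#' images. `native_gray` is only valid for grayscale files.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param channel_rule How to collapse RGB input: one of `"native_gray"`,
#'   `"select_red"`, `"select_green"`, `"select_blue"`, `"luminance"`.
#' @param channel_label Spectral label for the result; default is inferred
#'   from `channel_rule` (`select_green` -> `"green"`, `select_red` ->
#'   `"red"`, otherwise `"gray"`).
#' @return A [raster_image].
#' @export
load_image <- function(path,
                       channel_rule = c("native_gray", "select_red",
                                        "select_green", "select_blue",
                                        "luminance"),
                       channel_label = NULL) {
  channel_rule <- match.arg(channel_rule)
  if (!file.exists(path)) {
    lfa_io_error(sprintf("image file does not exist: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    lfa_format_error(paste0(
      "JPEG input is not supported (no JPEG reader available); lossy ",
      "compression artifacts would bias band AUC readout anyway - convert ",
      "the capture to PNG or TIFF: ", path))
  }
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bit_depth <- as.integer(info$bit.depth)
    if (!bit_depth %in% c(8L, 16L)) {
      lfa_format_error(sprintf("unsupported PNG bit depth %d in '%s'",
                               bit_depth, path))
    }
    # readPNG normalises to [0,1]; undo the scaling exactly.
    arr <- round(arr * (2^bit_depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    bit_depth <- as.integer(bits)
    if (!bit_depth %in% c(8L, 16L)) {
      lfa_format_error(sprintf("unsupported TIFF bit depth %d in '%s'",
                               bit_depth, path))
    }
  } else {
    lfa_format_error(sprintf("unsupported image format '.%s': '%s'", ext, path))
  }

  nd <- length(dim(arr))
  if (nd == 2L) {
    if (channel_rule != "native_gray") {
      lfa_log("debug", "grayscale input; channel_rule '", channel_rule,
              "' reduces to native_gray")
    }
    px <- arr
  } else if (nd == 3L && dim(arr)[3] >= 3L) {
    if (channel_rule == "native_gray") {
      lfa_usage_error(paste0(
        "'native_gray' is only valid for grayscale files; '", path,
        "' is RGB - pick select_red/select_green/select_blue or luminance"))
    }
    nr <- dim(arr)[1]
    r <- matrix(arr[, , 1], nrow = nr)
    g <- matrix(arr[, , 2], nrow = nr)
    b <- matrix(arr[, , 3], nrow = nr)
    px <- switch(channel_rule,
                 select_red = r,
                 select_green = g,
                 select_blue = b,
                 luminance = round(0.299 * r + 0.587 * g + 0.114 * b))
  } else {
    lfa_format_error(sprintf("unsupported channel layout in '%s'", path))
  }

  if (is.null(channel_label)) {
    channel_label <- switch(channel_rule, select_green = "green",
                            select_red = "red", "gray")
  }
  raster_image(px, bit_depth = bit_depth, channel_label = channel_label,
               source_id = path)
}

#' Write a raster image to PNG or TIFF
#'
#' The file suffix selects the format. 16-bit images must be written as
#' TIFF (PNG output is 8-bit here).
#'
#' @param image A [raster_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- image$pixels / image_max_value(image)
  if (ext == "png") {
    if (image$bit_depth != 8L) {
      lfa_format_error("PNG output supports 8-bit images only; use TIFF for 16-bit")
    }
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = image$bit_depth)
  } else {
    lfa_format_error(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}

#' Detect pixel saturation
#'
#' Pixels clipped at the detector maximum produce flat-topped intensity
#' peaks that bias band AUC readout, so saturated captures must be flagged
#' rather than silently quantified.
#'
#' @param image A [raster_image].
#' @param threshold Fraction of at-maximum pixels above which the image is
#'   flagged (strictly greater than; default 0.001).
#' @return A list with `saturated_fraction` (in `[0, 1]`) and `flag`.
#' @export
detect_saturation <- function(image, threshold = 0.001) {
  stopifnot(inherits(image, "raster_image"))
  frac <- mean(image$pixels == image_max_value(image))
  list(saturated_fraction = frac, flag = frac > threshold)
}
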