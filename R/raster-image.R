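#' Calibrated raster image
#'
#' A `raster_image` is the unit of image analysis: a 2-D grid of integer
#' intensities together with its bit depth, spatial calibration and
#' intensity convention. Two conventions are supported. Image files store
#' intensities in the usual light-is-high form (0 = black, maximum = white,
#' `"light_high"`). Densitometric work on stained sections often uses the
#' opposite dark-is-high scale (0 = white, maximum = black, `"dark_high"`);
#' segmentation thresholds in this package are always expressed on the
#' dark-is-high scale, and [binarize()] resolves the convention of the image
#' it is given.
#'
#' @param pixels Numeric matrix of intensities (rows are image rows).
#' @param bit_depth Integer, 8 or 16.
#' @param um_per_px Positive number, micrometres per pixel.
#' @param convention `"light_high"` (file convention, default) or
#'   `"dark_high"`.
#'
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, bit_depth, um_per_px,
                         convention = c("light_high", "dark_high")) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16, got ", bit_depth)
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0) {
    stop("um_per_px must be a single positive number")
  }
  mx <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > mx)) {
    stop("pixel intensities outside [0, ", mx, "]")
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         um_per_px = um_per_px, convention = convention),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d-bit, %.4g um/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$um_per_px,
              x$convention))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Total calibrated image area
#'
#' @param image A [raster_image()].
#' @return Image area in square micrometres.
#' @export
image_area_um2 <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  length(image$pixels) * image$um_per_px^2
}

# Rec. 601 luminance weights, the common grayscale conversion for
# camera-acquired histology; recorded in provenance wherever applied.
LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

rgb_to_gray <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] >= 3L)
  arr[, , 1] * LUMA_WEIGHTS[["r"]] +
    arr[, , 2] * LUMA_WEIGHTS[["g"]] +
    arr[, , 3] * LUMA_WEIGHTS[["b"]]
}

#' Read a histology image from file
#'
#' Reads TIFF or PNG (8- or 16-bit, grayscale or RGB) into a calibrated
#' [raster_image()]. RGB images are converted to grayscale with Rec. 601
#' luminance weights unless `allow_rgb = FALSE`, in which case colour input
#' is refused with an error. File intensities are taken as light-is-high.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param um_per_px Micrometres per pixel (operator-supplied calibration).
#' @param allow_rgb Convert RGB to grayscale (default) or refuse it.
#' @return A [raster_image()] in `"light_high"` convention.
#' @export
read_image <- function(path, um_per_px, allow_rgb = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bits <- attr(arr, "info")$bit.depth
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  }
  bit_depth <- if (!is.null(bits) && bits > 8) 16L else 8L
  if (length(dim(arr)) == 3L) {
    if (!allow_rgb) stop("RGB input refused (allow_rgb = FALSE): ", path)
    arr <- rgb_to_gray(arr)
  }
  mx <- 2^bit_depth - 1
  px <- round(arr * mx)
  attributes(px) <- list(dim = dim(px))  # drop file metadata attributes
  raster_image(px, bit_depth = bit_depth,
               um_per_px = um_per_px, convention = "light_high")
}

#' Write a raster image or label mask to file
#'
#' Images are written at their native bit depth; label masks are written as
#' 16-bit TIFF. Dark-is-high images are converted back to the file
#' (light-is-high) convention on write.
#'
#' @param image A [raster_image()] or an integer label matrix.
#' @param path Output path (`.tif`/`.tiff` or `.png` for images; label
#'   masks are always TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "raster_image")) {
    mx <- 2^image$bit_depth - 1
    px <- image$pixels
    if (image$convention == "dark_high") px <- mx - px
    dat <- px / mx
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(dat, path, bits.per.sample = image$bit_depth)
    } else if (ext == "png") {
      png::writePNG(dat, path)
    } else {
      stop("unsupported output format: .", ext)
    }
  } else if (is.matrix(image) && is.numeric(image)) {
    if (max(image) > 65535) stop("label ids exceed 16-bit range")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  } else {
    stop("write_image expects a raster_image or a numeric label matrix")
  }
  invisible(path)
}
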