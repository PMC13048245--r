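#' Raster image container
#'
#' A `raster_image` holds pixel intensities as floats in `[0, 1]` together
#' with the native bit depth of the source file and an optional mapping of
#' fluorescence channels (actin, nuclei) to array planes. Single-channel
#' images are stored as a `height x width` matrix, RGB images as a
#' `height x width x 3` array, with rows increasing downwards as in the
#' image frame.
#'
#' @param pixels numeric matrix (single channel) or `h x w x 3` array with
#'   values in `[0, 1]`.
#' @param bit_depth native bit depth of the source, 8 or 16. Used to map
#'   the internal float representation back to native intensity counts.
#' @param channel_roles optional named list mapping `"actin"` and/or
#'   `"nuclei"` to a plane index. Defaults to the RGB convention
#'   actin = green (2), nuclei = blue (3) for 3-channel images.
#' @param meta optional list of metadata (e.g. source path, original size).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, bit_depth = 8L, channel_roles = NULL,
                         meta = list()) {
  if (!is.numeric(pixels))
    stop("`pixels` must be numeric", call. = FALSE)
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || !(nd %in% c(2L, 3L)))
    stop("`pixels` must be a matrix or a 3-way array", call. = FALSE)
  if (nd == 3L && dim(pixels)[3L] == 1L) {
    pixels <- pixels[, , 1L, drop = TRUE]
    nd <- 2L
  }
  if (nd == 3L && !(dim(pixels)[3L] %in% c(3L)))
    stop("unsupported channel count: ", dim(pixels)[3L],
         " (expected 1 or 3)", call. = FALSE)
  if (!(bit_depth %in% c(8L, 16L)))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  rng <- range(pixels)
  if (is.na(rng[1L]) || rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    stop("pixel intensities must lie in [0, 1]", call. = FALSE)
  structure(
    list(pixels = pixels,
         height = dim(pixels)[1L],
         width = dim(pixels)[2L],
         n_channels = if (nd == 2L) 1L else dim(pixels)[3L],
         bit_depth = as.integer(bit_depth),
         channel_roles = channel_roles,
         meta = meta),
    class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d, %d channel(s), %d-bit source\n",
              x$height, x$width, x$n_channels, x$bit_depth))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

assert_single_channel <- function(img, what = "input") {
  if (!is_raster_image(img))
    stop(what, " must be a raster_image", call. = FALSE)
  if (img$n_channels != 1L)
    stop(what, " must be single-channel, got ", img$n_channels,
         " channels", call. = FALSE)
  invisible(img)
}

#' Native-scale intensities of a raster image
#'
#' Maps the internal `[0, 1]` float representation back to the integer
#' counts of the source bit depth (`value * (2^bit_depth - 1)`, rounded).
#'
#' @param img a `raster_image`.
#' @return numeric array of the same shape as `img$pixels`.
#' @export
native_intensities <- function(img) {
  stopifnot(is_raster_image(img))
  round(img$pixels * (2^img$bit_depth - 1))
}

png_bit_depth <- function(path) {
  # IHDR bit depth is the 25th byte of a PNG stream
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(8L)
  d <- as.integer(hdr[25L])
  if (d == 16L) 16L else 8L
}

#' Load a micrograph from disk
#'
#' Reads TIFF (including 16-bit), PNG or JPEG into a [raster_image].
#' Intensities are converted to floats in `[0, 1]` by dividing by the
#' native white point (`2^bit_depth - 1`), so 16-bit dynamic range is
#' preserved without truncation.
#'
#' @param path path to an image file.
#' @param channel_roles optional channel role mapping, see [raster_image].
#' @return A [raster_image] with `meta$path` set.
#' @export
load_image <- function(path, channel_roles = NULL) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path)
    } else if (ext == "png") {
      png::readPNG(path)
    } else {
      # EBImage dispatches on content; covers JPEG and unlabeled files
      eb <- EBImage::readImage(path)
      a <- EBImage::imageData(eb)
      # EBImage stores x (columns) first; convert to row-major frame
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }
  }, error = function(e) {
    stop("cannot read image '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(dim(arr)) || length(arr) == 0L)
    stop("cannot read image '", path, "': empty or corrupt file",
         call. = FALSE)
  # drop alpha plane if present
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 4L)
    arr <- arr[, , 1:3, drop = FALSE]
  if (length(dim(arr)) == 3L && !(dim(arr)[3L] %in% c(1L, 3L)))
    stop("unsupported channel count in '", path, "': ", dim(arr)[3L],
         call. = FALSE)
  bit_depth <- 8L
  if (ext %in% c("tif", "tiff")) {
    # infer white point by comparing the normalized and raw reads
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) NULL)
    if (!is.null(raw) && max(arr) > 0) {
      scale <- max(raw) / max(arr)
      if (is.finite(scale) && scale > 300) bit_depth <- 16L
    }
  } else if (ext == "png") {
    bit_depth <- png_bit_depth(path)
  }
  raster_image(pmin(pmax(arr, 0), 1), bit_depth = bit_depth,
               channel_roles = channel_roles,
               meta = list(path = path,
                           original_height = dim(arr)[1L],
                           original_width = dim(arr)[2L]))
}

#' Standardize image geometry
#'
#' Resizes an image to the square working frame (default 512 x 512 pixels)
#' by bilinear interpolation. Non-square inputs are stretched; the original
#' aspect ratio is retained in `meta`. Already-standardized images are
#' returned unchanged, so the operation is idempotent.
#'
#' @param img a [raster_image].
#' @param side target side length in pixels.
#' @return A [raster_image] of size `side x side`.
#' @export
standardize <- function(img, side = 512L) {
  stopifnot(is_raster_image(img))
  side <- as.integer(side)
  if (is.na(side) || side <= 0L)
    stop("`side` must be a positive integer", call. = FALSE)
  if (img$height == side && img$width == side) return(img)
  eb <- as_ebimage(img)
  # EBImage dims are (x = width, y = height)
  out <- EBImage::resize(eb, w = side, h = side, filter = "bilinear")
  arr <- from_ebimage(out)
  meta <- img$meta
  meta$original_aspect <- img$width / img$height
  raster_image(pmin(pmax(arr, 0), 1), bit_depth = img$bit_depth,
               channel_roles = img$channel_roles, meta = meta)
}

#' Extract a fluorescence channel
#'
#' Returns the single-channel view of an RGB micrograph for a given role.
#' Without an explicit `channel_roles` mapping the RGB staining convention
#' is assumed: actin (phalloidin) in green, nuclei (DAPI/Hoechst) in blue.
#'
#' @param img a [raster_image].
#' @param role `"actin"` or `"nuclei"`.
#' @return A single-channel [raster_image].
#' @export
extract_channel <- function(img, role = c("actin", "nuclei")) {
  stopifnot(is_raster_image(img))
  role <- match.arg(role)
  idx <- img$channel_roles[[role]]
  if (is.null(idx)) {
    if (img$n_channels != 3L)
      stop("cannot resolve channel '", role, "' for a ", img$n_channels,
           "-channel image without a channel_roles mapping", call. = FALSE)
    idx <- switch(role, actin = 2L, nuclei = 3L)
  }
  idx <- as.integer(idx)
  if (idx < 1L || idx > img$n_channels)
    stop("channel index ", idx, " out of range for role '", role, "'",
         call. = FALSE)
  plane <- if (img$n_channels == 1L) img$pixels else img$pixels[, , idx]
  raster_image(plane, bit_depth = img$bit_depth, meta = img$meta)
}

# EBImage stores arrays as (x, y[, channel]); raster_image as (row, col).
as_ebimage <- function(img) {
  a <- img$pixels
  if (img$n_channels == 1L) {
    EBImage::Image(t(a), colormode = "Grayscale")
  } else {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  }
}

from_ebimage <- function(eb) {
  a <- EBImage::imageData(eb)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Write a raster image to disk
#'
#' Writes PNG or TIFF according to the file extension. 16-bit sources are
#' written as 16-bit files.
#'
#' @param img a [raster_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is_raster_image(img))
  ext <- tolower(tools::file_ext(path))
  a <- pmin(pmax(img$pixels, 0), 1)
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = img$bit_depth)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}
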