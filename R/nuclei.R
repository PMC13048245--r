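#' HSV range for nuclear stain detection
#'
#' Bounds on hue (degrees), saturation and value isolating the blue
#' DAPI/Hoechst rendering. The defaults bracket blue fluorophore hues
#' while excluding cyan-green bleed from the actin channel.
#'
#' @param hue_lo,hue_hi hue bounds in degrees on `[0, 360)`, `hue_lo < hue_hi`.
#' @param sat_lo minimum saturation in `[0, 1]`.
#' @param val_lo minimum value (brightness) in `[0, 1]`.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(hue_lo = 190, hue_hi = 270, sat_lo = 0.25,
                      val_lo = 0.20) {
  if (!(hue_lo < hue_hi))
    stop("`hue_lo` must be < `hue_hi` (no wraparound needed for blue)",
         call. = FALSE)
  if (hue_lo < 0 || hue_hi >= 360)
    stop("hue bounds must lie on [0, 360)", call. = FALSE)
  if (sat_lo < 0 || sat_lo > 1 || val_lo < 0 || val_lo > 1)
    stop("`sat_lo` and `val_lo` must lie in [0, 1]", call. = FALSE)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi,
                 sat_lo = sat_lo, val_lo = val_lo),
            class = "hsv_range")
}

#' Convert an RGB image to HSV
#'
#' Standard RGB to hue-saturation-value conversion. Hue is returned in
#' degrees on `[0, 360)`; saturation and value in `[0, 1]`.
#'
#' @param img 3-channel [raster_image] with intensities in `[0, 1]`.
#' @return A `height x width x 3` array with planes H, S, V.
#' @export
rgb_to_hsv_image <- function(img) {
  stopifnot(is_raster_image(img))
  if (img$n_channels != 3L)
    stop("HSV conversion requires a 3-channel image", call. = FALSE)
  p <- img$pixels
  hsv <- grDevices::rgb2hsv(r = as.vector(p[, , 1L]),
                            g = as.vector(p[, , 2L]),
                            b = as.vector(p[, , 3L]),
                            maxColorValue = 1)
  out <- array(0, dim = dim(p), dimnames = NULL)
  out[, , 1L] <- (hsv[1L, ] * 360) %% 360
  out[, , 2L] <- hsv[2L, ]
  out[, , 3L] <- hsv[3L, ]
  out
}

#' Detect nuclei as blue regions in HSV space
#'
#' Thresholds the image in HSV space with a predefined blue range, labels
#' 8-connected components, removes regions below `min_region_area` pixels
#' (debris), and returns the survivors ordered by area (largest first).
#' Each region's centroid — the "blue center" — is the arithmetic mean of
#' its pixel coordinates and anchors the distance feature of the
#' dispersion statistic.
#'
#' @param img standardized 3-channel [raster_image].
#' @param range an [hsv_range()].
#' @param min_region_area minimum region area in pixels.
#' @return A list of `nucleus_region` objects with `mask` (n x 2 matrix of
#'   row, col), `area`, and `centroid` (row, col, fractional).
#' @export
detect_nuclei <- function(img, range = hsv_range(), min_region_area = 50L) {
  if (!inherits(range, "hsv_range"))
    stop("`range` must be an hsv_range", call. = FALSE)
  hsv <- rgb_to_hsv_image(img)
  mask <- hsv[, , 1L] >= range$hue_lo & hsv[, , 1L] <= range$hue_hi &
    hsv[, , 2L] >= range$sat_lo & hsv[, , 3L] >= range$val_lo
  lab <- label8(mask)
  if (!any(lab > 0L)) return(list())
  fg <- which(lab > 0L)
  h <- nrow(lab)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  by_lab <- split(seq_along(fg), lab[fg])
  regions <- list()
  for (ix in by_lab) {
    if (length(ix) < min_region_area) next
    coords <- cbind(row = rows[ix], col = cols[ix])
    regions[[length(regions) + 1L]] <-
      structure(list(mask = coords,
                     area = nrow(coords),
                     centroid = c(row = mean(coords[, 1L]),
                                  col = mean(coords[, 2L]))),
                class = "nucleus_region")
  }
  if (length(regions) == 0L) return(list())
  regions[order(vapply(regions, function(r) r$area, numeric(1)),
                decreasing = TRUE)]
}
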