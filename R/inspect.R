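#' Debug outputs for a single micrograph
#'
#' Runs the pipeline on one image and writes intermediate artifacts for
#' visual inspection: the binary edge map, an RGB overlay (edges in red
#' over the standardized image, nucleus centers marked), a per-segment
#' table (id, length, angle, davg) and a per-nucleus table (id, area,
#' centroid).
#'
#' @param img a [raster_image] or a path readable by [load_image()].
#' @param config a [run_config()].
#' @param out_dir directory for the debug artifacts (created if missing).
#' @return The [compute_dispersion()] result, invisibly.
#' @export
inspect_image <- function(img, config = run_config(), out_dir) {
  if (is.character(img)) img <- load_image(img)
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  std <- standardize(img, side = config$side)
  actin <- extract_channel(std, "actin")
  edge_map <- canny_edges(actin, sigma = config$sigma,
                          reduction_ratio = config$reduction_ratio)
  segments <- extract_segments(edge_map,
                               min_edge_length = config$min_edge_length)
  rng <- hsv_range(config$hsv_range$hue_lo, config$hsv_range$hue_hi,
                   config$hsv_range$sat_lo, config$hsv_range$val_lo)
  nuclei <- detect_nuclei(std, range = rng,
                          min_region_area = config$min_region_area)
  png::writePNG(edge_map * 1, file.path(out_dir, "edge_map.png"))
  overlay <- if (std$n_channels == 3L) std$pixels else
    array(rep(std$pixels, 3L), c(std$height, std$width, 3L))
  red <- overlay[, , 1L]
  red[edge_map] <- 1
  overlay[, , 1L] <- red
  for (nu in nuclei) {
    r0 <- round(nu$centroid[1L]); c0 <- round(nu$centroid[2L])
    rows <- pmax(1L, r0 - 3L):pmin(std$height, r0 + 3L)
    cols <- pmax(1L, c0 - 3L):pmin(std$width, c0 + 3L)
    overlay[rows, c0, 1L] <- 1; overlay[rows, c0, 2:3] <- 0
    overlay[r0, cols, 1L] <- 1; overlay[r0, cols, 2:3] <- 0
  }
  png::writePNG(pmin(pmax(overlay, 0), 1),
                file.path(out_dir, "overlay.png"))
  centers <- do.call(rbind, lapply(nuclei, function(n) n$centroid))
  seg_tab <- data.frame(
    id = vapply(segments, function(s) s$id, numeric(1)),
    length = vapply(segments, function(s) s$length, numeric(1)),
    angle_deg = vapply(segments, function(s) s$angle_deg, numeric(1)),
    davg = if (length(nuclei))
      vapply(segments, compute_davg, numeric(1), centers = centers)
    else NA_real_)
  utils::write.csv(seg_tab, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  nuc_tab <- data.frame(
    id = seq_along(nuclei),
    area = vapply(nuclei, function(n) n$area, numeric(1)),
    centroid_row = vapply(nuclei, function(n) n$centroid[[1L]], numeric(1)),
    centroid_col = vapply(nuclei, function(n) n$centroid[[2L]], numeric(1)))
  utils::write.csv(nuc_tab, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  res <- tryCatch(compute_dispersion(img, config), error = function(e) e)
  if (inherits(res, "error")) {
    message("[actindisp] dispersion not computable: ",
            conditionMessage(res))
    return(invisible(NULL))
  }
  invisible(res)
}
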