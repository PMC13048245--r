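#' Pipeline run configuration
#'
#' Collects every tunable parameter of the dispersion pipeline. Defaults:
#' 512 px working frame, Gaussian sigma 1.4 px, reduction ratio 2 (the
#' canonical 2:1 high:low Canny ratio), minimum edge length 10 px,
#' blue HSV bracket hue 190-270 deg / sat >= 0.25 / val >= 0.20, minimum
#' nucleus area 50 px, and an 8 x 8 feature histogram (n = 64 subspaces).
#' The full record is echoed into every result so parameter provenance
#' travels with the numbers.
#'
#' @param side working frame side in pixels.
#' @param sigma Gaussian smoothing scale in pixels.
#' @param reduction_ratio hysteresis threshold reduction ratio T >= 1.
#' @param min_edge_length minimum edge-segment size in pixels.
#' @param hsv_range list with `hue_lo`, `hue_hi`, `sat_lo`, `val_lo`.
#' @param min_region_area minimum nucleus area in pixels.
#' @param n_dist_bins,n_angle_bins feature histogram bin counts.
#' @param distance_range_mode `"per_image"` (distance axis spans the
#'   observed maximum) or `"fixed"` (spans `[0, fixed_d_max]`).
#' @param fixed_d_max distance bound in pixels for `"fixed"` mode.
#' @param channel_roles list mapping `actin`/`nuclei` to plane indices.
#' @param seed RNG seed (consumed only by fixture generation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(side = 512L,
                       sigma = 1.4,
                       reduction_ratio = 2,
                       min_edge_length = 10L,
                       hsv_range = list(hue_lo = 190, hue_hi = 270,
                                        sat_lo = 0.25, val_lo = 0.20),
                       min_region_area = 50L,
                       n_dist_bins = 8L,
                       n_angle_bins = 8L,
                       distance_range_mode = c("per_image", "fixed"),
                       fixed_d_max = NULL,
                       channel_roles = list(actin = 2L, nuclei = 3L),
                       seed = 1L) {
  distance_range_mode <- match.arg(distance_range_mode)
  if (identical(distance_range_mode, "fixed") &&
      (is.null(fixed_d_max) || fixed_d_max <= 0))
    stop("`fixed_d_max` must be a positive distance for fixed mode",
         call. = FALSE)
  structure(list(side = as.integer(side),
                 sigma = sigma,
                 reduction_ratio = reduction_ratio,
                 min_edge_length = as.integer(min_edge_length),
                 hsv_range = hsv_range,
                 min_region_area = as.integer(min_region_area),
                 n_dist_bins = as.integer(n_dist_bins),
                 n_angle_bins = as.integer(n_angle_bins),
                 distance_range_mode = distance_range_mode,
                 fixed_d_max = fixed_d_max,
                 channel_roles = channel_roles,
                 seed = as.integer(seed)),
            class = "run_config")
}

as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (!is.list(x)) stop("`config` must be a run_config or list",
                        call. = FALSE)
  do.call(run_config, x)
}

#' Save / load a run configuration
#'
#' Round-trips the configuration through a human-editable YAML file so a
#' run's parameters are reproducible from its config alone.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the restored `run_config`.
#' @export
save_config <- function(config, path) {
  config <- as_run_config(config)
  x <- unclass(config)
  x$fixed_d_max <- if (is.null(x$fixed_d_max)) NA else x$fixed_d_max
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$fixed_d_max) && length(x$fixed_d_max) == 1L &&
      is.na(x$fixed_d_max))
    x$fixed_d_max <- NULL
  do.call(run_config, x)
}

#' Short hash of a configuration
#'
#' Stable digest of the full parameter record, stamped into every result
#' row so outputs can be traced to the exact parameters that produced
#' them.
#'
#' @param config a [run_config()].
#' @return A 8-character hash string.
#' @export
config_hash <- function(config) {
  config <- as_run_config(config)
  substr(digest::digest(unclass(config), algo = "sha1"), 1L, 8L)
}

image_extensions <- c("png", "tif", "tiff", "jpg", "jpeg")

#' Batch dispersion over a directory of micrographs
#'
#' Processes every readable image in `input_dir` through
#' [compute_dispersion()] and writes one CSV row per image. Per-image
#' failures are logged to stderr with the failing stage and do not abort
#' the batch.
#'
#' @param input_dir directory containing images (PNG/TIFF/JPEG).
#' @param config a [run_config()].
#' @param output optional CSV path for the results table.
#' @return Data frame with columns `path`, `n_points`, `n_nuclei`,
#'   `n_bins`, `etp_nats`, `dsp`, `param_hash`; failed images are
#'   recorded in `attr(, "failures")`.
#' @export
run_batch <- function(input_dir, config = run_config(), output = NULL) {
  if (!dir.exists(input_dir))
    stop("input directory not found: ", input_dir, call. = FALSE)
  files <- list.files(input_dir, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% image_extensions]
  files <- sort(files)
  if (length(files) == 0L)
    stop("no readable images in ", input_dir, call. = FALSE)
  config <- as_run_config(config)
  hash <- config_hash(config)
  rows <- list(); failures <- list()
  for (f in files) {
    res <- tryCatch({
      img <- load_image(f, channel_roles = config$channel_roles)
      compute_dispersion(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("[actindisp] FAIL ", f, ": ", conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        data.frame(path = f, reason = conditionMessage(res))
    } else {
      message(sprintf("[actindisp] %s: dsp = %.4f (%d points)",
                      basename(f), res$dsp, res$n_points))
      rows[[length(rows) + 1L]] <-
        data.frame(path = f, n_points = res$n_points,
                   n_nuclei = res$n_nuclei, n_bins = res$n_bins,
                   etp_nats = res$etp, dsp = res$dsp, param_hash = hash)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), n_points = integer(0),
               n_nuclei = integer(0), n_bins = integer(0),
               etp_nats = numeric(0), dsp = numeric(0),
               param_hash = character(0))
  attr(out, "failures") <-
    if (length(failures)) do.call(rbind, failures) else NULL
  if (!is.null(output))
    utils::write.csv(out, output, row.names = FALSE)
  out
}

#' Two-group comparison from batch result files
#'
#' Reads the `dsp` column of two batch CSVs and runs the unpaired
#' pooled-variance Student t-test via [compare_groups()].
#'
#' @param group_a_csv,group_b_csv result CSVs from [run_batch()] (must
#'   contain a `dsp` column with at least 2 rows each).
#' @param output optional JSON path for the comparison report.
#' @param names_ab group labels for the report.
#' @return The comparison report as a list.
#' @export
run_compare <- function(group_a_csv, group_b_csv, output = NULL,
                        names_ab = c("A", "B")) {
  read_dsp <- function(path) {
    if (!file.exists(path))
      stop("group file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path)
    if (!("dsp" %in% names(df)))
      stop("no `dsp` column in ", path, call. = FALSE)
    if (nrow(df) < 2L)
      stop("need at least 2 dsp rows in ", path, call. = FALSE)
    df$dsp
  }
  a <- read_dsp(group_a_csv)
  b <- read_dsp(group_b_csv)
  cmp <- compare_groups(a, b)
  report <- c(list(group_a = names_ab[1L], group_b = names_ab[2L]), cmp)
  if (!is.null(output))
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA)
  report
}
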