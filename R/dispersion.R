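#' Mean distance from an edge segment to the nucleus centers
#'
#' An edge is represented by the centroid of its pixel coordinates; the
#' feature is the arithmetic mean of the Euclidean distances from that
#' centroid to every detected blue center. With a single nucleus this is
#' the plain center-to-edge distance.
#'
#' @param seg an `edge_segment` (or an n x 2 coordinate matrix).
#' @param centers numeric matrix with one `(row, col)` center per row.
#' @return Mean distance in pixels.
#' @export
compute_davg <- function(seg, centers) {
  coords <- if (inherits(seg, "edge_segment")) seg$pixel_coords else seg
  centers <- rbind(centers)
  if (is.null(centers) || nrow(centers) == 0L)
    stop("no nuclei detected: cannot compute distance features",
         call. = FALSE)
  cr <- mean(coords[, 1L]); cc <- mean(coords[, 2L])
  mean(sqrt((centers[, 1L] - cr)^2 + (centers[, 2L] - cc)^2))
}

#' Build (distance, angle) feature points
#'
#' Pairs every surviving edge segment with its mean distance to the
#' nucleus centers and its orientation angle. Each pair is one point in
#' the 2D feature space whose histogram entropy defines the dispersion.
#'
#' @param segments list of `edge_segment` from [extract_segments()].
#' @param nuclei list of `nucleus_region` from [detect_nuclei()].
#' @return A data frame with columns `segment_id`, `davg`, `angle_deg`.
#' @export
build_feature_points <- function(segments, nuclei) {
  if (length(segments) == 0L)
    stop("no fiber edges detected", call. = FALSE)
  if (length(nuclei) == 0L)
    stop("no nuclei detected", call. = FALSE)
  centers <- do.call(rbind, lapply(nuclei, function(n) n$centroid))
  data.frame(
    segment_id = vapply(segments, function(s) s$id, numeric(1)),
    davg = vapply(segments, compute_davg, numeric(1), centers = centers),
    angle_deg = vapply(segments, function(s) s$angle_deg, numeric(1)))
}

#' 2D histogram of feature points
#'
#' Bins the `(davg, angle)` points on a regular grid: equal-width distance
#' bins over `[0, d_max]` (by default `d_max` is the largest observed
#' distance, with the maximum placed in the top bin) and equal-width angle
#' bins over `[0, 180)` degrees. Cell probabilities are counts divided by
#' the number of points.
#'
#' @param points data frame from [build_feature_points()] (columns `davg`,
#'   `angle_deg`).
#' @param n_dist_bins,n_angle_bins bin counts per axis; the product is the
#'   number of subspaces n and must be at least 2.
#' @param d_max optional fixed upper distance bound (pixels) for
#'   cross-image comparability; `NULL` uses the per-image maximum.
#' @return An object of class `histogram2d` with `counts`, `probs`,
#'   `edges_dist`, `edges_angle`, `n_points`, `n_bins`.
#' @export
bin_features <- function(points, n_dist_bins = 8L, n_angle_bins = 8L,
                         d_max = NULL) {
  n_dist_bins <- as.integer(n_dist_bins)
  n_angle_bins <- as.integer(n_angle_bins)
  if (n_dist_bins < 1L || n_angle_bins < 1L ||
      n_dist_bins * n_angle_bins < 2L)
    stop("bin counts must be >= 1 with product >= 2", call. = FALSE)
  np <- nrow(points)
  if (is.null(np) || np == 0L)
    stop("no feature points to bin", call. = FALSE)
  d <- points$davg
  a <- points$angle_deg
  if (any(d < 0) || any(a < 0 | a >= 180))
    stop("feature points out of range (davg >= 0, angle in [0, 180))",
         call. = FALSE)
  dm <- if (is.null(d_max)) max(d) else d_max
  if (dm <= 0) {
    di <- rep(1L, np)  # all distances zero: single degenerate bin
    dm <- 1
  } else {
    di <- pmin(floor(d / dm * n_dist_bins) + 1L, n_dist_bins)
    di[d > dm] <- n_dist_bins  # fixed-range mode: clamp overshoot to top
  }
  ai <- pmin(floor(a / 180 * n_angle_bins) + 1L, n_angle_bins)
  counts <- matrix(0L, n_dist_bins, n_angle_bins)
  tab <- table(factor(di, levels = seq_len(n_dist_bins)),
               factor(ai, levels = seq_len(n_angle_bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts,
                 probs = counts / np,
                 edges_dist = seq(0, dm, length.out = n_dist_bins + 1L),
                 edges_angle = seq(0, 180, length.out = n_angle_bins + 1L),
                 n_points = np,
                 n_dist_bins = n_dist_bins,
                 n_angle_bins = n_angle_bins,
                 n_bins = n_dist_bins * n_angle_bins),
            class = "histogram2d")
}

#' Shannon entropy of a 2D histogram
#'
#' `etp = sum over cells of -p log(p)` in nats, with the convention
#' `0 log 0 = 0`. Bounded by `log(n)` for n cells.
#'
#' @param h a `histogram2d` (or a numeric vector/matrix of probabilities).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(h) {
  p <- if (inherits(h, "histogram2d")) h$probs else h
  p <- as.vector(p)
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  etp <- -sum(p * log(p))
  if (etp <= 0) 0 else etp  # guard the -0 of a single-cell histogram
}

#' Normalized spatial dispersion
#'
#' Divides the histogram entropy by its maximum `log(n)` (uniform
#' occupancy of the n subspaces), normalizing to `[0, 1]`: 0 means all
#' feature points share one cell (perfect order), 1 means uniform spread
#' (maximal disorder). The ratio is invariant to the logarithm base.
#'
#' @param etp entropy in nats, in `[0, log(n_bins)]`.
#' @param n_bins total number of histogram cells, at least 2.
#' @return Dispersion in `[0, 1]`.
#' @export
dispersion <- function(etp, n_bins) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("`n_bins` must be >= 2", call. = FALSE)
  if (!is.numeric(etp) || length(etp) != 1L || etp < 0 ||
      etp > log(n_bins) + 1e-9)
    stop("`etp` must lie in [0, log(n_bins)]", call. = FALSE)
  min(max(etp / log(n_bins), 0), 1)
}

#' End-to-end spatial dispersion of a micrograph
#'
#' Runs the full pipeline on an RGB micrograph: standardize to the square
#' working frame, detect stress-fiber edges on the actin channel with the
#' statistics-adaptive Canny detector, segment nuclei in HSV space,
#' build per-edge (mean distance, angle) feature points, and compute the
#' normalized histogram entropy.
#'
#' @param img RGB [raster_image] (any size; standardized internally).
#' @param config a [run_config()]; defaults control every stage.
#' @return An object of class `dispersion_result` with `etp` (nats),
#'   `dsp` in `[0, 1]`, `n_points`, `n_nuclei`, `n_bins`, `histogram`,
#'   `features`, and the full `params` record.
#' @export
compute_dispersion <- function(img, config = run_config()) {
  stopifnot(is_raster_image(img))
  config <- as_run_config(config)
  std <- standardize(img, side = config$side)
  if (std$n_channels != 3L && is.null(std$channel_roles))
    stop("compute_dispersion requires an RGB micrograph (or explicit ",
         "channel roles)", call. = FALSE)
  actin <- extract_channel(std, "actin")
  edge_map <- canny_edges(actin, sigma = config$sigma,
                          reduction_ratio = config$reduction_ratio)
  segments <- extract_segments(edge_map,
                               min_edge_length = config$min_edge_length)
  if (length(segments) == 0L)
    stop("no fiber edges detected (edge detection stage)", call. = FALSE)
  rng <- hsv_range(config$hsv_range$hue_lo, config$hsv_range$hue_hi,
                   config$hsv_range$sat_lo, config$hsv_range$val_lo)
  nuclei <- detect_nuclei(std, range = rng,
                          min_region_area = config$min_region_area)
  if (length(nuclei) == 0L)
    stop("no nuclei detected (nucleus segmentation stage)", call. = FALSE)
  feats <- build_feature_points(segments, nuclei)
  dmax <- if (identical(config$distance_range_mode, "fixed"))
    config$fixed_d_max else NULL
  h <- bin_features(feats, n_dist_bins = config$n_dist_bins,
                    n_angle_bins = config$n_angle_bins, d_max = dmax)
  etp <- shannon_entropy(h)
  structure(list(etp = etp,
                 dsp = dispersion(etp, h$n_bins),
                 n_points = h$n_points,
                 n_nuclei = length(nuclei),
                 n_segments = length(segments),
                 n_bins = h$n_bins,
                 histogram = h,
                 features = feats,
                 params = config),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion_result> dsp = %.4f (etp = %.4f nats, n = %d bins)\n",
    x$dsp, x$etp, x$n_bins))
  cat(sprintf("  %d feature points from %d edge segments, %d nuclei\n",
              x$n_points, x$n_segments, x$n_nuclei))
  invisible(x)
}

#' Two-group comparison of dispersion scores
#'
#' Unpaired pooled-variance Student t-test between two groups of
#' per-image dispersion values, with per-group mean and standard error.
#'
#' @param dsp_a,dsp_b numeric vectors of dispersion values, each of
#'   length at least 2.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(dsp_a, dsp_b) {
  dsp_a <- as.numeric(dsp_a); dsp_b <- as.numeric(dsp_b)
  if (length(dsp_a) < 2L || length(dsp_b) < 2L)
    stop("each group needs at least 2 values for the t-test",
         call. = FALSE)
  tt <- stats::t.test(dsp_a, dsp_b, var.equal = TRUE)
  list(t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       mean_a = mean(dsp_a), mean_b = mean(dsp_b),
       sem_a = stats::sd(dsp_a) / sqrt(length(dsp_a)),
       sem_b = stats::sd(dsp_b) / sqrt(length(dsp_b)),
       n_a = length(dsp_a), n_b = length(dsp_b))
}
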