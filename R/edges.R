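# 3x3 correlation with replicate borders; m is a (row, col) matrix
conv3 <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  p[1L, ] <- p[2L, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1L] <- p[, 2L]; p[, w + 2L] <- p[, w + 1L]
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * p[i:(i + h - 1L), j:(j + w - 1L)]
  }
  out
}

# separable Gaussian convolution with replicate borders; spatial-domain
# (not FFT) so flat regions stay exactly flat
sep_gauss <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # columns pass
  p <- m[, c(rep(1L, r), 1:w, rep(w, r))]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * p[, j:(j + w - 1L)]
  # rows pass
  p <- out[c(rep(1L, r), 1:h, rep(h, r)), ]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * p[j:(j + h - 1L), ]
  out
}

# shift matrix by (dr, dc), zero fill
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Gaussian smoothing
#'
#' Low-pass filters a single-channel image with an isotropic Gaussian
#' kernel (replicated borders), the denoising step preceding gradient
#' computation.
#'
#' @param img single-channel [raster_image].
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return A smoothed single-channel [raster_image].
#' @export
gaussian_smooth <- function(img, sigma = 1.4) {
  assert_single_channel(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  sm <- sep_gauss(img$pixels, sigma)
  raster_image(pmin(pmax(sm, 0), 1),
               bit_depth = img$bit_depth, meta = img$meta)
}

#' Sobel gradient field
#'
#' Computes horizontal and vertical intensity gradients with the 3x3 Sobel
#' stencils and the per-pixel gradient magnitude
#' \eqn{G = \sqrt{G_x^2 + G_y^2}}, together with the mean M and population
#' standard deviation S of G over all pixels. M and S drive the adaptive
#' hysteresis thresholds of [compute_thresholds()].
#'
#' @param img single-channel [raster_image].
#' @return An object of class `gradient_field` with elements `gx`, `gy`,
#'   `magnitude`, `mean_mag`, `sd_mag`.
#' @export
compute_gradients <- function(img) {
  assert_single_channel(img)
  m <- img$pixels
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3(m, kx)       # d/dcol
  gy <- conv3(m, t(kx))    # d/drow
  g <- sqrt(gx^2 + gy^2)
  mu <- mean(g)
  s <- sqrt(mean((g - mu)^2))  # population form
  structure(list(gx = gx, gy = gy, magnitude = g,
                 mean_mag = mu, sd_mag = s),
            class = "gradient_field")
}

#' Adaptive dual thresholds from gradient statistics
#'
#' The hysteresis thresholds adapt to the image's own gradient statistics:
#' the upper threshold is `Tmax = M + 2 S` (mean plus two population
#' standard deviations of the gradient magnitude) and the lower threshold
#' is `Tmin = Tmax / T`, where `T >= 1` is the reduction ratio.
#'
#' @param field a `gradient_field` from [compute_gradients()].
#' @param reduction_ratio the reduction ratio T, at least 1.
#' @return An object of class `threshold_pair` with `t_max`, `t_min`,
#'   `reduction_ratio`.
#' @export
compute_thresholds <- function(field, reduction_ratio = 2) {
  if (!inherits(field, "gradient_field"))
    stop("`field` must be a gradient_field", call. = FALSE)
  if (!is.numeric(reduction_ratio) || length(reduction_ratio) != 1L ||
      !is.finite(reduction_ratio) || reduction_ratio < 1)
    stop("`reduction_ratio` must be >= 1", call. = FALSE)
  t_max <- field$mean_mag + 2 * field$sd_mag
  structure(list(t_max = t_max, t_min = t_max / reduction_ratio,
                 reduction_ratio = reduction_ratio),
            class = "threshold_pair")
}

# non-maximum suppression along the quantized gradient direction.
# Returns the magnitude image with non-maxima zeroed. One strict
# comparison guarantees that two adjacent pixels sharing a quantized
# direction can never both survive.
nms_suppress <- function(gx, gy, mag) {
  theta <- atan2(gy, gx) * 180 / pi
  theta <- theta %% 180
  sector <- integer(length(theta))
  dim(sector) <- dim(theta)
  sector[theta >= 22.5 & theta < 67.5] <- 1L   # 45 deg
  sector[theta >= 67.5 & theta < 112.5] <- 2L  # 90 deg
  sector[theta >= 112.5 & theta < 157.5] <- 3L # 135 deg
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  n_fwd <- matrix(0, nrow(mag), ncol(mag))
  n_bwd <- n_fwd
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    o <- offs[[s + 1L]]
    f <- shift_mat(mag, -o[1L], -o[2L])  # value at (r+dr, c+dc)
    b <- shift_mat(mag, o[1L], o[2L])
    n_fwd[sel] <- f[sel]
    n_bwd[sel] <- b[sel]
  }
  floor_mag <- 1e-9 * max(mag)  # guard against numerical ripple
  keep <- mag > floor_mag & mag >= n_fwd & mag > n_bwd
  out <- mag
  out[!keep] <- 0
  out
}

# 8-connected labeling of a logical/binary matrix; returns an integer
# matrix of component labels (0 = background). Sparse-foreground
# implementation: neighbor pairs become graph edges, components are
# labeled with igraph.
label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0)
  lab <- matrix(0L, h, w)
  k <- length(fg)
  if (k == 0L) return(lab)
  id <- integer(h * w)
  id[fg] <- seq_len(k)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  for (o in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + o[1L]; cn <- c + o[2L]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    if (!any(ok)) next
    nb <- (cn[ok] - 1L) * h + rn[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok][hit]], id[nb[hit]]))
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = k, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(k)
  }
  lab[fg] <- as.integer(memb)
  lab
}

#' Canny edge map with statistics-adaptive hysteresis
#'
#' Detects stress-fiber edges: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction
#' (4 sectors), and dual-threshold hysteresis. Pixels at or above `Tmax`
#' seed edges; pixels in `[Tmin, Tmax)` are kept only when 8-connected to
#' a seed through above-`Tmin` pixels. The thresholds come from
#' [compute_thresholds()], so they track the image's gradient statistics.
#'
#' @param img standardized single-channel [raster_image].
#' @param sigma Gaussian smoothing scale in pixels.
#' @param reduction_ratio threshold reduction ratio T.
#' @return A logical matrix (same size as `img`) marking edge pixels.
#' @export
canny_edges <- function(img, sigma = 1.4, reduction_ratio = 2) {
  sm <- gaussian_smooth(img, sigma)
  field <- compute_gradients(sm)
  thr <- compute_thresholds(field, reduction_ratio)
  # on the [0,1] intensity scale a threshold this small can only arise
  # from floating-point residue of a flat field: no real edges
  if (thr$t_max <= 1e-8)
    return(matrix(FALSE, img$height, img$width))
  nm <- nms_suppress(field$gx, field$gy, field$magnitude)
  strong <- nm >= thr$t_max
  weak <- nm >= thr$t_min
  if (!any(strong)) return(matrix(FALSE, img$height, img$width))
  lab <- label8(weak)
  keep_labels <- unique(lab[strong])
  lab > 0L & lab %in% keep_labels
}

#' Connected edge segments
#'
#' Groups an edge map into 8-connected components, discards components
#' shorter than `min_edge_length` pixels (short spurious edges), and
#' computes each survivor's orientation by principal-axis fit.
#'
#' @param edge_map logical or 0/1 matrix from [canny_edges()].
#' @param min_edge_length minimum component size in pixels.
#' @return A list of `edge_segment` objects, each with `pixel_coords`
#'   (n x 2 matrix of row, col), `length`, `angle_deg` and a `davg` slot
#'   filled later by the dispersion stage.
#' @export
extract_segments <- function(edge_map, min_edge_length = 10L) {
  lab <- label8(edge_map)
  if (!any(lab > 0L)) return(list())
  fg <- which(lab > 0L)
  h <- nrow(lab)
  df <- data.frame(lab = lab[fg],
                   row = ((fg - 1L) %% h) + 1L,
                   col = ((fg - 1L) %/% h) + 1L)
  df <- df[order(df$lab, df$row, df$col), ]
  split_idx <- split(seq_len(nrow(df)), df$lab)
  segs <- list()
  sid <- 0L
  for (ix in split_idx) {
    if (length(ix) < min_edge_length) next
    coords <- cbind(row = df$row[ix], col = df$col[ix])
    sid <- sid + 1L
    seg <- structure(list(id = sid, pixel_coords = coords,
                          length = nrow(coords),
                          angle_deg = NA_real_, davg = NA_real_),
                     class = "edge_segment")
    seg$angle_deg <- segment_orientation(seg)
    segs[[sid]] <- seg
  }
  segs
}

#' Orientation of an edge segment
#'
#' Angle of the principal axis of the segment's pixel coordinates,
#' measured against the horizontal axis in the mathematical convention
#' (counterclockwise positive, with the image y-axis pointing up), folded
#' into `[0, 180)` degrees. Undirected fibers make the two antipodal
#' directions equivalent, hence the half-circle range.
#'
#' @param seg an `edge_segment` with at least 2 pixels.
#' @return Orientation in degrees, in `[0, 180)`.
#' @export
segment_orientation <- function(seg) {
  coords <- if (inherits(seg, "edge_segment")) seg$pixel_coords else seg
  if (is.null(dim(coords)) || nrow(coords) < 2L)
    stop("orientation undefined for a segment with fewer than 2 pixels",
         call. = FALSE)
  x <- coords[, 2L]            # col
  y <- -coords[, 1L]           # math y-axis points up
  xm <- x - mean(x); ym <- y - mean(y)
  sxx <- mean(xm^2); syy <- mean(ym^2); sxy <- mean(xm * ym)
  if (sxx == syy && sxy == 0) return(0)  # isotropic: no preferred axis
  ang <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  ang %% 180
}
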