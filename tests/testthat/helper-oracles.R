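# Independent oracles and small fixture builders shared across tests.

# nested-loop entropy oracle, deliberately naive
entropy_oracle <- function(probs) {
  total <- 0
  for (p in as.vector(probs)) {
    if (p > 0) total <- total - p * log(p)
  }
  total
}

# nested-loop 2D binning oracle: counts points per cell one at a time
binning_oracle <- function(d, a, n_dist, n_angle, d_max = max(d)) {
  counts <- matrix(0L, n_dist, n_angle)
  for (i in seq_along(d)) {
    di <- if (d_max <= 0) 1L else min(floor(d[i] / d_max * n_dist) + 1L, n_dist)
    ai <- min(floor(a[i] / 180 * n_angle) + 1L, n_angle)
    counts[di, ai] <- counts[di, ai] + 1L
  }
  counts
}

# two-pass mean / population-sd oracle
two_pass_stats <- function(x) {
  x <- as.vector(x)
  m <- sum(x) / length(x)
  s2 <- sum((x - m)^2) / length(x)
  c(mean = m, sd = sqrt(s2))
}

# bright line of given width/contrast on a dark background
make_line_image <- function(rows = 250:252, cols = 50:460, bg = 0.05,
                            fg = 0.85, side = 512L) {
  m <- matrix(bg, side, side)
  m[rows, cols] <- fg
  raster_image(m)
}

# no aligned pair of NMS survivors may share the quantized direction
count_same_direction_pairs <- function(gx, gy, nms_mag) {
  theta <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- matrix(0L, nrow(nms_mag), ncol(nms_mag))
  sector[theta >= 22.5 & theta < 67.5] <- 1L
  sector[theta >= 67.5 & theta < 112.5] <- 2L
  sector[theta >= 112.5 & theta < 157.5] <- 3L
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  kept <- nms_mag > 0
  shift01 <- function(m, dr, dc) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  total <- 0L
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    a <- kept & sector == s
    b <- shift01(a, -o[1L], -o[2L]) & shift01(sector == s, -o[1L], -o[2L])
    total <- total + sum(a & b)
  }
  total
}

# angular difference on the half-circle
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# axial circular variance: 1 - mean resultant length of doubled angles
axial_circ_var <- function(angles_deg) {
  th <- 2 * angles_deg * pi / 180
  1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}
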