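test_that("Gaussian smoothing preserves constants, mass and symmetry", {
  const <- raster_image(matrix(0.3, 64, 64))
  expect_equal(gaussian_smooth(const, 2)$pixels, const$pixels)

  # single bright pixel -> symmetric blob peaking at the source
  m <- matrix(0, 41, 41)
  m[21, 21] <- 1
  sm <- gaussian_smooth(raster_image(m), 1)$pixels
  expect_equal(which(sm == max(sm)), which(m == 1))
  expect_equal(sm[21 + 3, 21], sm[21 - 3, 21])
  expect_equal(sm[21, 21 + 3], sm[21, 21 - 3])
  expect_equal(sm, t(sm))

  # total intensity conserved within 0.5% (interior-dominated image)
  set.seed(1)
  x <- matrix(runif(512 * 512), 512, 512)
  sm2 <- gaussian_smooth(raster_image(x), 1.4)$pixels
  expect_lt(abs(sum(sm2) / sum(x) - 1), 0.005)

  expect_error(gaussian_smooth(const, 0), "positive")
  expect_error(gaussian_smooth(const, -1), "positive")
})

test_that("smoothing reduces the variance of white noise", {
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(runif(64 * 64), 64, 64)
    sm <- gaussian_smooth(raster_image(x), 1.4)$pixels
    expect_lt(var(as.vector(sm)), var(as.vector(x)))
  }
})

test_that("Sobel gradient field satisfies the magnitude identity", {
  set.seed(7)
  img <- raster_image(matrix(runif(32 * 32), 32, 32))
  f <- compute_gradients(img)
  expect_equal(f$magnitude, sqrt(f$gx^2 + f$gy^2))
  expect_true(all(f$magnitude >= 0))
  # 3-4-5 identity holds pointwise by construction of the magnitude
  expect_equal(sqrt(3^2 + 4^2), 5)

  const <- compute_gradients(raster_image(matrix(0.5, 16, 16)))
  expect_equal(const$mean_mag, 0)
  expect_equal(const$sd_mag, 0)
  expect_true(all(const$magnitude == 0))

  expect_error(compute_gradients(
    raster_image(array(0.1, c(4, 4, 3)))), "single-channel")
})

test_that("a vertical step edge concentrates gx on the step", {
  # 5x5 toy grid, step between columns 2 and 3
  m <- matrix(0, 5, 5)
  m[, 3:5] <- 1
  f <- compute_gradients(raster_image(m))
  # direct Sobel stencil arithmetic: interior response rows, step columns
  expect_equal(f$gx[3, 2], 4)   # (1+2+1) * step across the stencil
  expect_equal(f$gx[3, 3], 4)
  expect_equal(f$gy[3, 2], 0)
  expect_true(all(abs(f$gy[2:4, 2:4]) < 1e-12))
  expect_equal(which.max(abs(f$gx[3, ])), 2)
})

test_that("adaptive thresholds follow Tmax = M + 2S and Tmin = Tmax/T", {
  mk_field <- function(mag) {
    structure(list(gx = mag, gy = mag * 0, magnitude = mag,
                   mean_mag = mean(mag),
                   sd_mag = sqrt(mean((mag - mean(mag))^2))),
              class = "gradient_field")
  }
  # zero-variance field
  thr <- compute_thresholds(mk_field(matrix(10, 4, 4)), 2)
  expect_equal(thr$t_max, 10)
  expect_equal(thr$t_min, 5)
  # {0, 20}: M = 10, population S = 10 -> Tmax = 30
  thr2 <- compute_thresholds(mk_field(matrix(c(0, 20), 4, 4)), 2)
  expect_equal(thr2$t_max, 30)
  expect_equal(thr2$t_min, 15)

  # seeded random field vs independent two-pass oracle
  set.seed(11)
  f <- compute_gradients(raster_image(matrix(runif(64 * 64), 64, 64)))
  thr3 <- compute_thresholds(f, 2.5)
  st <- two_pass_stats(f$magnitude)
  expect_equal(thr3$t_max, st["mean"] + 2 * st["sd"],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(thr3$t_min, thr3$t_max / 2.5)

  expect_error(compute_thresholds(f, 0.5), ">= 1")
})

test_that("canny_edges finds a bright line and nothing in a blank image", {
  blank <- raster_image(matrix(0.2, 512, 512))
  expect_equal(sum(canny_edges(blank)), 0)

  img <- make_line_image()
  em <- canny_edges(img)
  w <- which(em, arr.ind = TRUE)
  expect_gt(nrow(w), 0)
  # all edge pixels within 2 px of the line border
  expect_true(all(w[, 1] >= 248 & w[, 1] <= 254 &
                    w[, 2] >= 48 & w[, 2] <= 462))
  expect_gte(max(actindisp:::label8(em)), 1)
})

test_that("thresholds adapt: faint texture does not inflate edge counts", {
  clean <- make_line_image()
  set.seed(11)
  noisy_m <- clean$pixels +
    matrix(runif(512 * 512, -0.05, 0.05), 512, 512)
  noisy <- raster_image(pmin(pmax(noisy_m, 0), 1))
  n_clean <- sum(canny_edges(clean))
  n_noisy <- sum(canny_edges(noisy))
  expect_lt(abs(n_noisy - n_clean) / n_clean, 0.10)
})

test_that("NMS leaves no aligned same-direction survivor pairs", {
  for (s in c(3, 5)) {
    fx <- generate_fixture(fixture_spec(seed = s))
    actin <- extract_channel(fx$image, "actin")
    f <- compute_gradients(gaussian_smooth(actin, 1.4))
    nm <- actindisp:::nms_suppress(f$gx, f$gy, f$magnitude)
    expect_equal(count_same_direction_pairs(f$gx, f$gy, nm), 0)
  }
})

test_that("edge maps are deterministic", {
  img <- extract_channel(generate_fixture(fixture_spec(seed = 2))$image,
                         "actin")
  expect_identical(canny_edges(img), canny_edges(img))
})

test_that("extract_segments filters short components and recovers drawn ones", {
  em <- matrix(FALSE, 64, 64)
  em[10, 5:44] <- TRUE    # length 40
  em[40, 3:5] <- TRUE     # length 3
  segs <- extract_segments(em, min_edge_length = 10)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$length, 40)

  expect_length(extract_segments(matrix(FALSE, 8, 8)), 0)

  # k = 5 disjoint drawn components recovered with exact pixel sets
  em2 <- matrix(FALSE, 100, 100)
  truth <- list()
  for (k in 1:5) {
    rows <- k * 15
    truth[[k]] <- cbind(row = rows, col = 10:(10 + 11 + k))
    em2[rows, 10:(10 + 11 + k)] <- TRUE
  }
  segs2 <- extract_segments(em2, min_edge_length = 10)
  expect_length(segs2, 5)
  got <- lapply(segs2, function(s)
    s$pixel_coords[order(s$pixel_coords[, 1], s$pixel_coords[, 2]), ])
  got <- got[order(vapply(got, function(m) m[1, 1], numeric(1)))]
  for (k in 1:5)
    expect_equal(unname(got[[k]]), unname(truth[[k]]))
})

test_that("segment orientation matches axis conventions and line fits", {
  horiz <- cbind(row = rep(5, 10), col = 1:10)
  expect_equal(segment_orientation(horiz), 0)
  vert <- cbind(row = 1:10, col = rep(5, 10))
  expect_equal(segment_orientation(vert), 90)
  # slope 1 in math convention: row decreases as col increases
  diag_up <- cbind(row = 10:1, col = 1:10)
  expect_equal(segment_orientation(diag_up), 45, tolerance = 1e-6)
  # matches the closed-form least-squares fit on the same points
  fit <- stats::lm(I(-row) ~ col, data = as.data.frame(diag_up))
  expect_equal(segment_orientation(diag_up),
               (atan(coef(fit)[[2]]) * 180 / pi) %% 180,
               tolerance = 1e-6)

  expect_error(segment_orientation(cbind(row = 3, col = 3)),
               "fewer than 2")
})

test_that("orientation is invariant to pixel order and translation", {
  set.seed(21)
  base <- cbind(row = 1:30 + rnorm(30, 0, 0.2), col = (1:30) * 0.7)
  a0 <- segment_orientation(base)
  expect_equal(segment_orientation(base[sample(30), ]), a0)
  expect_equal(segment_orientation(base + 17), a0)
})

test_that("rotating the image by 90 degrees rotates recovered orientations", {
  fx <- generate_fixture(fixture_spec(
    n_filaments = 1, orientation_mode_deg = 30, orientation_kappa = 1e6,
    length_range = c(60, 60), nuclei = list(c(400, 400, 12)), seed = 9))
  actin <- extract_channel(fx$image, "actin")
  segs <- extract_segments(canny_edges(actin))
  expect_gte(length(segs), 1)
  a0 <- segs[[1]]$angle_deg
  # rotate the pixel grid 90 degrees counterclockwise
  rot <- raster_image(t(actin$pixels)[rev(seq_len(512)), ])
  segs_r <- extract_segments(canny_edges(rot))
  expect_gte(length(segs_r), 1)
  a1 <- segs_r[[1]]$angle_deg
  expect_lt(axial_diff(a1, (a0 + 90) %% 180), 3)
})
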