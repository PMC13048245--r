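fake_segment <- function(coords, id = 1L) {
  structure(list(id = id, pixel_coords = coords,
                 length = nrow(coords),
                 angle_deg = segment_orientation(coords),
                 davg = NA_real_),
            class = "edge_segment")
}

fake_nucleus <- function(row, col) {
  structure(list(mask = cbind(row = row, col = col), area = 1L,
                 centroid = c(row = row, col = col)),
            class = "nucleus_region")
}

test_that("compute_davg averages center distances from the edge centroid", {
  seg <- cbind(row = c(2, 3, 4), col = c(3, 4, 5))  # centroid (3, 4)
  expect_equal(compute_davg(seg, rbind(c(0, 0))), 5)
  expect_equal(compute_davg(seg, rbind(c(0, 0), c(6, 8))), 5)
  expect_error(compute_davg(seg, NULL), "no nuclei")
})

test_that("build_feature_points emits one point per segment", {
  segs <- lapply(1:5, function(i)
    fake_segment(cbind(row = rep(i * 10, 5), col = 1:5), id = i))
  nucs <- list(fake_nucleus(10, 10), fake_nucleus(40, 40))
  pts <- build_feature_points(segs, nucs)
  expect_equal(nrow(pts), 5)
  expect_true(all(pts$davg >= 0))
  expect_error(build_feature_points(list(), nucs), "no fiber edges")
  expect_error(build_feature_points(segs, list()), "no nuclei")
})

test_that("binning reproduces hand-checkable occupancy patterns", {
  # 4 points, one per cell of a 2x2 grid
  pts <- data.frame(davg = c(1, 1, 9, 9), angle_deg = c(10, 100, 10, 100))
  h <- bin_features(pts, 2, 2)
  expect_true(all(h$probs == 0.25))
  expect_equal(sum(h$counts), 4)

  # all points identical -> a single cell with p = 1
  same <- data.frame(davg = rep(5, 7), angle_deg = rep(33, 7))
  h2 <- bin_features(same, 4, 4)
  expect_equal(sort(as.vector(h2$probs), decreasing = TRUE)[1], 1)
  expect_equal(sum(h2$probs > 0), 1)

  expect_error(bin_features(pts, 1, 1), "product")
  expect_error(bin_features(pts[0, ], 2, 2), "no feature points")
})

test_that("binning matches the nested-loop counting oracle exactly", {
  set.seed(13)
  n <- 1000
  pts <- data.frame(davg = runif(n, 0, 300),
                    angle_deg = runif(n, 0, 180 - 1e-9))
  h <- bin_features(pts, 8, 8)
  oracle <- binning_oracle(pts$davg, pts$angle_deg, 8, 8)
  expect_identical(unname(h$counts), unname(oracle))
  expect_equal(sum(h$probs), 1, tolerance = 1e-12)
})

test_that("entropy and dispersion satisfy their closed forms", {
  expect_equal(shannon_entropy(c(1)), 0)
  expect_equal(shannon_entropy(rep(1 / 64, 64)), log(64))
  expect_equal(shannon_entropy(c(0.25, 0.75)),
               -0.25 * log(0.25) - 0.75 * log(0.75))
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.5623, tolerance = 1e-4)

  expect_equal(dispersion(0, 64), 0)
  expect_equal(dispersion(log(64), 64), 1)
  expect_equal(dispersion(0.5623, 64), 0.1352, tolerance = 1e-3)
  expect_error(dispersion(0.5, 1), "n_bins")
})

test_that("end-to-end dispersion is deterministic and stage errors are named", {
  fx <- generate_fixture(fixture_spec(n_filaments = 15L, seed = 31))
  r1 <- compute_dispersion(fx$image)
  r2 <- compute_dispersion(fx$image)
  expect_identical(r1, r2)
  expect_true(r1$dsp >= 0 && r1$dsp <= 1)
  expect_equal(r1$dsp, r1$etp / log(r1$n_bins), tolerance = 1e-12)

  bare <- generate_fixture(fixture_spec(n_filaments = 0L, noise_sd = 0,
                                        seed = 32))
  expect_error(compute_dispersion(bare$image), "no fiber edges")

  no_nuc <- generate_fixture(fixture_spec(n_filaments = 10L,
                                          nuclei = list(), seed = 33))
  expect_error(compute_dispersion(no_nuc$image), "no nuclei")
})

test_that("dispersion is invariant to segment processing order", {
  fx <- generate_fixture(fixture_spec(seed = 17))
  std <- standardize(fx$image)
  actin <- extract_channel(std, "actin")
  segs <- extract_segments(canny_edges(actin))
  nucs <- detect_nuclei(std)
  base <- build_feature_points(segs, nucs)
  set.seed(1)
  shuf <- build_feature_points(segs[sample(length(segs))], nucs)
  h0 <- bin_features(base, 8, 8)
  h1 <- bin_features(shuf, 8, 8)
  expect_identical(h0$counts, h1$counts)
  expect_equal(shannon_entropy(h0), shannon_entropy(h1),
               tolerance = 1e-12)
})

test_that("translating the nucleus shifts davg by the analytic amount", {
  seg <- fake_segment(cbind(row = 100:120, col = rep(50, 21)))
  c0 <- rbind(c(200, 50))
  c1 <- rbind(c(230, 50))  # 30 px further down the same column
  expect_equal(compute_davg(seg, c0), 90)
  expect_equal(compute_davg(seg, c1) - compute_davg(seg, c0), 30)
})

test_that("mean dsp decreases as orientation concentration grows", {
  kappas <- c(0, 2, 8, 32)
  n_seeds <- 20
  dsp <- sapply(kappas, function(k) {
    sapply(seq_len(n_seeds), function(s) {
      fx <- generate_fixture(fixture_spec(orientation_kappa = k,
                                          seed = 200 * k + s))
      compute_dispersion(fx$image)$dsp
    })
  })
  m <- colMeans(dsp)
  sem <- apply(dsp, 2, sd) / sqrt(n_seeds)
  for (i in 1:3) {
    expect_gt(m[i] - m[i + 1], 0)
    expect_gt(m[i] - m[i + 1], sqrt(sem[i]^2 + sem[i + 1]^2))
  }
})

test_that("the pooled Student t-test matches its closed form", {
  same <- compare_groups(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  cmp <- compare_groups(a, b)
  # closed-form pooled-variance oracle
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_or <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(cmp$t, t_or, tolerance = 1e-12)
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(t_or, 4), tolerance = 1e-12)
  expect_equal(cmp$p, 0.0213, tolerance = 1e-3)
  expect_equal(cmp$sem_a, sd(a) / sqrt(3))

  expect_error(compare_groups(c(1, 2), 1), "at least 2")
})
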