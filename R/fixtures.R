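#' Synthetic micrograph specification
#'
#' Parameters of the seeded fixture generator. Fixtures emulate the
#' structure of phalloidin/DAPI micrographs: bright curvilinear actin
#' filaments (anti-aliased straight segments in the green channel, whose
#' soft profile mimics the microscope point-spread), one or more blue
#' disk-like nuclei, a dim background, and additive Gaussian noise so the
#' adaptive thresholds see nonzero gradient statistics.
#'
#' @param n_filaments number of filaments to draw.
#' @param orientation_mode_deg modal filament orientation, degrees in
#'   `[0, 180)`.
#' @param orientation_kappa von Mises concentration of the orientations
#'   (on doubled angles, the correct treatment for undirected fibers);
#'   0 gives the uniform axial distribution.
#' @param length_range `(min, max)` filament length in pixels.
#' @param width filament width in pixels.
#' @param filament_intensity peak filament intensity in `[0, 1]`.
#' @param nuclei list of `c(center_row, center_col, radius)` triples;
#'   radii must be at least 3 px.
#' @param noise_sd Gaussian pixel noise standard deviation; must stay
#'   below `filament_intensity / 2` to guarantee contrast.
#' @param background background level added to all channels.
#' @param placement `"uniform"` scatters filament centers over the frame;
#'   `"arc"` places them on a circle of radius `arc_radius` around the
#'   first nucleus (the ordered arrangement).
#' @param arc_radius radius in pixels for `"arc"` placement.
#' @param side frame side length in pixels.
#' @param seed RNG seed; identical specs yield byte-identical images.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_filaments = 40L,
                         orientation_mode_deg = 45,
                         orientation_kappa = 0,
                         length_range = c(40, 80),
                         width = 3,
                         filament_intensity = 0.8,
                         nuclei = list(c(256, 256, 18)),
                         noise_sd = 0.02,
                         background = 0.05,
                         placement = c("uniform", "arc"),
                         arc_radius = 150,
                         side = 512L,
                         seed = 1L) {
  placement <- match.arg(placement)
  if (n_filaments < 0L) stop("`n_filaments` must be >= 0", call. = FALSE)
  if (orientation_kappa < 0)
    stop("`orientation_kappa` must be >= 0", call. = FALSE)
  if (length(length_range) != 2L || any(length_range <= 0) ||
      length_range[1L] > length_range[2L])
    stop("`length_range` must be (min, max) with 0 < min <= max",
         call. = FALSE)
  for (nu in nuclei)
    if (length(nu) != 3L || nu[3L] < 3)
      stop("each nucleus is c(row, col, radius) with radius >= 3",
           call. = FALSE)
  if (noise_sd >= filament_intensity / 2)
    stop("`noise_sd` must be < filament_intensity / 2 (contrast guard)",
         call. = FALSE)
  structure(list(n_filaments = as.integer(n_filaments),
                 orientation_mode_deg = orientation_mode_deg %% 180,
                 orientation_kappa = orientation_kappa,
                 length_range = length_range,
                 width = width,
                 filament_intensity = filament_intensity,
                 nuclei = nuclei,
                 noise_sd = noise_sd,
                 background = background,
                 placement = placement,
                 arc_radius = arc_radius,
                 side = as.integer(side),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# von Mises sampler, Best & Fisher rejection scheme
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Sample axial orientations
#'
#' Draws undirected fiber orientations in degrees on `[0, 180)` from a
#' von Mises distribution applied to doubled angles (the standard device
#' for axial data): sample on the full circle around `2 * mode`, then
#' halve. `kappa = 0` gives the uniform axial distribution.
#'
#' @param n number of samples.
#' @param mode_deg modal orientation in degrees.
#' @param kappa concentration parameter (of the doubled angles), >= 0.
#' @return Numeric vector of orientations in `[0, 180)` degrees.
#' @export
sample_axial_orientations <- function(n, mode_deg, kappa) {
  phi <- rvonmises(n, 2 * mode_deg * pi / 180, kappa)
  ((phi / 2) * 180 / pi) %% 180
}

# accumulate an anti-aliased capsule (thick segment) into a matrix
draw_capsule <- function(canvas, p0, p1, width, intensity) {
  h <- nrow(canvas); w <- ncol(canvas)
  pad <- width / 2 + 2
  r0 <- max(1L, floor(min(p0[1L], p1[1L]) - pad))
  r1 <- min(h, ceiling(max(p0[1L], p1[1L]) + pad))
  c0 <- max(1L, floor(min(p0[2L], p1[2L]) - pad))
  c1 <- min(w, ceiling(max(p0[2L], p1[2L]) + pad))
  rr <- r0:r1; cc <- c0:c1
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d <- sqrt((pr - p0[1L])^2 + (pc - p0[2L])^2)
  } else {
    t <- ((pr - p0[1L]) * v[1L] + (pc - p0[2L]) * v[2L]) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((pr - (p0[1L] + t * v[1L]))^2 + (pc - (p0[2L] + t * v[2L]))^2)
  }
  val <- pmin(pmax(width / 2 + 0.5 - d, 0), 1) * intensity
  canvas[rr, cc] <- pmax(canvas[rr, cc], val)
  canvas
}

draw_disk <- function(canvas, center, radius, intensity) {
  draw_capsule(canvas, center, center, 2 * radius, intensity)
}

#' Generate a synthetic micrograph with ground truth
#'
#' Renders the fixture described by `spec` and returns both the RGB image
#' and the ground-truth annotations (filament endpoints and angles,
#' nucleus centers). Identical specs (including the seed) produce
#' byte-identical images.
#'
#' @param spec a [fixture_spec()].
#' @return A list with `image` (RGB [raster_image]) and `truth` (list with
#'   `filament_endpoints`, `filament_angles_deg`, `nucleus_centers`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  side <- spec$side
  green <- matrix(0, side, side)
  blue <- matrix(0, side, side)
  angles <- if (spec$n_filaments > 0L)
    sample_axial_orientations(spec$n_filaments, spec$orientation_mode_deg,
                              spec$orientation_kappa)
  else numeric(0)
  lengths <- if (spec$n_filaments > 0L)
    stats::runif(spec$n_filaments, spec$length_range[1L],
                 spec$length_range[2L])
  else numeric(0)
  nuc_centers <- do.call(rbind, lapply(spec$nuclei, function(x) x[1:2]))
  endpoints <- vector("list", spec$n_filaments)
  margin <- spec$width / 2 + 2
  for (i in seq_len(spec$n_filaments)) {
    th <- angles[i] * pi / 180
    # math convention: angle up-positive, row axis points down
    dvec <- c(-sin(th), cos(th)) * lengths[i] / 2
    placed <- FALSE
    for (try in 1:200) {
      center <- if (spec$placement == "arc") {
        phi <- 2 * pi * (i - 1) / max(spec$n_filaments, 1L)
        nuc_centers[1L, 1:2] +
          spec$arc_radius * c(sin(phi), cos(phi))
      } else {
        stats::runif(2, 1 + margin, side - margin)
      }
      p0 <- center - dvec; p1 <- center + dvec
      if (all(c(p0, p1) >= 1 + margin) && all(c(p0, p1) <= side - margin)) {
        endpoints[[i]] <- list(p0 = p0, p1 = p1)
        placed <- TRUE
        break
      }
      if (spec$placement == "arc")
        stop("arc placement does not fit in the frame; reduce ",
             "arc_radius or filament length", call. = FALSE)
    }
    if (!placed)
      stop("could not place filament ", i, " after bounded retries ",
           "(overcrowded spec)", call. = FALSE)
    green <- draw_capsule(green, endpoints[[i]]$p0, endpoints[[i]]$p1,
                          spec$width, spec$filament_intensity)
  }
  for (nu in spec$nuclei)
    blue <- draw_disk(blue, nu[1:2], nu[3L], 0.9)
  arr <- array(spec$background, dim = c(side, side, 3L))
  arr[, , 2L] <- arr[, , 2L] + green
  arr[, , 3L] <- arr[, , 3L] + blue
  if (spec$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
  arr <- pmin(pmax(arr, 0), 1)
  truth <- list(
    filament_endpoints = endpoints,
    filament_angles_deg = angles,
    nucleus_centers = nuc_centers)
  list(image = raster_image(arr, bit_depth = 8L,
                            meta = list(fixture_seed = spec$seed)),
       truth = truth)
}

#' Ordered / disordered fixture pair
#'
#' Builds two fixtures sharing the filament count and nucleus layout of
#' `base`: an ordered member (near-degenerate orientation concentration,
#' filament centers on a regular arc at fixed distance from the nucleus)
#' and a disordered member (uniform orientations, uniform placement).
#' The ordered arrangement concentrates the (distance, angle) features in
#' few histogram cells and so should score a lower dispersion.
#'
#' @param base a [fixture_spec()]; its seed pairs the two members.
#' @return A list with elements `ordered` and `disordered`, each a
#'   `list(image, truth)` as from [generate_fixture()].
#' @export
ordered_vs_random_pair <- function(base) {
  stopifnot(inherits(base, "fixture_spec"))
  ordered_spec <- base
  ordered_spec$orientation_kappa <- 1e6
  ordered_spec$placement <- "arc"
  disordered_spec <- base
  disordered_spec$orientation_kappa <- 0
  disordered_spec$placement <- "uniform"
  disordered_spec$seed <- base$seed + 10000L
  list(ordered = generate_fixture(ordered_spec),
       disordered = generate_fixture(disordered_spec))
}

#' Write a standard fixture battery to disk
#'
#' Emits seeded fixture images (PNG) with ground-truth JSON sidecars:
#' single-filament geometry fixtures plus ordered/disordered pairs.
#' Used by the command-line `fixtures` subcommand to set up test inputs.
#'
#' @param dir output directory (created if missing).
#' @param n_pairs number of ordered/disordered pairs.
#' @param n_single number of single-filament fixtures.
#' @param seed base seed.
#' @return Data frame listing the files written, invisibly.
#' @export
write_fixture_battery <- function(dir, n_pairs = 3L, n_single = 3L,
                                  seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(fix, name) {
    img_path <- file.path(dir, paste0(name, ".png"))
    write_image(fix$image, img_path)
    tr <- fix$truth
    jsonlite::write_json(
      list(filament_endpoints = lapply(tr$filament_endpoints,
                                       function(e) list(p0 = e$p0, p1 = e$p1)),
           filament_angles_deg = tr$filament_angles_deg,
           nucleus_centers = tr$nucleus_centers),
      file.path(dir, paste0(name, ".truth.json")),
      auto_unbox = FALSE, digits = NA)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, path = img_path)
  }
  for (i in seq_len(n_single)) {
    sp <- fixture_spec(n_filaments = 1L, orientation_mode_deg = 30 * i,
                       orientation_kappa = 1e6,
                       length_range = c(60, 60),
                       nuclei = list(c(150, 150, 15)),
                       seed = seed + i)
    emit(generate_fixture(sp), sprintf("single_%02d", i))
  }
  for (i in seq_len(n_pairs)) {
    pair <- ordered_vs_random_pair(fixture_spec(seed = seed + 100L + i))
    emit(pair$ordered, sprintf("ordered_%02d", i))
    emit(pair$disordered, sprintf("disordered_%02d", i))
  }
  invisible(do.call(rbind, rows))
}
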