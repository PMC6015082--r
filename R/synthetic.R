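#' Von Mises angle sampling (degrees)
#'
#' Best-Fisher (1979) rejection sampler for the von Mises distribution,
#' returned in degrees in \[0, 360). `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of n angles in degrees in \[0, 360).
#' @keywords internal
#' @export
rvonmises_deg <- function(n, mu = 0, kappa = 1) {
  assert_pos(n, "n")
  assert_that(is.finite(kappa) && kappa >= 0, "parameter error: kappa must be >= 0")
  if (kappa < 1e-9) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  wrap_deg(out[seq_len(n)] * 180 / pi + mu)
}

# Probability mass of a von Mises(0, kappa) angle within +/- half_angle
# degrees of the mean, by numerical integration of the density.
#' @noRd
vonmises_sector_mass <- function(kappa, half_angle = 45) {
  h <- half_angle * pi / 180
  if (kappa < 1e-9) return(h / pi)
  # scale by exp(-kappa) to keep the integrand finite at large kappa
  num <- stats::integrate(function(t) exp(kappa * (cos(t) - 1)), -h, h,
                          rel.tol = 1e-10)$value
  den <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  num / den
}

#' Calibrate the von Mises concentration to a target front-quadrant mass
#'
#' Solves numerically for the concentration kappa such that a mixture
#' `weight * vonMises(0, kappa) + (1 - weight) * Uniform[0, 360)` places the
#' target probability mass within +/- 45 degrees of the mean direction
#' (the front 90 degree quadrant). Used to generate angle populations whose
#' analytic front-quadrant fraction matches an observed polarization level,
#' e.g. the ~50% front-quadrant polarization seen for MT1-MMP endosomes
#' under confinement.
#'
#' @param front_mass target probability in (0.25, 1) of the front quadrant
#'   (0.25 is the uniform value).
#' @param weight von Mises mixture weight in (0, 1\].
#' @param half_angle half-width of the sector in degrees (default 45).
#' @return kappa (scalar, >= 0).
#' @examples
#' k <- calibrate_kappa(0.5)   # 50% of angles within 45 deg of the mean
#' @export
calibrate_kappa <- function(front_mass, weight = 1, half_angle = 45) {
  assert_prob(weight, "weight")
  assert_that(weight > 0, "parameter error: weight must be > 0 to calibrate kappa")
  u <- half_angle / 180  # uniform sector mass
  lo <- weight * u + (1 - weight) * u
  assert_that(is.finite(front_mass) && front_mass > lo &&
                front_mass < weight + (1 - weight) * u,
              sprintf("parameter error: front_mass must lie in (%.3f, %.3f)",
                      lo, weight + (1 - weight) * u))
  target <- function(k) weight * vonmises_sector_mass(k, half_angle) +
    (1 - weight) * u - front_mass
  stats::uniroot(target, c(1e-8, 500), tol = 1e-10)$root
}

#' Sample endosome angles from the generator's angular mixture
#'
#' Draws angles from
#' `weight * vonMises(mu, kappa) + (1 - weight) * Uniform[0, 360)`.
#'
#' @param n number of angles, >= 1.
#' @param mixture numeric vector or list with elements `weight` (in \[0,1\]),
#'   `mu` (degrees) and `kappa` (>= 0), in that order if unnamed.
#' @param seed optional integer seed (caller's RNG state untouched).
#' @return n angles in degrees in \[0, 360).
#' @export
sample_angles <- function(n, mixture = c(weight = 1, mu = 0, kappa = 1), seed = NULL) {
  assert_that(is.numeric(n) && length(n) == 1L && is.finite(n) && n >= 1,
              "empty-sample error: n must be >= 1")
  mx <- as.list(mixture)
  if (is.null(names(mx)) || !all(c("weight", "mu", "kappa") %in% names(mx)))
    names(mx) <- c("weight", "mu", "kappa")
  assert_prob(mx$weight, "weight")
  assert_that(is.finite(mx$kappa) && mx$kappa >= 0, "parameter error: kappa must be >= 0")
  draw <- function() {
    vm <- runif(n) < mx$weight
    ang <- numeric(n)
    if (any(vm)) ang[vm] <- rvonmises_deg(sum(vm), mx$mu, mx$kappa)
    if (any(!vm)) ang[!vm] <- runif(sum(!vm), 0, 360)
    ang
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Parameters of a synthetic confined-migration scene
#'
#' Constructs and validates the parameter set of the synthetic microscopy
#' generator. Defaults encode the confined control regime: nuclei performing
#' a persistent random walk, endosome angles drawn from a von Mises mixture
#' calibrated so that half of the endosomes fall in the front 90 degree
#' quadrant, the centrosome ahead of the nucleus front edge in half of the
#' frames, imaging at 5 min frame intervals.
#'
#' @param n_cells number of nuclei in the scene.
#' @param n_frames number of time frames.
#' @param frame_interval min/frame.
#' @param pixel_size um/pixel.
#' @param image_shape c(rows, cols) pixels.
#' @param nucleus_radius um.
#' @param speed_mean nucleus speed, um/min; per-frame step length is
#'   `speed_mean * frame_interval`.
#' @param turn_persistence in \[0,1\]; correlation of successive step
#'   directions (1 = straight line). The heading update is
#'   `theta_{t+1} = theta_t + (1 - turn_persistence) * N(0, (pi/2)^2)`.
#' @param endosome_count_per_cell endosomes drawn per cell per frame.
#' @param angular_mixture c(weight, mu_deg, kappa); defaults to a pure
#'   von Mises at 0 degrees with kappa from `calibrate_kappa(0.5)`.
#' @param endosome_radius_range c(min, max) um from the nucleus centroid.
#' @param centrosome_ahead_prob per-frame Bernoulli probability that the
#'   centrosome sits beyond the nucleus front edge.
#' @param deformed_fraction Bernoulli probability that a nucleus carries the
#'   two-lobe deformed shape.
#' @param degradation_spot_density degradation spots per cell (static field,
#'   rendered as a third channel when > 0). Default 0 for movies; see
#'   [simulate_degradation_field()] for collagenolysis fields.
#' @param spot_sigma Gaussian peak sigma of rendered spots, pixels.
#' @param psf_sigma Gaussian PSF blur sigma applied to rendered frames, pixels.
#' @param noise c(poisson_scale, gaussian_sd); `poisson_scale = 0` disables
#'   shot noise.
#' @param seed integer seed; identical parameters + seed give identical
#'   scenes and pixel data.
#' @return validated list of class `scene_params`.
#' @export
scene_params <- function(n_cells = 1L,
                         n_frames = 30L,
                         frame_interval = 5,
                         pixel_size = 0.2,
                         image_shape = c(384L, 384L),
                         nucleus_radius = 5,
                         speed_mean = 0.3,
                         turn_persistence = 0.8,
                         endosome_count_per_cell = 20L,
                         angular_mixture = c(weight = 1, mu = 0,
                                             kappa = calibrate_kappa(0.5)),
                         endosome_radius_range = c(3, 12),
                         centrosome_ahead_prob = 0.5,
                         deformed_fraction = 0,
                         degradation_spot_density = 0,
                         spot_sigma = 2,
                         psf_sigma = 1,
                         noise = c(poisson_scale = 1, gaussian_sd = 2),
                         seed = NULL) {
  p <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
            frame_interval = frame_interval, pixel_size = pixel_size,
            image_shape = as.integer(image_shape),
            nucleus_radius = nucleus_radius, speed_mean = speed_mean,
            turn_persistence = turn_persistence,
            endosome_count_per_cell = as.integer(endosome_count_per_cell),
            angular_mixture = stats::setNames(as.numeric(angular_mixture),
                                              c("weight", "mu", "kappa")),
            endosome_radius_range = as.numeric(endosome_radius_range),
            centrosome_ahead_prob = centrosome_ahead_prob,
            deformed_fraction = deformed_fraction,
            degradation_spot_density = degradation_spot_density,
            spot_sigma = spot_sigma, psf_sigma = psf_sigma,
            noise = stats::setNames(as.numeric(noise),
                                    c("poisson_scale", "gaussian_sd")),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  assert_pos(p$n_cells, "n_cells"); assert_pos(p$n_frames, "n_frames")
  assert_pos(p$frame_interval, "frame_interval")
  assert_pos(p$pixel_size, "pixel_size")
  assert_that(length(p$image_shape) == 2L && all(p$image_shape >= 32L),
              "parameter error: image_shape must be two dimensions >= 32 pixels")
  assert_pos(p$nucleus_radius, "nucleus_radius")
  assert_pos(p$speed_mean, "speed_mean", strict = FALSE)
  assert_prob(p$turn_persistence, "turn_persistence")
  assert_pos(p$endosome_count_per_cell, "endosome_count_per_cell", strict = FALSE)
  assert_prob(p$angular_mixture[["weight"]], "angular_mixture weight")
  assert_that(is.finite(p$angular_mixture[["kappa"]]) && p$angular_mixture[["kappa"]] >= 0,
              "parameter error: angular_mixture kappa must be >= 0")
  assert_that(length(p$endosome_radius_range) == 2L &&
                all(p$endosome_radius_range > 0) && !is.unsorted(p$endosome_radius_range),
              "parameter error: endosome_radius_range must be increasing and positive")
  assert_prob(p$centrosome_ahead_prob, "centrosome_ahead_prob")
  assert_prob(p$deformed_fraction, "deformed_fraction")
  assert_pos(p$degradation_spot_density, "degradation_spot_density", strict = FALSE)
  assert_pos(p$spot_sigma, "spot_sigma"); assert_pos(p$psf_sigma, "psf_sigma")
  assert_pos(p$noise, "noise", strict = FALSE)
  margin <- p$nucleus_radius / p$pixel_size
  assert_that(all(p$image_shape * p$pixel_size > 4 * p$nucleus_radius),
              "parameter error: image_shape too small to contain a nucleus")
  class(p) <- "scene_params"
  p
}

# Reflect a coordinate into [lo, hi].
#' @noRd
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate the ground truth of a synthetic scene
#'
#' Simulates nucleus trajectories as persistent random walks (reflective
#' borders), per-frame endosome point clouds with angles drawn from the
#' angular mixture *relative to the true movement direction*, a per-frame
#' centrosome whose ahead-of-nucleus flag is Bernoulli(centrosome_ahead_prob),
#' per-cell deformation labels Bernoulli(deformed_fraction), and a static
#' degradation-spot field of the requested density. All downstream modules
#' can be validated against this truth.
#'
#' @param params a [scene_params()] object.
#' @return object of class `scene_truth`: list with `params` and data.frames
#'   `nuclei` (cell, frame, x_um, y_um, dir_deg, speed_um_min), `cells`
#'   (cell, deformed, shape parameters), `endosomes` (cell, frame,
#'   angle_true_deg, radius_um, x_um, y_um), `centrosome` (cell, frame,
#'   x_um, y_um, ahead), `degradation` (x_um, y_um).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  gen <- function() generate_scene_impl(params)
  if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())
}

#' @noRd
generate_scene_impl <- function(p) {
  fov <- rev(p$image_shape) * p$pixel_size        # (x extent, y extent) um
  margin <- p$nucleus_radius + p$endosome_radius_range[2]
  margin <- min(margin, min(fov) / 3)
  lo <- c(margin, margin); hi <- fov - margin
  step <- p$speed_mean * p$frame_interval

  nuclei <- vector("list", p$n_cells)
  cells <- data.frame(cell = seq_len(p$n_cells),
                      deformed = runif(p$n_cells) < p$deformed_fraction)
  cells$axis_ratio <- stats::runif(p$n_cells, 1, 1.3)
  cells$lobe_sep <- stats::runif(p$n_cells, 1.4, 1.8)   # used when deformed
  cells$orient <- stats::runif(p$n_cells, 0, pi)
  for (ci in seq_len(p$n_cells)) {
    pos <- matrix(NA_real_, p$n_frames, 2)
    pos[1, ] <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    heading <- runif(1, 0, 2 * pi)
    if (p$n_frames > 1L) for (t in 2:p$n_frames) {
      heading <- heading + (1 - p$turn_persistence) * rnorm(1, 0, pi / 2)
      cand <- pos[t - 1, ] + step * c(cos(heading), -sin(heading))
      newp <- c(reflect_into(cand[1], lo[1], hi[1]),
                reflect_into(cand[2], lo[2], hi[2]))
      pos[t, ] <- newp
      d <- newp - pos[t - 1, ]
      if (sqrt(sum(d^2)) > 1e-12) heading <- atan2(-d[2], d[1])
    }
    d <- rbind(diff(pos), c(NA, NA))
    disp <- sqrt(rowSums(d^2))
    nuclei[[ci]] <- data.frame(
      cell = ci, frame = seq_len(p$n_frames),
      x_um = pos[, 1], y_um = pos[, 2],
      dir_deg = ifelse(disp > 1e-12, vec_angle_deg(d[, 1], d[, 2]), NA_real_),
      speed_um_min = disp / p$frame_interval)
  }
  nuclei <- do.call(rbind, nuclei)

  moving <- nuclei[!is.na(nuclei$dir_deg), , drop = FALSE]
  n_mov <- nrow(moving)

  endo <- NULL
  if (p$endosome_count_per_cell > 0L && n_mov > 0L) {
    k <- p$endosome_count_per_cell
    ang <- sample_angles(n_mov * k, p$angular_mixture)
    rad <- runif(n_mov * k, p$endosome_radius_range[1], p$endosome_radius_range[2])
    idx <- rep(seq_len(n_mov), each = k)
    bearing <- wrap_deg(moving$dir_deg[idx] + ang)
    uv <- angle_unit_vec(bearing)
    endo <- data.frame(cell = moving$cell[idx], frame = moving$frame[idx],
                       angle_true_deg = ang, radius_um = rad,
                       x_um = moving$x_um[idx] + rad * uv[, "dx"],
                       y_um = moving$y_um[idx] + rad * uv[, "dy"])
  } else {
    endo <- data.frame(cell = integer(), frame = integer(),
                       angle_true_deg = numeric(), radius_um = numeric(),
                       x_um = numeric(), y_um = numeric())
  }

  centro <- NULL
  if (n_mov > 0L) {
    ahead <- runif(n_mov) < p$centrosome_ahead_prob
    uv <- angle_unit_vec(moving$dir_deg)
    nv <- cbind(-uv[, "dy"], uv[, "dx"])  # lateral unit vector
    r <- p$nucleus_radius
    gap <- runif(n_mov, 0.5, 2)
    lat <- rnorm(n_mov, 0, 0.5)
    # ahead: beyond the front edge along the direction; behind: inside the
    # rear half of the nucleus so the projection never exceeds the front edge
    rho <- runif(n_mov, 0, 0.8 * r)
    phi <- runif(n_mov, 90, 270) * pi / 180
    cx <- ifelse(ahead,
                 moving$x_um + (r + gap) * uv[, "dx"] + lat * nv[, 1],
                 moving$x_um + rho * (cos(phi) * uv[, "dx"] + sin(phi) * nv[, 1]))
    cy <- ifelse(ahead,
                 moving$y_um + (r + gap) * uv[, "dy"] + lat * nv[, 2],
                 moving$y_um + rho * (cos(phi) * uv[, "dy"] + sin(phi) * nv[, 2]))
    centro <- data.frame(cell = moving$cell, frame = moving$frame,
                         x_um = cx, y_um = cy, ahead = ahead)
  } else {
    centro <- data.frame(cell = integer(), frame = integer(),
                         x_um = numeric(), y_um = numeric(), ahead = logical())
  }

  n_deg <- stats::rpois(1, p$degradation_spot_density * p$n_cells)
  degr <- data.frame(x_um = runif(n_deg, margin, fov[1] - margin),
                     y_um = runif(n_deg, margin, fov[2] - margin))

  structure(list(params = p, nuclei = nuclei, cells = cells,
                 endosomes = endo, centrosome = centro, degradation = degr),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("Synthetic scene:", x$params$n_cells, "cell(s) x", x$params$n_frames,
      "frame(s);", nrow(x$endosomes), "endosome truth records\n")
  invisible(x)
}

# ---- shape rasterisation -------------------------------------------------

# Logical mask of an ellipse on a canvas of `shape` = c(rows, cols) pixels.
# Center in 0-based pixel coordinates (row, col); radii in pixels;
# orientation in radians (of the major axis, image coordinates).
#' @noRd
ellipse_mask <- function(shape, center_rc, radii, orient = 0) {
  r <- matrix(0:(shape[1] - 1L), shape[1], shape[2])
  c_ <- matrix(0:(shape[2] - 1L), shape[1], shape[2], byrow = TRUE)
  dr <- r - center_rc[1]; dc <- c_ - center_rc[2]
  u <- cos(orient) * dc + sin(orient) * dr
  v <- -sin(orient) * dc + cos(orient) * dr
  (u / radii[1])^2 + (v / radii[2])^2 <= 1
}

# Two-lobe "peanut" mask: union of two disks of radius r1 and r2 whose
# centers are sep apart along `orient`.
#' @noRd
peanut_mask <- function(shape, center_rc, r1, r2, sep, orient = 0) {
  off <- c(sin(orient), cos(orient)) * sep / 2  # (drow, dcol)
  ellipse_mask(shape, center_rc + off, c(r1, r1), 0) |
    ellipse_mask(shape, center_rc - off, c(r2, r2), 0)
}

# Mask of one nucleus at one frame given truth, in a local window.
# Returns logical matrix with attr "offset_px" = c(row0, col0) (0-based).
#' @noRd
nucleus_truth_mask <- function(truth, cell, frame, window = TRUE) {
  p <- truth$params
  nuc <- truth$nuclei[truth$nuclei$cell == cell & truth$nuclei$frame == frame, ]
  assert_that(nrow(nuc) == 1L, "no such cell/frame in scene truth")
  info <- truth$cells[truth$cells$cell == cell, ]
  r_px <- p$nucleus_radius / p$pixel_size
  cen <- c(nuc$y_um, nuc$x_um) / p$pixel_size   # (row, col), 0-based
  if (window) {
    half <- ceiling(r_px * 2.2)
    r0 <- max(0, floor(cen[1]) - half); c0 <- max(0, floor(cen[2]) - half)
    r1 <- min(p$image_shape[1] - 1, floor(cen[1]) + half)
    c1 <- min(p$image_shape[2] - 1, floor(cen[2]) + half)
    shape <- c(r1 - r0 + 1L, c1 - c0 + 1L)
    local_cen <- cen - c(r0, c0)
  } else {
    shape <- p$image_shape; r0 <- 0L; c0 <- 0L; local_cen <- cen
  }
  m <- if (isTRUE(info$deformed)) {
    rl <- r_px / sqrt(1 + (info$lobe_sep / 2)^2 * 0.4)  # keep area comparable
    peanut_mask(shape, local_cen, rl, rl * 0.92, info$lobe_sep * rl, info$orient)
  } else {
    b <- r_px / sqrt(info$axis_ratio)
    ellipse_mask(shape, local_cen, c(info$axis_ratio * b, b), info$orient)
  }
  attr(m, "offset_px") <- c(r0, c0)
  m
}

# Add a Gaussian peak of given sigma (px) and amplitude at 0-based pixel
# position (row, col) into matrix img; clipped at borders.
#' @noRd
add_peak <- function(img, row0, col0, sigma, amplitude) {
  half <- ceiling(4 * sigma)
  rr <- floor(row0) + (-half:half); cc <- floor(col0) + (-half:half)
  keep_r <- rr >= 0 & rr <= nrow(img) - 1L
  keep_c <- cc >= 0 & cc <= ncol(img) - 1L
  if (!any(keep_r) || !any(keep_c)) return(img)
  rr <- rr[keep_r]; cc <- cc[keep_c]
  g <- amplitude * outer(exp(-(rr - row0)^2 / (2 * sigma^2)),
                         exp(-(cc - col0)^2 / (2 * sigma^2)))
  img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + g
  img
}

#' Render a synthetic scene to a calibrated image stack
#'
#' Rasterises the ground truth into a multi-channel movie: nuclei as filled
#' ellipses (two-lobe shapes for deformed nuclei) in a nuclear channel,
#' endosomes as Gaussian peaks of `spot_sigma` in an endosome channel, and,
#' when the scene carries degradation spots, a static degradation channel.
#' Each frame is blurred with a Gaussian PSF and degraded with Poisson shot
#' noise and Gaussian read noise on a 100-count background (16-bit camera
#' model). Objects whose centers fall outside the image are clipped with a
#' warning.
#'
#' @param truth a `scene_truth` from [generate_scene()].
#' @return list with `stack` (an [ImageStack]) and `truth` (the sidecar
#'   ground truth, unchanged).
#' @export
render_movie <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  p <- truth$params
  rend <- function() render_movie_impl(truth)
  if (is.null(p$seed)) rend() else withr::with_seed(p$seed + 1L, rend())
}

#' @noRd
apply_camera <- function(img, p) {
  if (p$psf_sigma > 0) {
    rad <- 2 * ceiling(3 * p$psf_sigma) + 1
    rad <- min(rad, 2 * floor((min(dim(img)) - 1) / 2) + 1)
    img <- EBImage::imageData(EBImage::gblur(img, p$psf_sigma, radius = rad))
  }
  img <- img + 100
  ps <- p$noise[["poisson_scale"]]; gs <- p$noise[["gaussian_sd"]]
  if (ps > 0) img <- matrix(stats::rpois(length(img), pmax(img, 0) * ps) / ps,
                            nrow(img), ncol(img))
  if (gs > 0) img <- img + matrix(stats::rnorm(length(img), 0, gs),
                                  nrow(img), ncol(img))
  matrix(pmin(pmax(round(img), 0), 65535), nrow(img), ncol(img))
}

#' @noRd
render_movie_impl <- function(truth) {
  p <- truth$params
  sh <- p$image_shape
  has_deg <- nrow(truth$degradation) > 0L
  chans <- c("nucleus", "endosomes", if (has_deg) "degradation")
  nC <- length(chans)
  pixels <- array(0, dim = c(p$n_frames, nC, sh[1], sh[2]))
  ps <- p$pixel_size
  clipped <- 0L

  deg_base <- NULL
  if (has_deg) {
    deg_base <- matrix(0, sh[1], sh[2])
    for (i in seq_len(nrow(truth$degradation))) {
      rc <- c(truth$degradation$y_um[i], truth$degradation$x_um[i]) / ps
      if (rc[1] < 0 || rc[1] > sh[1] - 1 || rc[2] < 0 || rc[2] > sh[2] - 1)
        clipped <- clipped + 1L
      deg_base <- add_peak(deg_base, rc[1], rc[2], p$spot_sigma, 400)
    }
  }

  for (t in seq_len(p$n_frames)) {
    nuc_img <- matrix(0, sh[1], sh[2])
    for (ci in seq_len(p$n_cells)) {
      m <- nucleus_truth_mask(truth, ci, t, window = TRUE)
      off <- attr(m, "offset_px")
      idx <- which(m, arr.ind = TRUE)
      nuc_img[cbind(idx[, 1] + off[1], idx[, 2] + off[2])] <-
        nuc_img[cbind(idx[, 1] + off[1], idx[, 2] + off[2])] + 300
    }
    endo_img <- matrix(0, sh[1], sh[2])
    es <- truth$endosomes[truth$endosomes$frame == t, , drop = FALSE]
    if (nrow(es) > 0L) for (i in seq_len(nrow(es))) {
      rc <- c(es$y_um[i], es$x_um[i]) / ps
      if (rc[1] < 0 || rc[1] > sh[1] - 1 || rc[2] < 0 || rc[2] > sh[2] - 1)
        clipped <- clipped + 1L
      endo_img <- add_peak(endo_img, rc[1], rc[2], p$spot_sigma, 600)
    }
    pixels[t, 1, , ] <- apply_camera(nuc_img, p)
    pixels[t, 2, , ] <- apply_camera(endo_img, p)
    if (has_deg) pixels[t, 3, , ] <- apply_camera(deg_base, p)
  }
  if (clipped > 0L)
    warning(clipped, " object(s) extended beyond image bounds and were clipped")
  stack <- ImageStack(pixels, pixel_size = ps, frame_interval = p$frame_interval,
                      channel_names = chans)
  list(stack = stack, truth = truth)
}

#' Generate a labelled population of nucleus masks
#'
#' Rasterises `n` nucleus masks on individual canvases: normal nuclei as
#' ellipses of mild random eccentricity, deformed nuclei as two-lobe
#' (peanut) shapes, with per-nucleus random orientation. Deformation labels
#' are Bernoulli(`deformed_fraction`). Used to validate the nuclear-shape
#' classifier against known labels.
#'
#' @param n number of nuclei.
#' @param deformed_fraction Bernoulli probability of the deformed label.
#' @param nucleus_radius um.
#' @param pixel_size um/pixel.
#' @param seed optional integer seed.
#' @return list with `masks` (list of logical matrices) and `labels`
#'   (data.frame: id, deformed, and shape parameters).
#' @export
generate_nucleus_population <- function(n, deformed_fraction = 0.28,
                                        nucleus_radius = 5, pixel_size = 0.2,
                                        seed = NULL) {
  assert_pos(n, "n"); assert_prob(deformed_fraction, "deformed_fraction")
  gen <- function() {
    r_px <- nucleus_radius / pixel_size
    side <- 2L * ceiling(2.6 * r_px) + 1L
    cen <- c(side, side) / 2
    deformed <- runif(n) < deformed_fraction
    axis_ratio <- runif(n, 1, 1.4)
    lobe_sep <- runif(n, 1.4, 1.8)
    lobe_ratio <- runif(n, 0.85, 1)
    orient <- runif(n, 0, pi)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      masks[[i]] <- if (deformed[i]) {
        peanut_mask(c(side, side), cen, r_px, r_px * lobe_ratio[i],
                    lobe_sep[i] * r_px, orient[i])
      } else {
        b <- r_px / sqrt(axis_ratio[i])
        ellipse_mask(c(side, side), cen, c(axis_ratio[i] * b, b), orient[i])
      }
    }
    list(masks = masks,
         labels = data.frame(id = seq_len(n), deformed = deformed,
                             axis_ratio = axis_ratio, lobe_sep = lobe_sep,
                             lobe_ratio = lobe_ratio, orient_rad = orient))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a pericellular degradation field
#'
#' Renders a single-channel field containing `rpois(n_cells * spot_density)`
#' degradation spots as Gaussian peaks at uniform positions, through the
#' same PSF/noise camera model as the movie renderer.
#'
#' @param n_cells number of cells assumed present in the field (used for the
#'   expected spot count and later for the degradation index denominator).
#' @param spot_density expected degradation spots per cell.
#' @param field_shape c(rows, cols) pixels.
#' @param pixel_size um/pixel.
#' @param spot_sigma peak sigma, pixels.
#' @param psf_sigma PSF blur sigma, pixels.
#' @param noise c(poisson_scale, gaussian_sd).
#' @param seed optional integer seed.
#' @return list with `image` (matrix of counts), `truth` (data.frame of spot
#'   positions in um), `n_cells`, `pixel_size`.
#' @export
simulate_degradation_field <- function(n_cells = 5, spot_density = 30,
                                       field_shape = c(512L, 512L),
                                       pixel_size = 0.2, spot_sigma = 2,
                                       psf_sigma = 1,
                                       noise = c(poisson_scale = 1, gaussian_sd = 2),
                                       seed = NULL) {
  assert_pos(n_cells, "n_cells"); assert_pos(spot_density, "spot_density",
                                             strict = FALSE)
  gen <- function() {
    n <- stats::rpois(1, n_cells * spot_density)
    margin <- 4 * spot_sigma
    r0 <- runif(n, margin, field_shape[1] - 1 - margin)
    c0 <- runif(n, margin, field_shape[2] - 1 - margin)
    img <- matrix(0, field_shape[1], field_shape[2])
    for (i in seq_len(n)) img <- add_peak(img, r0[i], c0[i], spot_sigma, 400)
    p <- list(psf_sigma = psf_sigma,
              noise = stats::setNames(as.numeric(noise),
                                      c("poisson_scale", "gaussian_sd")))
    list(image = apply_camera(img, p),
         truth = data.frame(x_um = c0 * pixel_size, y_um = r0 * pixel_size),
         n_cells = n_cells, pixel_size = pixel_size)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Rasterise the per-frame nucleus masks of one cell from scene truth
#'
#' Returns the ground-truth nucleus mask of `cell` at each requested frame
#' as a cropped logical window carrying an `offset_px` attribute
#' `(row0, col0)` locating it in the full image, the format consumed by
#' [centrosome_ahead_fraction()] and [centrosome_nucleus_distance()].
#'
#' @param truth a `scene_truth` from [generate_scene()].
#' @param cell cell index.
#' @param frames frame indices (default: all frames of the scene).
#' @return named list of logical mask windows, names = frame indices.
#' @export
scene_nucleus_masks <- function(truth, cell, frames = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  frames <- frames %||% sort(unique(truth$nuclei$frame[truth$nuclei$cell == cell]))
  out <- lapply(frames, function(f) nucleus_truth_mask(truth, cell, f, window = TRUE))
  stats::setNames(out, frames)
}
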