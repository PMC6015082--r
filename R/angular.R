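#' Convert detected spots into the nucleus-velocity polar frame
#'
#' Defines, for every frame of every track, a polar coordinate system whose
#' origin is the nucleus centroid and whose 0 degree axis points along the
#' instantaneous direction of nuclear movement. Endosomes exactly in front of
#' the nucleus (in the direction of movement) are at 0 degrees; endosomes at
#' the rear of the displacement vector are at 180 degrees. The frame is
#' recomputed at every time point, separately for every nucleus.
#'
#' Spots on frames for which the movement direction is undefined (last frame
#' of a track, or displacement below the tracking gate) are excluded; the
#' number excluded is reported via [message()].
#'
#' @param spots data.frame with columns `frame`, `track_id`, `x_um`, `y_um`
#'   (typically from [assign_spots_to_nucleus()]).
#' @param tracks data.frame of track kinematics with columns `track_id`,
#'   `frame`, `x_um`, `y_um`, `dir_deg` (from [compute_kinematics()]).
#' @return data.frame with columns `track_id`, `frame`, `angle_deg` in
#'   \[0, 360) and `radius_um`.
#' @seealso [pool_and_bin()], [rao_spacing_test()]
#' @export
to_velocity_frame <- function(spots, tracks) {
  need <- c("frame", "track_id", "x_um", "y_um")
  assert_that(all(need %in% names(spots)), "spots must have frame/track_id/x_um/y_um")
  assert_that(all(c(need, "dir_deg") %in% names(tracks)),
              "tracks must carry kinematics (dir_deg); run compute_kinematics() first")
  key <- function(d) paste(d$track_id, d$frame)
  m <- match(key(spots), key(tracks))
  nuc_x <- tracks$x_um[m]; nuc_y <- tracks$y_um[m]
  dir <- tracks$dir_deg[m]
  ok <- !is.na(m) & !is.na(dir)
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    message(n_drop, " spot(s) on frames with undefined movement direction excluded")
  dx <- spots$x_um[ok] - nuc_x[ok]
  dy <- spots$y_um[ok] - nuc_y[ok]
  data.frame(track_id = spots$track_id[ok],
             frame = spots$frame[ok],
             angle_deg = wrap_deg(vec_angle_deg(dx, dy) - dir[ok]),
             radius_um = sqrt(dx^2 + dy^2))
}

#' Pool angles across cells and movies and bin into a rose histogram
#'
#' Pools endosome angles from all processed nuclei (and movies) of one
#' condition and builds the 15 degree rose histogram together with the
#' front-quadrant fraction: the proportion of angles within 45 degrees of the
#' movement direction, i.e. in \[315, 360) or \[0, 45).
#'
#' @param records data.frame with columns `angle_deg` and optionally
#'   `track_id` (used for the cell count); or a bare numeric vector of angles
#'   in degrees.
#' @param bin_width histogram bin width in degrees; must divide 360.
#'   Default 15.
#' @return An object of class `angular_distribution`: a list with `angles`,
#'   `n_cells`, `n_endosomes`, `bin_width`, `bin_fractions` (named by bin
#'   start, summing to 1) and `front_quadrant_fraction`.
#' @export
pool_and_bin <- function(records, bin_width = 15) {
  if (is.numeric(records)) records <- data.frame(angle_deg = records)
  assert_that("angle_deg" %in% names(records), "records must have an angle_deg column")
  angles <- wrap_deg(records$angle_deg)
  assert_that(length(angles) >= 1L && all(is.finite(angles)),
              "empty-sample error: need at least one finite angle")
  assert_that(360 %% bin_width == 0, "bin_width must divide 360")
  nb <- as.integer(360 / bin_width)
  bin <- pmin(floor(angles / bin_width), nb - 1L)  # half-open [k*w, (k+1)*w)
  frac <- tabulate(bin + 1L, nbins = nb) / length(angles)
  names(frac) <- seq(0, 360 - bin_width, by = bin_width)
  structure(list(
    angles = angles,
    n_cells = if ("track_id" %in% names(records))
      length(unique(records$track_id)) else NA_integer_,
    n_endosomes = length(angles),
    bin_width = bin_width,
    bin_fractions = frac,
    front_quadrant_fraction = mean(angles >= 315 | angles < 45)
  ), class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat("Angular distribution:", x$n_endosomes, "endosomes",
      if (!is.na(x$n_cells)) paste0("from ", x$n_cells, " cells") else "", "\n")
  cat(sprintf("  front-quadrant fraction (|angle| < 45 deg): %.3f\n",
              x$front_quadrant_fraction))
  invisible(x)
}

#' Rao's spacing statistic of circular uniformity
#'
#' Sorts the angles, forms the n circular spacings T_i (including the
#' wrap-around gap), and returns U = 1/2 * sum |T_i - lambda| with
#' lambda = 360/n, all in degrees. U is 0 for perfectly evenly spaced angles
#' and attains its maximum 360 * (1 - 1/n) when all angles coincide. U is
#' invariant to rotating all angles and to the input order.
#'
#' @param angles numeric vector of at least 2 finite angles in degrees
#'   (any range; wrapped internally).
#' @return list with components `U` (degrees) and `lambda` (mean spacing,
#'   360/n, degrees).
#' @references Rao, J.S. (1976) Some tests based on arc-lengths for the
#'   circle. Sankhya B 38, 329-338.
#' @export
rao_spacing_statistic <- function(angles) {
  assert_that(is.numeric(angles) && length(angles) >= 2L && all(is.finite(angles)),
              "sample-size error: Rao's spacing statistic needs >= 2 finite angles")
  n <- length(angles)
  s <- sort.int(wrap_deg(angles))
  gaps <- diff(c(s, s[1L] + 360))
  lambda <- 360 / n
  list(U = 0.5 * sum(abs(gaps - lambda)), lambda = lambda)
}

# U only, for tight Monte-Carlo loops (angles already in [0, 360)).
#' @noRd
rao_U <- function(angles) {
  s <- sort.int(angles, method = "quick")
  gaps <- diff(c(s, s[1L] + 360))
  0.5 * sum(abs(gaps - 360 / length(angles)))
}

#' Rao's spacing test of circular uniformity with a Monte-Carlo null
#'
#' Tests whether an angle sample differs from the uniform distribution on the
#' circle. The null distribution of U is simulated by drawing
#' `mc_replicates` samples of the observed size from Uniform\[0, 360); the
#' P-value uses the add-one estimator
#' p = (1 + #\{U* >= U\}) / (mc_replicates + 1), which is exact at any n and
#' never returns 0.
#'
#' @param angles numeric vector of at least 4 finite angles in degrees.
#' @param mc_replicates number of null replicates; default 9999. Values
#'   below 999 trigger a warning because the P-value resolution becomes too
#'   coarse to call P < 0.001.
#' @param seed optional integer seed making the null draw reproducible
#'   (the caller's RNG state is untouched).
#' @return An object of class `rao_test`: list with `U`, `lambda`, `n`,
#'   `p_value`, `mc_replicates`, `seed`.
#' @examples
#' ang <- sample_angles(200, mixture = c(weight = 1, mu = 0, kappa = 2), seed = 1)
#' rao_spacing_test(ang, mc_replicates = 999, seed = 1)
#' @export
rao_spacing_test <- function(angles, mc_replicates = 9999, seed = NULL) {
  assert_that(is.numeric(angles) && length(angles) >= 4L && all(is.finite(angles)),
              "sample-size error: Rao's spacing test needs >= 4 finite angles")
  mc_replicates <- as.integer(mc_replicates)
  assert_pos(mc_replicates, "mc_replicates")
  if (mc_replicates < 999L)
    warning("mc_replicates < 999: P-value resolution insufficient to call P < 0.001")
  n <- length(angles)
  obs <- rao_U(wrap_deg(angles))
  draw <- function() {
    exceed <- 0L
    for (i in seq_len(mc_replicates)) {
      if (rao_U(runif(n, 0, 360)) >= obs) exceed <- exceed + 1L
    }
    exceed
  }
  exceed <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(U = obs, lambda = 360 / n, n = n,
                 p_value = (1 + exceed) / (mc_replicates + 1),
                 mc_replicates = mc_replicates, seed = seed),
            class = "rao_test")
}

#' @export
print.rao_test <- function(x, ...) {
  cat(sprintf("Rao's spacing test: U = %.3f deg (lambda = %.3f), n = %d\n",
              x$U, x$lambda, x$n))
  cat(sprintf("  Monte-Carlo P = %.4g (%d replicates)\n", x$p_value, x$mc_replicates))
  invisible(x)
}

#' Rose (radar) plot of an angular distribution
#'
#' Draws the binned angle fractions as a circular histogram with 0 degrees
#' (direction of nuclear movement) pointing up.
#'
#' @param dist an `angular_distribution` from [pool_and_bin()].
#' @param col fill colour of the sectors.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `dist`.
#' @export
plot_rose <- function(dist, col = "indianred", ...) {
  stopifnot(inherits(dist, "angular_distribution"))
  f <- dist$bin_fractions
  r_max <- max(f)
  graphics::plot(NA, xlim = c(-r_max, r_max), ylim = c(-r_max, r_max),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", ...)
  starts <- as.numeric(names(f))
  for (i in seq_along(f)) {
    # 0 deg drawn pointing up, angles increasing counterclockwise
    th <- seq(starts[i], starts[i] + dist$bin_width, length.out = 16) * pi / 180 + pi / 2
    graphics::polygon(c(0, f[i] * cos(th)), c(0, f[i] * sin(th)),
                      col = col, border = "grey30")
  }
  graphics::symbols(0, 0, circles = r_max, inches = FALSE, add = TRUE, fg = "grey70")
  graphics::text(0, r_max * 1.05, "0°", pos = 3)
  invisible(dist)
}
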