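#' Normalized pericellular degradation index
#'
#' The raw degradation index of a field is the number of degradation spots
#' divided by the number of cells in the field. Indices are normalized so
#' that the mean raw index over the control fields equals 100.
#'
#' @param fields data.frame with columns `field_id`, `spot_count`,
#'   `cell_count` and a logical `control` column (or pass `control_ids`).
#' @param control_ids optional vector of `field_id` values forming the
#'   control set (alternative to a `control` column).
#' @return data.frame with `field_id`, `spot_count`, `cell_count`,
#'   `control`, `raw_index`, `norm_index`. The mean `norm_index` over the
#'   control fields is exactly 100.
#' @export
degradation_index <- function(fields, control_ids = NULL) {
  need <- c("field_id", "spot_count", "cell_count")
  assert_that(all(need %in% names(fields)),
              "fields must have field_id/spot_count/cell_count")
  assert_that(all(fields$cell_count >= 1),
              "cell_count must be >= 1 for a defined index")
  if (!is.null(control_ids)) fields$control <- fields$field_id %in% control_ids
  assert_that("control" %in% names(fields) && any(fields$control),
              "control set must be non-empty")
  fields$raw_index <- fields$spot_count / fields$cell_count
  ctrl_mean <- mean(fields$raw_index[fields$control])
  assert_that(ctrl_mean > 0,
              "normalization error: control fields have zero mean raw index")
  fields$norm_index <- 100 * fields$raw_index / ctrl_mean
  fields
}

#' Extract a maximal-intensity line scan along a polyline
#'
#' Samples intensity along a polyline at pixel pitch; at each sample
#' position the maximal intensity within a transverse band of width
#' `transverse_width_um` (perpendicular to the local segment) is taken,
#' emulating a maximal-intensity line-scan tool.
#'
#' @param img 2-D numeric matrix.
#' @param polyline_um matrix or data.frame with >= 2 rows of `(x_um, y_um)`
#'   vertices; must lie inside the image.
#' @param pixel_size um/pixel.
#' @param transverse_width_um full width of the transverse maximum band in
#'   um (0 = plain interpolated profile).
#' @return data.frame with `pos_um` (arclength from the first vertex) and
#'   `intensity`.
#' @export
extract_linescan <- function(img, polyline_um, pixel_size,
                             transverse_width_um = 0) {
  assert_that(is.matrix(img) && is.numeric(img), "img must be a numeric matrix")
  assert_pos(pixel_size, "pixel_size")
  pl <- as.matrix(polyline_um)[, 1:2, drop = FALSE]
  assert_that(nrow(pl) >= 2L, "polyline needs at least 2 vertices")
  xmax <- (ncol(img) - 1) * pixel_size; ymax <- (nrow(img) - 1) * pixel_size
  assert_that(all(pl[, 1] >= 0 & pl[, 1] <= xmax &
                    pl[, 2] >= 0 & pl[, 2] <= ymax),
              "geometry error: polyline outside image")
  seg <- diff(pl)
  seg_len <- sqrt(rowSums(seg^2))
  assert_that(all(seg_len > 0), "geometry error: degenerate polyline segment")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  pos <- seq(0, total, by = pixel_size)
  if (pos[length(pos)] < total) pos <- c(pos, total)
  # point and local tangent at each arclength position
  si <- findInterval(pos, cum, rightmost.closed = TRUE)
  si <- pmin(si, nrow(seg))
  frac <- (pos - cum[si]) / seg_len[si]
  px <- pl[si, 1] + frac * seg[si, 1]
  py <- pl[si, 2] + frac * seg[si, 2]
  tx <- seg[si, 1] / seg_len[si]; ty <- seg[si, 2] / seg_len[si]
  nx <- -ty; ny <- tx
  offs <- 0
  if (transverse_width_um > 0)
    offs <- seq(-transverse_width_um / 2, transverse_width_um / 2,
                by = pixel_size / 2)
  vals <- rep(-Inf, length(pos))
  for (o in offs) {
    sx <- px + o * nx; sy <- py + o * ny
    v <- bilinear(img, sy / pixel_size, sx / pixel_size)
    vals <- pmax(vals, v, na.rm = TRUE)
  }
  vals[!is.finite(vals)] <- NA_real_
  data.frame(pos_um = pos, intensity = vals)
}

#' Normalize a line-scan profile onto the back/center/front frame
#'
#' Maps the three reference points - cell back, nucleus center, cell front
#' (manually defined from the DAPI profile, or auto-derived) - onto the
#' coordinates -1, 0 and 1 with a two-segment piecewise-linear coordinate
#' transform (`[back, center] -> [-1, 0]`, `[center, front] -> [0, 1]`),
#' then linearly interpolates the intensity onto a fixed grid, allowing
#' direct comparison and averaging of profiles with different lengths.
#'
#' @param profile data.frame from [extract_linescan()] (`pos_um`,
#'   `intensity`).
#' @param references numeric length-3: positions (um, along the profile) of
#'   cell back, nucleus center and cell front; must be strictly increasing
#'   and within the profile range.
#' @param grid_points number of grid points over \[-1, 1\] (default 201).
#' @return data.frame with `coord` (the fixed grid) and `intensity`.
#' @export
normalize_linescan <- function(profile, references, grid_points = 201L) {
  assert_that(all(c("pos_um", "intensity") %in% names(profile)),
              "profile must have pos_um and intensity")
  assert_that(length(references) == 3L && all(is.finite(references)),
              "references must be (back, center, front)")
  back <- references[1]; center <- references[2]; front <- references[3]
  assert_that(back < center && center < front,
              "validation error: references must satisfy back < center < front")
  rng <- range(profile$pos_um)
  assert_that(back >= rng[1] && front <= rng[2],
              "validation error: references outside the profile range")
  s <- ifelse(profile$pos_um <= center,
              (profile$pos_um - center) / (center - back),
              (profile$pos_um - center) / (front - center))
  grid <- seq(-1, 1, length.out = grid_points)
  data.frame(coord = grid,
             intensity = stats::approx(s, profile$intensity, xout = grid,
                                       rule = 1, ties = "ordered")$y)
}

#' Auto-derive line-scan reference points from a DAPI profile
#'
#' Extension of the manual workflow: the nucleus center is the
#' intensity-weighted centroid of the background-subtracted DAPI profile and
#' back/front are the outermost positions where the DAPI signal rises above
#' `frac` of its maximum, expanded by `pad_um` on each side to reach the
#' cell limits.
#'
#' @param dapi_profile data.frame (`pos_um`, `intensity`).
#' @param frac threshold fraction of the maximum (default 0.1).
#' @param pad_um padding added beyond the nuclear extent on each side, um.
#' @return numeric length-3 `(back, center, front)`.
#' @export
derive_references <- function(dapi_profile, frac = 0.1, pad_um = 0) {
  v <- dapi_profile$intensity - min(dapi_profile$intensity, na.rm = TRUE)
  ok <- which(v >= frac * max(v, na.rm = TRUE))
  assert_that(length(ok) >= 2L, "DAPI profile has no clear nuclear signal")
  center <- sum(dapi_profile$pos_um[ok] * v[ok]) / sum(v[ok])
  back <- max(min(dapi_profile$pos_um[ok]) - pad_um, min(dapi_profile$pos_um))
  front <- min(max(dapi_profile$pos_um[ok]) + pad_um, max(dapi_profile$pos_um))
  c(back = back, center = center, front = front)
}

#' Average normalized line-scan profiles
#'
#' Pointwise mean and standard deviation of profiles on the common
#' normalized grid. With a single profile the SD is reported as 0 and
#' flagged by `n = 1`.
#'
#' @param profiles list of data.frames from [normalize_linescan()], all on
#'   the same grid.
#' @return data.frame with `coord`, `mean`, `sd`, `n` per grid point
#'   (NA intensities excluded pointwise).
#' @export
average_profiles <- function(profiles) {
  assert_that(is.list(profiles) && length(profiles) >= 1L,
              "empty-sample error: need at least one profile")
  g <- profiles[[1]]$coord
  for (p in profiles)
    assert_that(isTRUE(all.equal(p$coord, g)), "profiles must share one grid")
  m <- vapply(profiles, function(p) p$intensity, numeric(length(g)))
  m <- matrix(m, nrow = length(g))
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, function(r) stats::sd(r, na.rm = TRUE))
  sdv[n <= 1L] <- 0
  data.frame(coord = g, mean = mu, sd = sdv, n = n)
}
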