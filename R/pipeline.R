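#' Full endosome-polarity pipeline on a rendered movie
#'
#' Runs the complete analysis chain on a calibrated movie: nucleus
#' segmentation per frame, nearest-neighbour tracking, kinematics,
#' LoG/watershed endosome detection per frame, spot-to-nucleus assignment,
#' conversion to the nucleus-velocity polar frame and pooling into a rose
#' histogram.
#'
#' @param stack an [ImageStack] with channels named `nucleus` and
#'   `endosomes` (or the first two channels).
#' @param nucleus_radius expected nucleus radius, um.
#' @param spot_sigma endosome spot sigma, pixels.
#' @param max_jump tracking gate, um; default `3 * nucleus_radius`.
#' @param max_radius spot assignment radius, um; default
#'   `3 * nucleus_radius`.
#' @param min_displacement direction gate, um (see [compute_kinematics()]).
#' @param k LoG threshold multiplier.
#' @return list with `tracks`, `spots`, `records` (velocity-frame endosome
#'   records) and `distribution` (an `angular_distribution`).
#' @export
quantify_endosome_polarity <- function(stack, nucleus_radius = 5,
                                       spot_sigma = 2, max_jump = NULL,
                                       max_radius = NULL,
                                       min_displacement = 0.1, k = 5) {
  stopifnot(inherits(stack, "ImageStack"))
  max_jump <- max_jump %||% (3 * nucleus_radius)
  max_radius <- max_radius %||% (3 * nucleus_radius)
  nT <- dim(stack$pixels)[1]
  nuc_ch <- if ("nucleus" %in% stack$channel_names) "nucleus" else 1L
  endo_ch <- if ("endosomes" %in% stack$channel_names) "endosomes" else 2L
  detections <- NULL
  spots <- NULL
  for (t in seq_len(nT)) {
    labels <- segment_nuclei(get_frame(stack, t, nuc_ch), stack$pixel_size,
                             nucleus_radius = nucleus_radius)
    cen <- nucleus_centroids(labels, stack$pixel_size)
    if (nrow(cen) > 0L)
      detections <- rbind(detections, cbind(frame = t, cen))
    sp <- detect_endosomes(get_frame(stack, t, endo_ch), stack$pixel_size,
                           spot_sigma = spot_sigma, k = k)
    if (nrow(sp) > 0L)
      spots <- rbind(spots, cbind(frame = t, sp))
  }
  assert_that(!is.null(detections), "no nuclei detected in any frame")
  tracks <- track_nuclei(detections, max_jump = max_jump)
  tracks <- compute_kinematics(tracks, stack$frame_interval,
                               min_displacement = min_displacement)
  assert_that(!is.null(spots), "no endosomes detected in any frame")
  spots <- assign_spots_to_nucleus(spots, tracks, max_radius = max_radius)
  records <- to_velocity_frame(spots, tracks)
  list(tracks = tracks, spots = spots, records = records,
       distribution = pool_and_bin(records))
}

#' Simulate, render and analyse one condition end to end
#'
#' Convenience wrapper pooling velocity-frame endosome records over
#' `n_movies` independently seeded synthetic movies of one condition, as
#' movies of one condition are pooled in the polarity analysis.
#'
#' @param params a [scene_params()] (its `seed` is combined with the movie
#'   index).
#' @param n_movies number of movies.
#' @param seed base seed for the movie series.
#' @return list with `records` (pooled) and `distribution`.
#' @export
run_polarity_condition <- function(params, n_movies = 10, seed = 1) {
  records <- NULL
  for (i in seq_len(n_movies)) {
    p <- params
    p$seed <- as.integer(seed + 1000L * i)
    truth <- generate_scene(p)
    movie <- render_movie(truth)
    res <- quantify_endosome_polarity(movie$stack,
                                      nucleus_radius = p$nucleus_radius,
                                      spot_sigma = p$spot_sigma)
    rec <- res$records
    rec$track_id <- paste0("m", i, "_", rec$track_id)
    records <- rbind(records, rec)
  }
  list(records = records, distribution = pool_and_bin(records))
}
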