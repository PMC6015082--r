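#' Segment nuclei from a 2-D nuclear-channel image
#'
#' Segments nuclei from a maximal z-projection of the nuclear channel by
#' Gaussian smoothing, global Otsu thresholding, hole filling and a
#' minimum-area filter. Labels are relabelled in order of decreasing area.
#' The default smoothing sigma is a quarter of the expected nucleus radius
#' (in pixels) and the minimum accepted area a quarter of the expected
#' nucleus area.
#'
#' @param frame 2-D numeric matrix (Y, X).
#' @param pixel_size um/pixel.
#' @param nucleus_radius expected nucleus radius in um (default 5).
#' @param sigma smoothing sigma in pixels; default `nucleus_radius / 4`
#'   converted to pixels.
#' @param min_area_frac minimum region area as a fraction of the expected
#'   nucleus area `pi * r^2` (default 0.25).
#' @return integer label matrix (0 = background); an all-background image
#'   yields a zero matrix, not an error.
#' @export
segment_nuclei <- function(frame, pixel_size, nucleus_radius = 5,
                           sigma = NULL, min_area_frac = 0.25) {
  assert_that(is.matrix(frame) && is.numeric(frame), "frame must be a numeric matrix")
  assert_pos(pixel_size, "pixel_size")
  sigma <- sigma %||% (nucleus_radius / 4 / pixel_size)
  rng <- range(frame)
  if (diff(rng) == 0) return(matrix(0L, nrow(frame), ncol(frame)))
  rad <- 2 * ceiling(3 * sigma) + 1
  rad <- min(rad, 2 * floor((min(dim(frame)) - 1) / 2) + 1)
  sm <- EBImage::imageData(EBImage::gblur(frame, sigma, radius = rad))
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(smn))
  mask <- smn > thr
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)
  min_area <- min_area_frac * pi * (nucleus_radius / pixel_size)^2
  tab <- tabulate(as.integer(labels))
  keep <- which(tab >= min_area)
  if (length(keep) == 0L) return(matrix(0L, nrow(frame), ncol(frame)))
  keep <- keep[order(tab[keep], decreasing = TRUE)]
  out <- matrix(0L, nrow(frame), ncol(frame))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Centroids of labelled nuclei
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param pixel_size um/pixel.
#' @return data.frame with `label`, `x_um`, `y_um`, `area_px` (0-based pixel
#'   center convention).
#' @export
nucleus_centroids <- function(labels, pixel_size) {
  label_centroids(labels, pixel_size)
}

#' Link nucleus detections over time into tracks
#'
#' Greedy nearest-neighbour linking: candidate links between frame t tracks
#' and frame t+1 detections are accepted in order of increasing distance
#' (ties broken by smaller track id, then smaller detection label), subject
#' to the `max_jump` gate. Unmatched detections start new tracks; unmatched
#' tracks end. Deterministic for fixed input.
#'
#' @param detections data.frame with columns `frame`, `label`, `x_um`,
#'   `y_um` (one row per detected nucleus per frame).
#' @param max_jump maximum linking distance in um.
#' @return data.frame with columns `track_id`, `frame`, `label`, `x_um`,
#'   `y_um`, ordered by track then frame.
#' @export
track_nuclei <- function(detections, max_jump) {
  assert_pos(max_jump, "max_jump")
  if (nrow(detections) == 0L)
    return(data.frame(track_id = integer(), frame = integer(),
                      label = integer(), x_um = numeric(), y_um = numeric()))
  frames <- sort(unique(detections$frame))
  next_id <- 1L
  out <- NULL
  active <- NULL  # data.frame: track_id, x_um, y_um (position at prev frame)
  prev_frame <- NULL
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    det <- det[order(det$label), , drop = FALSE]
    assigned_track <- rep(NA_integer_, nrow(det))
    if (!is.null(active) && nrow(active) > 0L && identical(prev_frame + 1L, as.integer(f))) {
      dm <- outer(seq_len(nrow(active)), seq_len(nrow(det)),
                  function(i, j) sqrt((active$x_um[i] - det$x_um[j])^2 +
                                        (active$y_um[i] - det$y_um[j])^2))
      cand <- which(dm <= max_jump, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(dm[cand], active$track_id[cand[, 1]], det$label[cand[, 2]])
        used_t <- logical(nrow(active)); used_d <- logical(nrow(det))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_t[i] && !used_d[j]) {
            used_t[i] <- TRUE; used_d[j] <- TRUE
            assigned_track[j] <- active$track_id[i]
          }
        }
      }
    }
    new <- is.na(assigned_track)
    if (any(new)) {
      assigned_track[new] <- next_id + seq_len(sum(new)) - 1L
      next_id <- next_id + sum(new)
    }
    out <- rbind(out, data.frame(track_id = assigned_track,
                                 frame = as.integer(f), label = det$label,
                                 x_um = det$x_um, y_um = det$y_um))
    active <- data.frame(track_id = assigned_track, x_um = det$x_um, y_um = det$y_um)
    prev_frame <- as.integer(f)
  }
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Compute per-frame kinematics of nucleus tracks
#'
#' For each track, the velocity at frame t is the forward difference
#' `(position[t+1] - position[t]) / frame_interval`; its magnitude is the
#' speed and its angle (package convention, degrees) the movement
#' direction. Frames whose displacement is below `min_displacement` - and
#' the last frame of each track - have an undefined direction (`NA`).
#' Track persistence is net displacement over path length, in \[0, 1\]
#' (`NA` for a zero-length path).
#'
#' @param tracks data.frame from [track_nuclei()] (columns `track_id`,
#'   `frame`, `x_um`, `y_um`).
#' @param frame_interval min/frame.
#' @param min_displacement minimum per-step displacement (um) for the
#'   direction to be defined; default 0.1 um (half a pixel at 0.2 um/px).
#' @return input data.frame with added columns `speed_um_min`, `dir_deg`,
#'   `persistence`. A single-frame track is a kinematics-undefined error.
#' @export
compute_kinematics <- function(tracks, frame_interval, min_displacement = 0.1) {
  assert_pos(frame_interval, "frame_interval")
  assert_pos(min_displacement, "min_displacement", strict = FALSE)
  assert_that(nrow(tracks) > 0L, "no tracks supplied")
  out <- NULL
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    assert_that(nrow(tr) >= 2L,
                sprintf("kinematics-undefined error: track %s has fewer than 2 frames", id))
    assert_that(all(diff(tr$frame) > 0), "frames must be strictly increasing")
    dx <- c(diff(tr$x_um), NA); dy <- c(diff(tr$y_um), NA)
    dt <- c(diff(tr$frame), NA) * frame_interval
    disp <- sqrt(dx^2 + dy^2)
    tr$speed_um_min <- disp / dt
    tr$dir_deg <- ifelse(!is.na(disp) & disp >= min_displacement,
                         vec_angle_deg(dx, dy), NA_real_)
    path <- sum(disp, na.rm = TRUE)
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                  (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    tr$persistence <- if (path > 0) min(net / path, 1) else NA_real_
    out <- rbind(out, tr)
  }
  out
}
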