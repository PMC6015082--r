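# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
wrap_deg <- function(x) x %% 360

# Angle (degrees in [0, 360)) of a displacement vector (dx, dy) given in
# image coordinates (y grows downwards). The math convention is applied to
# (dx, -dy) so that visually counterclockwise angles are positive.
#' @noRd
vec_angle_deg <- function(dx, dy) wrap_deg(atan2(-dy, dx) * 180 / pi)

# Unit vector (dx, dy) in image coordinates for an angle in degrees under
# the same convention.
#' @noRd
angle_unit_vec <- function(deg) {
  rad <- deg * pi / 180
  cbind(dx = cos(rad), dy = -sin(rad))
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' @noRd
assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
                x >= 0 && x <= 1,
              sprintf("parameter error: '%s' must be a probability in [0, 1]", name))
}

#' @noRd
assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    (if (strict) all(x > 0) else all(x >= 0))
  assert_that(ok, sprintf("parameter error: '%s' must be %s", name,
                          if (strict) "positive and finite" else "non-negative and finite"))
}

# 3x3 neighbourhood maximum of a matrix (replicated borders), used for
# regional-maximum detection.
#' @noRd
maxfilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  out
}

# Bilinear interpolation of matrix `img` at fractional 0-based pixel
# positions (row, col). Positions outside the image return NA.
#' @noRd
bilinear <- function(img, row0, col0) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- floor(row0); c1 <- floor(col0)
  fr <- row0 - r1; fc <- col0 - c1
  get_px <- function(r, c) {
    r <- pmin(pmax(r, 0), nr - 1L); c <- pmin(pmax(c, 0), nc - 1L)
    img[cbind(r + 1L, c + 1L)]
  }
  inside <- row0 >= 0 & row0 <= nr - 1L & col0 >= 0 & col0 <= nc - 1L
  v <- (1 - fr) * (1 - fc) * get_px(r1, c1) +
    (1 - fr) * fc * get_px(r1, c1 + 1L) +
    fr * (1 - fc) * get_px(r1 + 1L, c1) +
    fr * fc * get_px(r1 + 1L, c1 + 1L)
  v[!inside] <- NA_real_
  v
}

# Centroids (micrometres, 0-based pixel convention) of a labelled mask.
#' @noRd
label_centroids <- function(labels, pixel_size) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(), x_um = numeric(), y_um = numeric(),
                      area_px = integer()))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- as.integer(labels[idx])
  rows <- rowsum(cbind(idx[, 1] - 1, idx[, 2] - 1, 1), lab)
  keep <- match(ids, as.integer(rownames(rows)))
  data.frame(label = ids,
             x_um = rows[keep, 2] / rows[keep, 3] * pixel_size,
             y_um = rows[keep, 1] / rows[keep, 3] * pixel_size,
             area_px = as.integer(rows[keep, 3]))
}
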