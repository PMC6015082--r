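# Oriented boundary contour of a single-object logical mask, as an
# n x 2 matrix of 0-based (row, col) coordinates (8-connected chain).
#' @noRd
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  oc[[1]]  # 0-based (row, col)
}

# Perimeter of an 8-connected closed chain with the Vossepoel-Smeulders
# correction (0.980 per axial step, 1.406 per diagonal step, -0.091 per
# chain-code corner), in pixels; markedly less orientation-dependent than
# raw or Kulpa-weighted chain length.
#' @noRd
chain_perimeter <- function(contour) {
  d <- diff(rbind(contour, contour[1, , drop = FALSE]))
  steps <- rowSums(abs(d))
  code <- atan2(d[, 1], d[, 2])
  corners <- sum(code != c(code[-1], code[1]))
  0.980 * sum(steps == 1) + 1.406 * sum(steps == 2) - 0.091 * corners
}

# Convex hull of 0-based pixel-center points; returns the hull vertices
# (counterclockwise, n x 2 (row, col)).
#' @noRd
hull_vertices <- function(pts) {
  h <- grDevices::chull(pts[, 2], pts[, 1])  # chull takes (x, y)
  pts[rev(h), , drop = FALSE]                # make counterclockwise in (row, col)
}

# Number of mask pixels whose centers lie inside (or on) the convex hull of
# the boundary, by half-plane tests over the bounding box.
#' @noRd
hull_pixel_area <- function(hull, bbox) {
  rr <- bbox[1]:bbox[2]; cc <- bbox[3]:bbox[4]
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  cen <- colMeans(hull)
  inside <- matrix(TRUE, length(rr), length(cc))
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (C - a[2]) - (b[2] - a[2]) * (R - a[1])
    cr_cen <- (b[1] - a[1]) * (cen[2] - a[2]) - (b[2] - a[2]) * (cen[1] - a[1])
    s <- sign(cr_cen)
    if (s == 0) next
    inside <- inside & (s * cr >= -1e-9)
  }
  sum(inside)
}

# Depth (pixels) of each contour point below the convex hull boundary:
# min distance to the hull polygon edges.
#' @noRd
hull_defect_depth <- function(contour, hull) {
  n <- nrow(hull)
  depth <- rep(Inf, nrow(contour))
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((contour[, 1] - a[1]) * ab[1] + (contour[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- contour[, 1] - (a[1] + t * ab[1])
    dy <- contour[, 2] - (a[2] + t * ab[2])
    depth <- pmin(depth, sqrt(dx^2 + dy^2))
  }
  depth
}

#' Shape descriptors and deformation class of a nucleus mask
#'
#' Computes area, perimeter (Kulpa-corrected boundary chain length),
#' circularity `4 * pi * area / perimeter^2`, solidity (pixel area over
#' convex-hull pixel area) and the number of dominant boundary concavities
#' (`lobe_count`): maximal runs of contour points whose depth below the
#' convex hull exceeds `defect_depth_frac` of the equivalent radius. A
#' nucleus is classified `deformed` when `solidity < solidity_threshold` or
#' `lobe_count >= 2` (a two-lobe constricted nucleus produces one concavity
#' on each flank of the waist). This descriptor rule is a transparent,
#' configurable stand-in for visual normal/deformed scoring.
#'
#' @param mask logical (or 0/1) matrix containing exactly one connected
#'   component.
#' @param pixel_size um/pixel.
#' @param solidity_threshold deformed when solidity falls below this
#'   (default 0.92).
#' @param defect_depth_frac concavity depth threshold as a fraction of the
#'   equivalent-disk radius (default 0.10).
#' @return list with `area_um2`, `perimeter_um`, `circularity`, `solidity`,
#'   `lobe_count`, `deformation_class` ("normal" or "deformed").
#' @export
score_nucleus_shape <- function(mask, pixel_size = 0.2,
                                solidity_threshold = 0.92,
                                defect_depth_frac = 0.10) {
  assert_that(is.matrix(mask), "mask must be a matrix")
  mask <- mask > 0
  assert_that(any(mask), "validation error: empty mask")
  labs <- EBImage::bwlabel(mask)
  assert_that(max(labs) == 1L,
              "validation error: mask must contain exactly one connected component")
  area_px <- sum(mask)
  contour <- mask_contour(mask)
  per_px <- chain_perimeter(contour)
  hull <- hull_vertices(contour)
  bbox <- c(range(contour[, 1]), range(contour[, 2]))
  hull_px <- hull_pixel_area(hull, bbox)
  solidity <- min(area_px / hull_px, 1)
  r_eq <- sqrt(area_px / pi)
  depth <- hull_defect_depth(contour, hull)
  deep <- depth > defect_depth_frac * r_eq
  # count circular runs of deep contour points
  if (all(deep)) {
    lobes <- 1L
  } else if (!any(deep)) {
    lobes <- 0L
  } else {
    rl <- rle(deep)
    lobes <- sum(rl$values)
    if (deep[1] && deep[length(deep)]) lobes <- lobes - 1L  # wrap-around run
  }
  deformed <- solidity < solidity_threshold || lobes >= 2L
  list(area_um2 = area_px * pixel_size^2,
       perimeter_um = per_px * pixel_size,
       circularity = 4 * pi * area_px / per_px^2,
       solidity = solidity,
       lobe_count = as.integer(lobes),
       deformation_class = if (deformed) "deformed" else "normal")
}

#' Distance from the centrosome to the nucleus rim
#'
#' Euclidean distance (um) from a point to the nearest boundary pixel of
#' the nucleus mask; 0 when the point lies inside the mask.
#'
#' @param point_um numeric length-2 `(x_um, y_um)`.
#' @param mask logical nucleus mask.
#' @param pixel_size um/pixel.
#' @return distance in um.
#' @export
centrosome_nucleus_distance <- function(point_um, mask, pixel_size) {
  assert_that(is.matrix(mask) && any(mask > 0), "validation error: empty mask")
  assert_pos(pixel_size, "pixel_size")
  mask <- mask > 0
  pr <- point_um[2] / pixel_size; pc <- point_um[1] / pixel_size  # 0-based
  ri <- round(pr) + 1L; ci <- round(pc) + 1L
  if (ri >= 1L && ri <= nrow(mask) && ci >= 1L && ci <= ncol(mask) &&
      mask[ri, ci]) return(0)
  contour <- mask_contour(mask)
  min(sqrt((contour[, 1] - pr)^2 + (contour[, 2] - pc)^2)) * pixel_size
}

#' Fraction of frames with the centrosome ahead of the nucleus front edge
#'
#' For every frame with a defined movement direction, the centrosome is
#' scored "ahead" when its scalar projection onto the movement direction
#' exceeds the maximal projection of all nucleus mask pixels (the front
#' edge of the nucleus). Returns the percentage of scored frames with the
#' centrosome ahead.
#'
#' @param track data.frame with `frame` and `dir_deg` (from
#'   [compute_kinematics()]) for one nucleus.
#' @param centrosome data.frame with `frame`, `x_um`, `y_um`.
#' @param masks named list of nucleus masks, names = frame indices; each a
#'   logical matrix, optionally with an `offset_px` attribute `(row0, col0)`
#'   locating a cropped window in the full frame.
#' @param pixel_size um/pixel.
#' @return list with `percent_ahead`, `n_scored`, and per-frame `ahead`
#'   logical vector (named by frame).
#' @export
centrosome_ahead_fraction <- function(track, centrosome, masks, pixel_size) {
  assert_pos(pixel_size, "pixel_size")
  scored <- track$frame[!is.na(track$dir_deg)]
  scored <- intersect(scored, centrosome$frame)
  scored <- scored[as.character(scored) %in% names(masks)]
  assert_that(length(scored) > 0, "empty-sample error: no scorable frames")
  ahead <- stats::setNames(logical(length(scored)), scored)
  for (i in seq_along(scored)) {
    f <- scored[i]
    u <- angle_unit_vec(track$dir_deg[track$frame == f][1])
    cen <- centrosome[centrosome$frame == f, ][1, ]
    proj_c <- cen$x_um * u[1, "dx"] + cen$y_um * u[1, "dy"]
    m <- masks[[as.character(f)]]
    off <- attr(m, "offset_px") %||% c(0, 0)
    idx <- which(m > 0, arr.ind = TRUE)
    x <- (idx[, 2] - 1 + off[2]) * pixel_size
    y <- (idx[, 1] - 1 + off[1]) * pixel_size
    ahead[i] <- proj_c > max(x * u[1, "dx"] + y * u[1, "dy"])
  }
  list(percent_ahead = 100 * mean(ahead), n_scored = length(scored),
       ahead = ahead)
}

# IsoData (iterative intermeans) threshold.
#' @noRd
isodata_threshold <- function(v) {
  t0 <- mean(range(v))
  for (i in 1:100) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (length(lo) == 0L || length(hi) == 0L) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-8) return(t1)
    t0 <- t1
  }
  t0
}

#' Invadopodia (Tks5) area as a percentage of cell area
#'
#' Thresholds the Tks5 channel (projection of the z-planes in contact with
#' the matrix) within the cell mask, discards connected regions smaller
#' than `min_region` pixels to avoid non-invadopodial structures, and
#' reports the remaining Tks5-positive area as a percentage of the cell
#' area.
#'
#' @param img 2-D numeric matrix (projected Tks5 channel).
#' @param cell_mask logical matrix, same shape as `img`, covering the cell.
#' @param threshold_mode "isodata" (iterative intermeans; default) or
#'   "otsu".
#' @param min_region minimum region size in pixels (default 8; regions
#'   < 8 px are excluded).
#' @return percentage of cell area covered by Tks5 signal.
#' @export
tks5_area_ratio <- function(img, cell_mask, threshold_mode = c("isodata", "otsu"),
                            min_region = 8L) {
  threshold_mode <- match.arg(threshold_mode)
  assert_that(is.matrix(img) && identical(dim(img), dim(cell_mask)),
              "img and cell_mask must have identical dimensions")
  cell_mask <- cell_mask > 0
  assert_that(any(cell_mask), "validation error: empty cell mask")
  v <- img[cell_mask]
  if (diff(range(v)) == 0) return(0)
  thr <- if (threshold_mode == "isodata") {
    isodata_threshold(v)
  } else {
    rngv <- range(v)
    rngv[1] + EBImage::otsu(EBImage::Image((img - rngv[1]) / diff(rngv))) * diff(rngv)
  }
  pos <- img > thr & cell_mask
  if (!any(pos)) return(0)
  labels <- EBImage::bwlabel(pos)
  tab <- tabulate(as.integer(labels))
  100 * sum(tab[tab >= min_region]) / sum(cell_mask)
}

#' Transwell invasion index from a DAPI z-series
#'
#' Fraction of total DAPI signal found at depths at or beyond the invasion
#' threshold. Depth 0 is the first slice with nonzero signal (the gel
#' surface); slices are `z_step` um apart.
#'
#' @param slice_intensity numeric vector of per-slice summed DAPI
#'   intensities, ordered from the gel surface downwards (>= 2 slices).
#' @param z_step um between slices (> 0; e.g. 10 um).
#' @param depth_threshold invasion depth in um (default 30).
#' @param origin depth origin: `"first_slice"` (default; the acquisition
#'   starts at the gel surface) or `"first_signal"` (the shallowest slice
#'   with nonzero signal defines 0 um, useful when the stack starts above
#'   the gel).
#' @return invasion fraction in \[0, 1\].
#' @export
invasion_index <- function(slice_intensity, z_step, depth_threshold = 30,
                           origin = c("first_slice", "first_signal")) {
  origin <- match.arg(origin)
  assert_that(length(slice_intensity) >= 2L, "need at least 2 slices")
  assert_pos(z_step, "z_step")
  assert_that(all(slice_intensity >= 0), "intensities must be non-negative")
  total <- sum(slice_intensity)
  assert_that(total > 0, "undefined-index error: zero total intensity")
  first <- if (origin == "first_signal") which(slice_intensity > 0)[1] else 1L
  depth <- (seq_along(slice_intensity) - first) * z_step
  sum(slice_intensity[depth >= depth_threshold]) / total
}

#' Centrosome displacement before and after laser ablation
#'
#' Net centrosome displacement over each observation window, projected onto
#' the direction of cell movement: positive displacements point in the
#' movement direction, negative otherwise. Pre- and post-ablation windows
#' of the same cell are returned as a pair for paired statistics.
#'
#' @param pre_um,post_um matrices (>= 2 rows) of `(x_um, y_um)` centrosome
#'   positions over the pre- and post-ablation windows.
#' @param movement_dir_deg direction of cell movement, degrees (package
#'   convention).
#' @return named numeric `c(pre = ..., post = ...)`, um.
#' @export
ablation_displacement <- function(pre_um, post_um, movement_dir_deg) {
  win <- function(m, nm) {
    m <- as.matrix(m)
    assert_that(nrow(m) >= 2L,
                sprintf("validation error: %s window needs >= 2 timepoints", nm))
    m
  }
  pre_um <- win(pre_um, "pre"); post_um <- win(post_um, "post")
  u <- angle_unit_vec(movement_dir_deg)
  proj <- function(m) unname((m[nrow(m), 1] - m[1, 1]) * u[1, "dx"] +
                               (m[nrow(m), 2] - m[1, 2]) * u[1, "dy"])
  c(pre = proj(pre_um), post = proj(post_um))
}
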