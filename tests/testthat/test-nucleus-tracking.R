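test_that("a single bright disk segments to one label at its center", {
  img <- matrix(0, 128, 128)
  img[oracle_disk(128, c(60, 70), 20)] <- 500
  labels <- segment_nuclei(img, pixel_size = 0.2, nucleus_radius = 4)
  expect_equal(max(labels), 1L)
  cen <- nucleus_centroids(labels, 0.2)
  expect_lt(abs(cen$x_um - 70 * 0.2), 0.5 * 0.2)
  expect_lt(abs(cen$y_um - 60 * 0.2), 0.5 * 0.2)
})

test_that("a blank image yields zero labels, not an error", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64), 0.2)), 0L)
  expect_equal(max(segment_nuclei(matrix(7, 64, 64), 0.2)), 0L)
})

test_that("a three-nucleus scene segments to three labels near truth", {
  p <- scene_params(n_cells = 3, n_frames = 2, image_shape = c(512L, 512L),
                    endosome_count_per_cell = 0L, seed = 14)
  tr <- generate_scene(p)
  mv <- render_movie(tr)
  labels <- segment_nuclei(get_frame(mv$stack, 1, "nucleus"), p$pixel_size,
                           nucleus_radius = p$nucleus_radius)
  expect_equal(max(labels), 3L)
  cen <- nucleus_centroids(labels, p$pixel_size)
  nuc <- tr$nuclei[tr$nuclei$frame == 1, ]
  for (i in seq_len(3)) {
    d <- sqrt((cen$x_um - nuc$x_um[i])^2 + (cen$y_um - nuc$y_um[i])^2)
    expect_lt(min(d), 1 * p$pixel_size)
  }
})

test_that("segmentation is translation-equivariant", {
  img <- matrix(0, 128, 128)
  img[oracle_disk(128, c(50, 50), 15)] <- 300
  shifted <- matrix(0, 128, 128)
  shifted[8:128, 5:128] <- img[1:121, 1:124]  # shift by (+7 rows, +4 cols)
  c0 <- nucleus_centroids(segment_nuclei(img, 1, nucleus_radius = 10), 1)
  c1 <- nucleus_centroids(segment_nuclei(shifted, 1, nucleus_radius = 10), 1)
  expect_equal(c1$y_um - c0$y_um, 7, tolerance = 1e-6)
  expect_equal(c1$x_um - c0$x_um, 4, tolerance = 1e-6)
})

test_that("one nucleus stepping steadily forms one full-length track", {
  det <- data.frame(frame = 1:10, label = 1L,
                    x_um = 0.4 * (0:9), y_um = rep(2, 10))
  tr <- track_nuclei(det, max_jump = 1)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)
})

test_that("two well-separated nuclei never swap identity", {
  det <- rbind(data.frame(frame = rep(1:10, each = 1), label = 1L,
                          x_um = 0.3 * (0:9), y_um = 0),
               data.frame(frame = 1:10, label = 2L,
                          x_um = 0.3 * (0:9), y_um = 50))
  tr <- track_nuclei(det, max_jump = 2)
  expect_equal(length(unique(tr$track_id)), 2L)
  ys <- tapply(tr$y_um, tr$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))  # each track stays on its own y level
})

test_that("greedy linking agrees with exhaustive optimal assignment", {
  set.seed(77)
  n <- 5
  agree <- 0L; total <- 0L
  for (rep in 1:20) {
    a <- matrix(runif(2 * n, 0, 50), n, 2)
    b <- a + matrix(rnorm(2 * n, 0, 0.8), n, 2)  # small motion, far apart cells
    det <- rbind(data.frame(frame = 1L, label = 1:n, x_um = a[, 1], y_um = a[, 2]),
                 data.frame(frame = 2L, label = 1:n, x_um = b[, 1], y_um = b[, 2]))
    tr <- track_nuclei(det, max_jump = 10)
    link <- merge(tr[tr$frame == 1, c("track_id", "label")],
                  tr[tr$frame == 2, c("track_id", "label")], by = "track_id")
    got <- link$label.y[order(link$label.x)]
    want <- oracle_optimal_assignment(a, b, max_jump = 10)$assignment
    agree <- agree + sum(got == want); total <- total + n
  }
  expect_gte(agree / total, 0.99)
})

test_that("kinematics match direct finite differences", {
  # straight track: step 1 um, interval 5 min
  tr <- data.frame(track_id = 1L, frame = 1:5, x_um = 0:4, y_um = 0)
  k <- compute_kinematics(tr, frame_interval = 5)
  expect_equal(k$speed_um_min[1:4], rep(0.2, 4))
  expect_equal(k$dir_deg[1:4], rep(0, 4))
  expect_true(is.na(k$dir_deg[5]))
  expect_equal(unique(k$persistence), 1)
  # out and back
  oab <- data.frame(track_id = 1L, frame = 1:3, x_um = c(0, 3, 0), y_um = 0)
  expect_equal(unique(compute_kinematics(oab, 1)$persistence), 0)
  # seeded random walk vs direct differences
  set.seed(5)
  rw <- data.frame(track_id = 1L, frame = 1:50,
                   x_um = cumsum(rnorm(50)), y_um = cumsum(rnorm(50)))
  k <- compute_kinematics(rw, frame_interval = 2, min_displacement = 0)
  direct <- sqrt(diff(rw$x_um)^2 + diff(rw$y_um)^2) / 2
  expect_equal(k$speed_um_min[1:49], direct, tolerance = 1e-9)
  expect_true(all(k$persistence <= 1 + 1e-12))
})

test_that("a single-frame track is a kinematics error", {
  tr <- data.frame(track_id = 1L, frame = 1L, x_um = 0, y_um = 0)
  expect_error(compute_kinematics(tr, 5), "kinematics-undefined")
})

test_that("low-displacement frames are gated out of the direction", {
  tr <- data.frame(track_id = 1L, frame = 1:4,
                   x_um = c(0, 0.01, 1, 2), y_um = 0)
  k <- compute_kinematics(tr, frame_interval = 1, min_displacement = 0.1)
  expect_true(is.na(k$dir_deg[1]))   # 0.01 um step below the gate
  expect_equal(k$dir_deg[2], 0)
})
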