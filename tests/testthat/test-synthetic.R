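test_that("degenerate persistence gives a straight track with constant steps", {
  p <- scene_params(n_cells = 1, n_frames = 10, frame_interval = 1,
                    speed_mean = 2, turn_persistence = 1,
                    image_shape = c(1024L, 1024L), seed = 3)
  tr <- generate_scene(p)$nuclei
  steps <- cbind(diff(tr$x_um), diff(tr$y_um))
  lens <- sqrt(rowSums(steps^2))
  expect_equal(lens, rep(2 * 1, 9), tolerance = 1e-9)  # speed * interval
  dirs <- atan2(steps[, 2], steps[, 1])
  expect_lt(max(abs(diff(dirs))), 1e-9)
})

test_that("large kappa concentrates all angles at the mean", {
  a <- sample_angles(200, c(weight = 1, mu = 0, kappa = 1e6), seed = 4)
  expect_true(all(pmin(a, 360 - a) < 1))
})

test_that("weight-0 mixture is uniform on the circle (KS criterion)", {
  crit <- 1.62762 / sqrt(1e4)  # 1% asymptotic KS critical value
  pass <- vapply(1:100, function(i) {
    a <- sample_angles(1e4, c(weight = 0, mu = 0, kappa = 1), seed = 1000 + i)
    oracle_ks_uniform(a) < crit
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("weight-0 mixture has vanishing mean resultant length", {
  rbar <- vapply(1:100, function(i) {
    a <- sample_angles(1e4, c(weight = 0, mu = 0, kappa = 1), seed = 2000 + i) * pi / 180
    sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  }, numeric(1))
  expect_gte(sum(rbar < 0.02), 95)
})

test_that("calibrated kappa places the target mass in the front quadrant", {
  k <- calibrate_kappa(0.5)
  a <- sample_angles(1e5, c(weight = 1, mu = 0, kappa = k), seed = 5)
  expect_equal(mean(a >= 315 | a < 45), 0.5, tolerance = 0.01)
  # also check a second calibration level against the empirical mass
  k2 <- calibrate_kappa(0.7)
  a2 <- sample_angles(1e5, c(weight = 1, mu = 0, kappa = k2), seed = 6)
  expect_equal(mean(a2 >= 315 | a2 < 45), 0.7, tolerance = 0.01)
})

test_that("rotating mu rotates the sample exactly (equivariance)", {
  base <- sample_angles(500, c(weight = 1, mu = 0, kappa = 2), seed = 9)
  rot <- sample_angles(500, c(weight = 1, mu = 73.5, kappa = 2), seed = 9)
  expect_equal((base + 73.5) %% 360, rot, tolerance = 1e-12)
})

test_that("identical params and seed give identical truth and pixels", {
  p <- scene_params(n_frames = 3, seed = 12)
  t1 <- generate_scene(p); t2 <- generate_scene(p)
  expect_identical(t1, t2)
  m1 <- render_movie(t1); m2 <- render_movie(t2)
  expect_identical(m1$stack$pixels, m2$stack$pixels)
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(turn_persistence = 1.2), "probability")
  expect_error(scene_params(centrosome_ahead_prob = -0.1), "probability")
  expect_error(scene_params(angular_mixture = c(1, 0, -2)), "kappa")
  expect_error(scene_params(speed_mean = NaN), "speed_mean")
  expect_error(sample_angles(0, c(1, 0, 1)), "empty-sample")
})

test_that("noiseless render recovers the nucleus centroid by half-max threshold", {
  p <- scene_params(n_frames = 2, noise = c(0, 0), endosome_count_per_cell = 0L,
                    seed = 21)
  tr <- generate_scene(p)
  mv <- render_movie(tr)
  img <- get_frame(mv$stack, 1, "nucleus") - 100  # remove camera offset
  mask <- img > max(img) / 2
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2] - 1) * p$pixel_size
  cy <- mean(idx[, 1] - 1) * p$pixel_size
  expect_lt(abs(cx - tr$nuclei$x_um[1]), 0.5 * p$pixel_size)
  expect_lt(abs(cy - tr$nuclei$y_um[1]), 0.5 * p$pixel_size)
})

test_that("zero endosomes render an exact background endosome channel", {
  p <- scene_params(n_frames = 2, noise = c(0, 0), endosome_count_per_cell = 0L,
                    seed = 22)
  mv <- render_movie(generate_scene(p))
  expect_true(all(get_frame(mv$stack, 1, "endosomes") == 100))
})

test_that("rendered endosome counts match the sidecar truth (conservation)", {
  p <- scene_params(n_frames = 3, noise = c(0, 0), endosome_count_per_cell = 5L,
                    endosome_radius_range = c(6, 12), seed = 23)
  tr <- generate_scene(p)
  mv <- render_movie(tr)
  for (t in 1:2) {  # last frame has no direction, hence no endosomes
    sp <- detect_endosomes(get_frame(mv$stack, t, "endosomes"), p$pixel_size,
                           spot_sigma = p$spot_sigma)
    expect_equal(nrow(sp), sum(tr$endosomes$frame == t))
  }
})

test_that("nucleus population masks are single-component and labels follow the rate", {
  pop <- generate_nucleus_population(60, deformed_fraction = 0.3, seed = 31)
  expect_length(pop$masks, 60)
  expect_equal(nrow(pop$labels), 60)
  comp <- vapply(pop$masks, function(m) max(EBImage::bwlabel(m)), numeric(1))
  expect_true(all(comp == 1))
  # Bernoulli(0.3) at n = 60: allow a wide band, just sanity
  expect_gt(mean(pop$labels$deformed), 0.1)
  expect_lt(mean(pop$labels$deformed), 0.55)
})

test_that("centrosome truth flags agree with the rendered geometry", {
  p <- scene_params(n_frames = 12, centrosome_ahead_prob = 0.5, seed = 41)
  tr <- generate_scene(p)
  masks <- scene_nucleus_masks(tr, 1)
  track <- tr$nuclei[tr$nuclei$cell == 1, ]
  cen <- tr$centrosome[tr$centrosome$cell == 1, ]
  res <- centrosome_ahead_fraction(track, cen, masks, p$pixel_size)
  truth_pct <- 100 * mean(cen$ahead[cen$frame %in% as.integer(names(res$ahead))])
  expect_equal(res$percent_ahead, truth_pct, tolerance = 1e-9)
})
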