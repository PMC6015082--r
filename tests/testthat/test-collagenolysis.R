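test_that("control fields normalize to mean index 100 by construction", {
  fields <- data.frame(field_id = 1:6,
                       spot_count = c(120, 150, 180, 60, 50, 70),
                       cell_count = c(5, 5, 6, 5, 5, 5),
                       control = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  res <- degradation_index(fields)
  expect_equal(mean(res$norm_index[res$control]), 100, tolerance = 1e-12)
  expect_equal(res$raw_index, fields$spot_count / fields$cell_count)
})

test_that("degradation index is linear and zero-preserving", {
  fields <- data.frame(field_id = 1:4, spot_count = c(100, 80, 0, 40),
                       cell_count = c(5, 4, 5, 5),
                       control = c(TRUE, TRUE, FALSE, FALSE))
  res <- degradation_index(fields)
  expect_equal(res$norm_index[3], 0)
  doubled <- fields; doubled$spot_count <- 2 * doubled$spot_count
  res2 <- degradation_index(doubled)
  expect_equal(res2$raw_index, 2 * res$raw_index)
  expect_equal(res2$norm_index, res$norm_index)  # normalization absorbs the scale
  zero <- fields; zero$spot_count[zero$control] <- 0
  expect_error(degradation_index(zero), "normalization error")
})

test_that("line scans of a uniform image are constant", {
  img <- matrix(42, 64, 64)
  pl <- cbind(x_um = c(1, 10), y_um = c(2, 8))
  prof <- extract_linescan(img, pl, pixel_size = 0.2)
  expect_true(all(abs(prof$intensity - 42) < 1e-9))
})

test_that("a bright pixel on the line peaks at its arclength position", {
  img <- matrix(10, 64, 64)
  img[33, 21] <- 1000  # 0-based (32, 20)
  pl <- cbind(x_um = c(0, 6), y_um = c(6.4, 6.4))  # row 32 at pixel_size 0.2
  prof <- extract_linescan(img, pl, pixel_size = 0.2)
  expect_equal(prof$pos_um[which.max(prof$intensity)], 20 * 0.2, tolerance = 0.2)
})

test_that("an anterior intensity bump is localized within a pixel", {
  img <- matrix(0, 128, 128)
  img <- oracle_add_gaussian(img, 64, 90, 3, 800)  # bump at col 90
  pl <- cbind(x_um = c(0, 25), y_um = c(12.8, 12.8))
  prof <- extract_linescan(img, pl, pixel_size = 0.2, transverse_width_um = 1)
  expect_equal(prof$pos_um[which.max(prof$intensity)], 90 * 0.2, tolerance = 0.2)
})

test_that("a polyline leaving the image is a geometry error", {
  img <- matrix(0, 32, 32)
  expect_error(extract_linescan(img, cbind(c(0, 50), c(0, 0)), 0.2), "geometry")
})

test_that("reference points map exactly to -1, 0, 1", {
  prof <- data.frame(pos_um = seq(0, 30, by = 0.2))
  prof$intensity <- prof$pos_um  # intensity encodes position
  refs <- c(back = 4, center = 13, front = 28)
  norm <- normalize_linescan(prof, refs)
  expect_equal(norm$intensity[norm$coord == -1], 4, tolerance = 1e-9)
  expect_equal(norm$intensity[norm$coord == 0], 13, tolerance = 1e-9)
  expect_equal(norm$intensity[norm$coord == 1], 28, tolerance = 1e-9)
  # point midway between center and front lands at 0.5
  expect_equal(norm$intensity[norm$coord == 0.5], (13 + 28) / 2, tolerance = 1e-9)
})

test_that("symmetric references give a globally affine map with known slope", {
  prof <- data.frame(pos_um = seq(0, 20, by = 0.1))
  prof$intensity <- 3 * prof$pos_um + 7
  refs <- c(5, 10, 15)  # center equidistant: both segments have slope 1/5
  norm <- normalize_linescan(prof, refs)
  # closed form: intensity(coord) = 3 * (10 + 5 * coord) + 7
  expect_equal(norm$intensity, 3 * (10 + 5 * norm$coord) + 7, tolerance = 1e-9)
  expect_error(normalize_linescan(prof, c(10, 5, 15)), "validation")
})

test_that("normalization with references (-1, 0, 1) is the identity", {
  prof <- data.frame(pos_um = seq(0, 10, by = 0.1), intensity = sin(seq(0, 10, by = 0.1)))
  once <- normalize_linescan(prof, c(2, 5, 9))
  again <- normalize_linescan(data.frame(pos_um = once$coord, intensity = once$intensity),
                              c(-1, 0, 1))
  expect_equal(again$intensity, once$intensity, tolerance = 1e-9)
})

test_that("profile averaging matches direct arithmetic", {
  g <- seq(-1, 1, length.out = 201)
  c1 <- data.frame(coord = g, intensity = g^2)
  c2 <- data.frame(coord = g, intensity = 2 * g^2)
  c3 <- data.frame(coord = g, intensity = 3 * g^2 + 1)
  avg <- average_profiles(list(c1, c2, c3))
  expect_equal(avg$mean, (c1$intensity + c2$intensity + c3$intensity) / 3)
  expect_equal(avg$sd, apply(cbind(c1$intensity, c2$intensity, c3$intensity), 1, sd))
  # identical curves: sd 0; single curve: mean = itself, sd 0, n = 1
  same <- average_profiles(list(c1, c1))
  expect_true(all(same$sd == 0))
  one <- average_profiles(list(c2))
  expect_equal(one$mean, c2$intensity)
  expect_true(all(one$sd == 0) && all(one$n == 1))
  expect_error(average_profiles(list()), "empty-sample")
})

test_that("auto-derived references bracket a synthetic DAPI peak", {
  pos <- seq(0, 30, by = 0.2)
  dapi <- data.frame(pos_um = pos,
                     intensity = 100 + 900 * exp(-(pos - 14)^2 / (2 * 3^2)))
  refs <- derive_references(dapi)
  expect_equal(unname(refs["center"]), 14, tolerance = 0.5)
  expect_lt(refs["back"], 14)
  expect_gt(refs["front"], 14)
})
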