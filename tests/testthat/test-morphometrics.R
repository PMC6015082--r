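test_that("a discrete disk is circular, solid and classified normal", {
  mask <- oracle_disk(80, c(40, 40), 30)
  s <- score_nucleus_shape(mask, pixel_size = 0.2)
  expect_gte(s$circularity, 0.95)
  expect_lte(s$circularity, 1.05)
  expect_gt(s$solidity, 0.98)
  expect_equal(s$lobe_count, 0L)
  expect_equal(s$deformation_class, "normal")
  expect_equal(s$area_um2, sum(mask) * 0.04)
})

test_that("a two-lobe peanut mask is classified deformed via its waist", {
  m1 <- oracle_disk(120, c(60, 45), 22)
  m2 <- oracle_disk(120, c(60, 80), 22)
  s <- score_nucleus_shape(m1 | m2, pixel_size = 0.2)
  expect_equal(s$deformation_class, "deformed")
  expect_gte(s$lobe_count, 2L)
})

test_that("shape descriptors are rotation-invariant within tolerance", {
  # same ellipse rasterized at 0 and 45 degrees
  ell <- function(theta) {
    rr <- matrix(0:119, 120, 120); cc <- t(rr)
    u <- cos(theta) * (cc - 60) + sin(theta) * (rr - 60)
    v <- -sin(theta) * (cc - 60) + cos(theta) * (rr - 60)
    (u / 40)^2 + (v / 25)^2 <= 1
  }
  s0 <- score_nucleus_shape(ell(0), 0.2)
  s45 <- score_nucleus_shape(ell(pi / 4), 0.2)
  expect_lt(abs(s0$circularity - s45$circularity) / s0$circularity, 0.02)
  expect_lt(abs(s0$solidity - s45$solidity) / s0$solidity, 0.02)
  expect_equal(s0$deformation_class, s45$deformation_class)
})

test_that("invalid masks are rejected", {
  expect_error(score_nucleus_shape(matrix(FALSE, 10, 10)), "empty")
  two <- matrix(FALSE, 40, 40); two[5:10, 5:10] <- TRUE; two[30:35, 30:35] <- TRUE
  expect_error(score_nucleus_shape(two), "one connected component")
})

test_that("the classifier recovers a labelled deformed fraction", {
  pop <- generate_nucleus_population(120, deformed_fraction = 0.3, seed = 90)
  cls <- vapply(pop$masks, function(m)
    score_nucleus_shape(m, 0.2)$deformation_class, character(1))
  got <- mean(cls == "deformed")
  expect_equal(got, mean(pop$labels$deformed), tolerance = 0.05)
})

test_that("centrosome-nucleus distance matches a brute-force oracle", {
  mask <- oracle_disk(100, c(50, 50), 20)
  ps <- 0.2
  # boundary point: distance 0
  expect_equal(centrosome_nucleus_distance(c(70 * ps, 50 * ps), mask, ps), 0)
  # interior point: 0
  expect_equal(centrosome_nucleus_distance(c(50 * ps, 50 * ps), mask, ps), 0)
  # 5 px outside the rim along +x: 1.0 um within half-pixel discretization
  d <- centrosome_nucleus_distance(c(75 * ps, 50 * ps), mask, ps)
  expect_equal(d, 1.0, tolerance = 0.5 * ps)
  # random points vs exhaustive min over boundary pixels (erosion difference)
  er <- mask & !(rbind(FALSE, mask[-100, ]) & rbind(mask[-1, ], FALSE) &
                   cbind(FALSE, mask[, -100]) & cbind(mask[, -1], FALSE))
  bidx <- which(er, arr.ind = TRUE) - 1
  set.seed(12)
  for (i in 1:10) {
    pt <- runif(2, 0, 99) * ps
    inside <- mask[round(pt[2] / ps) + 1, round(pt[1] / ps) + 1]
    want <- if (inside) 0 else
      min(sqrt((bidx[, 1] * ps - pt[2])^2 + (bidx[, 2] * ps - pt[1])^2))
    expect_equal(centrosome_nucleus_distance(pt, mask, ps), want, tolerance = 1e-6)
  }
})

test_that("centrosome ahead scoring hits its trivial extremes", {
  track <- data.frame(frame = 1:5, dir_deg = rep(0, 5))
  masks <- lapply(1:5, function(f) oracle_disk(60, c(30, 30), 10))
  names(masks) <- 1:5
  ps <- 1
  far <- data.frame(frame = 1:5, x_um = 55, y_um = 30)      # beyond the front edge
  res <- centrosome_ahead_fraction(track, far, masks, ps)
  expect_equal(res$percent_ahead, 100)
  at_c <- data.frame(frame = 1:5, x_um = 30, y_um = 30)     # at the centroid
  expect_equal(centrosome_ahead_fraction(track, at_c, masks, ps)$percent_ahead, 0)
  expect_error(centrosome_ahead_fraction(
    data.frame(frame = 1, dir_deg = NA_real_), far, masks, ps), "empty-sample")
})

test_that("Tks5 area ratio honours the sub-8-pixel exclusion", {
  cell <- matrix(TRUE, 40, 25)          # 1000 px cell
  img <- matrix(10, 40, 25)
  img[2:8, 2] <- 1000                   # 7-px region: excluded
  expect_equal(tks5_area_ratio(img, cell), 0)
  img2 <- matrix(10, 40, 25)
  img2[11:20, 5:14] <- 1000             # 100-px region in a 1000-px cell
  expect_equal(tks5_area_ratio(img2, cell), 10)
  expect_equal(tks5_area_ratio(img2, cell, threshold_mode = "otsu"), 10)
  expect_equal(tks5_area_ratio(matrix(10, 40, 25), cell), 0)  # blank channel
  expect_error(tks5_area_ratio(img2, cell & FALSE), "empty cell mask")
})

test_that("invasion index follows the depth-threshold arithmetic", {
  expect_equal(invasion_index(c(500, 0, 0, 0), z_step = 10), 0)
  expect_equal(invasion_index(c(0, 0, 0, 0, 700), z_step = 10), 1)
  # slices at depths 0, 20, 40 um: only the 40-um slice is beyond 30 um
  expect_equal(invasion_index(c(300, 100, 100), z_step = 20), 0.2)
  # invariant to a global intensity scale
  expect_equal(invasion_index(c(300, 100, 100) * 13, z_step = 20), 0.2)
  # optional origin: depth measured from the first slice with signal
  expect_equal(invasion_index(c(0, 300, 100, 100), z_step = 20,
                              origin = "first_signal"), 0.2)
  expect_error(invasion_index(c(0, 0, 0), z_step = 10), "zero total")
  expect_error(invasion_index(c(100), z_step = 10), "2 slices")
})

test_that("ablation displacement projects net window motion onto the movement axis", {
  still <- cbind(x = rep(3, 5), y = rep(4, 5))
  expect_equal(ablation_displacement(still, still, 0), c(pre = 0, post = 0))
  drift <- cbind(x = seq(0, 2, length.out = 6), y = rep(0, 6))
  expect_equal(ablation_displacement(still, drift, 0)[["post"]], 2)
  # oscillation vs direct projected-difference oracle, arbitrary direction
  set.seed(13)
  for (i in 1:5) {
    dir <- runif(1, 0, 360)
    w1 <- cbind(cumsum(rnorm(8)), cumsum(rnorm(8)))
    w2 <- cbind(cumsum(rnorm(8)), cumsum(rnorm(8)))
    u <- c(cos(dir * pi / 180), -sin(dir * pi / 180))
    want <- c(pre = sum((w1[8, ] - w1[1, ]) * u),
              post = sum((w2[8, ] - w2[1, ]) * u))
    expect_equal(ablation_displacement(w1, w2, dir), want, tolerance = 1e-9)
  }
  expect_error(ablation_displacement(still[1, , drop = FALSE], drift, 0),
               "validation")
})
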