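test_that("track speed sums Euclidean segments over elapsed hours", {
  two <- tibble::tibble(timestamp = c(0, 15), x = c(0, 3), y = c(0, 4))
  expect_equal(track_speed(two)$distance_m, 5)
  # 100 segments of 15 m in exactly one hour -> 1500 m/h
  n <- 101
  path <- tibble::tibble(timestamp = seq(0, 3600, length.out = n),
                         x = seq(0, 15 * (n - 1), by = 15), y = 0)
  expect_equal(track_speed(path)$speed_m_h, 1500)
})

test_that("GPS error filter drops long segments but keeps elapsed time", {
  jump <- tibble::tibble(timestamp = c(0, 15, 30), x = c(0, 500, 510),
                         y = 0)
  res <- track_speed(jump, max_step_m = 100)
  expect_equal(res$distance_m, 10)
  expect_equal(res$n_dropped, 1)
  # filter off is a no-op
  free <- track_speed(jump)
  expect_equal(free$distance_m, 510)
  expect_equal(free$n_dropped, 0)
  # speed-based cutoff scales with the gap: same displacement over a long
  # gap survives
  slow <- tibble::tibble(timestamp = c(0, 3600), x = c(0, 500), y = 0)
  expect_equal(track_speed(slow, max_speed_kmh = 10)$distance_m, 500)
  expect_error(track_speed(jump[1, ]), "2 fixes")
  bad <- tibble::tibble(timestamp = c(0, 15, 10), x = 0, y = 0)
  expect_error(track_speed(bad), "increasing")
})

test_that("pedometer summary is a duration-weighted aggregation", {
  one <- tibble::tibble(duration_s = 3600, steps = 95, lying_s = 1800)
  s <- pedometer_summary(one)
  expect_equal(s$steps_per_h, 95)
  expect_equal(s$lying_ratio, 0.5)
  all_lying <- tibble::tibble(duration_s = 600, steps = 0, lying_s = 600)
  expect_equal(pedometer_summary(all_lying)$lying_ratio, 1)
  # two intervals merge to the duration-weighted rate (hand sum)
  two <- tibble::tibble(duration_s = c(3600, 1800), steps = c(60, 90),
                        lying_s = c(0, 900))
  s2 <- pedometer_summary(two)
  expect_equal(s2$steps_per_h, (60 + 90) / 1.5)
  expect_equal(s2$lying_ratio, 900 / 5400)
  expect_error(pedometer_summary(tibble::tibble(duration_s = 10, steps = 1,
                                                lying_s = 20)), "lying_s")
})

test_that("rasterized fixes land in half-open cells and are conserved", {
  pad <- flat_paddock(side = 20)
  fixes <- tibble::tibble(x = c(1, 6, 11, 16), y = c(1, 6, 11, 16))
  g <- rasterize_fixes(fixes, pad)
  expect_equal(sum(g$counts), 4)
  expect_equal(sum(g$counts == 1), 4)
  # a fix exactly on a cell edge goes to the higher-index cell, once
  edge <- rasterize_fixes(tibble::tibble(x = 5, y = 2.5), pad)
  expect_equal(sum(edge$counts), 1)
  expect_equal(which(edge$counts > 0, arr.ind = TRUE)[1, ],
               c(row = 1, col = 2))
  # fixes outside the paddock are reported, not dropped silently
  out <- rasterize_fixes(tibble::tibble(x = c(1, 100), y = c(1, 100)), pad)
  expect_equal(out$n_inside, 1)
  expect_equal(out$n_outside, 1)
  expect_equal(sum(out$counts), out$n_inside)
})

test_that("Horn slope is exact on planes and isotropic", {
  flat <- list(z = matrix(0, 5, 5), cellsize = 5)
  expect_true(all(slope_raster(flat) == 0))
  # plane rising 1 m per metre of x -> 100% everywhere inside
  n <- 7
  plane_x <- list(z = matrix(rep(seq(0, by = 5, length.out = n), each = n),
                             n, n),
                  cellsize = 5)
  sx <- slope_raster(plane_x)
  expect_equal(sx[2:(n - 1), 2:(n - 1)], matrix(100, n - 2, n - 2))
  # same plane rising in y has the same slope magnitude
  plane_y <- list(z = t(plane_x$z), cellsize = 5)
  expect_equal(slope_raster(plane_y)[2:(n - 1), 2:(n - 1)],
               sx[2:(n - 1), 2:(n - 1)])
  expect_error(slope_raster(list(z = matrix(0, 2, 2), cellsize = 5)),
               "3 x 3")
})

test_that("water-distance raster is a min over points", {
  pad <- flat_paddock(side = 100, water = c(2.5, 2.5))
  wd <- water_distance_raster(pad)
  expect_equal(wd[1, 1], 0)
  # cell centre at (32.5, 42.5): distance to (2.5, 2.5) is 50
  expect_equal(wd[9, 7], 50)
  # adding a water point can only decrease distances
  pad2 <- flat_paddock(side = 100, water = c(2.5, 2.5))
  pad2$water <- rbind(pad2$water, c(97.5, 97.5))
  expect_true(all(water_distance_raster(pad2) <= wd + 1e-12))
})

test_that("covariate effect recovers a known Poisson coefficient", {
  set.seed(71)
  # synthetic grid: counts drawn with log-mean 1.0 * z(slope), 2000 cells
  side <- 225 # 45 x 45 cells
  n <- side / 5
  dem <- list(z = matrix(rnorm(n * n, sd = 4), n, n), xll = 0, yll = 0,
              cellsize = 5, nodata = -9999)
  dem$z <- grazemetry:::smooth_matrix(dem$z, 2) * 40
  pad <- paddock("p", "P", cbind(c(0, side, side, 0), c(0, 0, side, side)),
                 dem, matrix(c(10, 10), ncol = 2))
  g <- rasterize_fixes(tibble::tibble(x = numeric(0), y = numeric(0)), pad)
  z <- as.vector(g$slope_pct)[as.vector(g$mask)]
  z <- (z - mean(z)) / sd(z)
  counts <- rpois(length(z), exp(0.5 + 1.0 * z))
  g$counts[as.vector(g$mask)] <- counts
  est <- covariate_effect(g, "slope")
  expect_equal(est$estimate, 1.0, tolerance = 0.1)
  expect_equal(est$n_cells, length(z))
  # sign: counts decreasing with slope give a negative coefficient
  g2 <- g
  g2$counts[as.vector(g2$mask)] <- rpois(length(z), exp(0.5 - 0.8 * z))
  expect_lt(covariate_effect(g2, "slope")$estimate, 0)
})

test_that("quasi-Poisson IRLS point estimates match a Newton oracle", {
  set.seed(72)
  pad <- flat_paddock(side = 50, water = c(2, 3))
  g <- rasterize_fixes(tibble::tibble(x = numeric(0), y = numeric(0)), pad)
  m <- as.vector(g$mask)
  wz <- as.vector(g$water_dist_m)[m]
  z <- (wz - mean(wz)) / sd(wz)
  y <- rpois(sum(m), exp(1 - 0.5 * z))
  g$counts[m] <- y
  est <- covariate_effect(g, "water")
  oracle <- poisson_newton(y, z)
  expect_equal(est$estimate, oracle[2], tolerance = 1e-8)
})

test_that("null covariates give near-zero standardized coefficients", {
  set.seed(73)
  pad <- flat_paddock(side = 150, water = c(10, 80))
  g0 <- rasterize_fixes(tibble::tibble(x = numeric(0), y = numeric(0)), pad)
  m <- sum(g0$mask)
  zs <- replicate(40, {
    g0$counts[as.vector(g0$mask)] <- rpois(m, 3)
    f <- covariate_effect(g0, "water")
    f$statistic
  })
  expect_gte(mean(abs(zs) < 2), 0.9)
})

test_that("movement_metrics joins tracks, pedometer and occupancy", {
  b <- tiny_bundle()
  mm <- movement_metrics(b$gps, b$pedometer, b$paddocks)
  expect_equal(nrow(mm), length(unique(b$gps$cow_id)) * 3)
  expect_true(all(mm$speed_m_h > 0))
  expect_true(all(mm$camargo_evenness > 0 & mm$camargo_evenness <= 1))
  expect_true(all(is.na(mm$steps_per_h) |
                    (mm$lying_ratio >= 0 & mm$lying_ratio <= 1)))
})
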