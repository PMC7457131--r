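test_that("simulated cows follow the claw power law and round-trip outlines", {
  bp <- breed_params("T", weight_meanlog = log(500), weight_sdlog = 0.1,
                     claw_coef = 2.1, claw_exp = 0.7, claw_noise_sd = 0)
  sim <- simulate_cows(bp, 20, seed = 5)
  # noiseless generator: log A exactly linear in log W
  a <- sim$cows |>
    dplyr::group_by(cow_id) |>
    dplyr::group_modify(~ tibble::tibble(A = total_claw_base(
      sim$outlines[sim$outlines$cow_id == .y$cow_id, ]))) |>
    dplyr::ungroup()
  d <- dplyr::left_join(sim$cows, a, by = "cow_id")
  fit <- lm(log(A) ~ log(weight_start), data = d)
  expect_equal(unname(coef(fit)[2]), 0.7, tolerance = 1e-6)
  expect_lt(suppressWarnings(summary(fit)$sigma), 1e-10)
  # outline rendering reproduces the target area through total_claw_base
  expect_equal(d$A, bp$claw_coef * d$weight_start^0.7, tolerance = 1e-6)
})

test_that("simulated body weights match the breed distribution", {
  bp <- default_breed_params()$OB
  sim <- simulate_cows(bp, 200, seed = 6)
  mu <- exp(bp$weight_meanlog + bp$weight_sdlog^2 / 2)
  se <- sd(sim$cows$weight_start) / sqrt(200)
  expect_lt(abs(mean(sim$cows$weight_start) - mu), 3 * se)
})

test_that("pasture generation hits the target slope and is deterministic", {
  tt <- alpine_taxa()
  spec <- default_pasture_specs()[["P2-HC"]]
  p1 <- make_pasture(spec, tt, seed = 9)
  p2 <- make_pasture(spec, tt, seed = 9)
  expect_identical(p1$dem$z, p2$dem$z)
  expect_identical(p1$water, p2$water)
  sl <- slope_raster(p1$dem)
  n <- nrow(sl)
  expect_equal(mean(sl[2:(n - 1), 2:(n - 1)]), spec$mean_slope_pct,
               tolerance = 0.05)
  # zero roughness -> flat
  flat_spec <- spec; flat_spec$mean_slope_pct <- 0
  expect_true(all(make_pasture(flat_spec, tt, seed = 9)$dem$z == 0))
})

test_that("tracks are deterministic and biased away from steep cells", {
  tt <- alpine_taxa()
  pad <- make_pasture(default_pasture_specs()[["P2-HC"]], tt, seed = 10)
  bp <- breed_params("T", weight_meanlog = log(500), weight_sdlog = 0.1,
                     claw_coef = 2, slope_aversion = 3,
                     water_attraction = 0, quality_preference = 0,
                     rest_prob = 0, persistence = 0,
                     step_rate_per_h = 700)
  t1 <- simulate_track(pad, bp, seed = 11, duration_h = 6)
  t2 <- simulate_track(pad, bp, seed = 11, duration_h = 6)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  # occupied-cell mean slope well below the paddock mean under strong aversion
  gs <- grazemetry:::grid_spec(pad, pad$dem$cellsize)
  sl <- slope_raster(pad$dem)
  cells <- attr(t1, "walk")$cell
  occupied_slope <- mean(as.vector(sl)[cells])
  expect_lt(occupied_slope, mean(as.vector(sl)[as.vector(gs$mask)]))
})

test_that("an unbiased non-resting walk spreads close to uniform", {
  tt <- alpine_taxa()
  spec <- default_pasture_specs()[["P1-HC"]] # 0.27 ha ~ 121 cells
  spec$mean_slope_pct <- 0
  pad <- make_pasture(spec, tt, seed = 12)
  bp <- breed_params("T", weight_meanlog = log(500), weight_sdlog = 0.1,
                     claw_coef = 2, slope_aversion = 0,
                     water_attraction = 0, quality_preference = 0,
                     rest_prob = 0, persistence = 0, step_rate_per_h = 900)
  tr <- simulate_track(pad, bp, seed = 13, duration_h = 60, gps_error_m = 0)
  g <- rasterize_fixes(tr, pad)
  e <- camargo_evenness(as.vector(g$counts)[as.vector(g$mask)])
  expect_gt(e, 0.8)
})

test_that("pedometer steps scale with distance and lying follows rest", {
  tt <- alpine_taxa()
  pad <- make_pasture(default_pasture_specs()[["P1-HC"]], tt, seed = 14)
  bp <- default_breed_params()$OB
  tr <- simulate_track(pad, bp, seed = 15, duration_h = 12)
  ped <- simulate_pedometer(tr, bp, seed = 16)
  walk <- attr(tr, "walk")
  expect_equal(sum(ped$duration_s), length(walk$cell) * 15)
  expect_equal(sum(ped$lying_s), sum(walk$resting) * 15)
  # Poisson mean proportional to distance: totals agree within 4 sd
  lam <- bp$steps_per_m * sum(walk$step_m)
  expect_lt(abs(sum(ped$steps) - lam), 4 * sqrt(lam) + 1)
  # a cow that always rests takes no steps and lies the whole time
  bp_rest <- breed_params("R", weight_meanlog = log(400), weight_sdlog = 0.1,
                          claw_coef = 2, rest_prob = 1)
  tr0 <- simulate_track(pad, bp_rest, seed = 17, duration_h = 2)
  ped0 <- simulate_pedometer(tr0, bp_rest, seed = 18)
  expect_equal(sum(ped0$steps), 0)
  expect_equal(sum(ped0$lying_s), sum(ped0$duration_s))
})

test_that("pedometer step rate tracks GPS speed across cows", {
  tt <- alpine_taxa()
  pad <- make_pasture(default_pasture_specs()[["P1-OB"]], tt, seed = 19)
  rates <- seq(60, 700, length.out = 12)
  res <- purrr::map_dfr(seq_along(rates), function(i) {
    bp <- breed_params("T", weight_meanlog = log(500), weight_sdlog = 0.1,
                       claw_coef = 2, step_rate_per_h = rates[i],
                       rest_prob = 0.3)
    tr <- simulate_track(pad, bp, seed = 20 + i, duration_h = 8)
    ped <- simulate_pedometer(tr, bp, seed = 40 + i)
    tibble::tibble(
      speed = track_speed(tr, max_speed_kmh = 10)$speed_m_h,
      steps = pedometer_summary(ped)$steps_per_h
    )
  })
  expect_gte(cor(res$steps, res$speed)^2, 0.8)
})

test_that("softmax bite selection reduces to availability sampling at tau 0", {
  tt <- tiny_taxa()
  av <- tibble::tibble(taxon_id = c("good_grass", "grass_b", "poor_shrub"),
                       abundance = c(0.5, 0.3, 0.2))
  neutral <- breed_params("N", weight_meanlog = log(400), weight_sdlog = 0.1,
                          claw_coef = 2, quality_preference = 0)
  b <- simulate_bites(av, tt, "P1", neutral, 5000, seed = 21)
  counts <- table(factor(b$taxon_id, levels = av$taxon_id))
  expect_gt(stats::chisq.test(counts, p = av$abundance)$p.value, 0.001)
})

test_that("diet quality rises with the selectivity temperature", {
  tt <- tiny_taxa()
  av <- tibble::tibble(taxon_id = c("good_grass", "grass_b", "poor_shrub",
                                    "thistle_sp"),
                       abundance = c(0.2, 0.2, 0.4, 0.2))
  mk <- function(tau) breed_params("T", weight_meanlog = log(400),
                                   weight_sdlog = 0.1, claw_coef = 2,
                                   quality_preference = tau)
  qual <- function(bites) {
    diet_quality(relative_consumption(bites), tt, "P1")
  }
  wins <- sapply(1:40, function(i) {
    q_hi <- qual(simulate_bites(av, tt, "P1", mk(2), 300, seed = 100 + i))
    q_lo <- qual(simulate_bites(av, tt, "P1", mk(0.3), 300, seed = 500 + i))
    q_hi > q_lo
  })
  expect_gte(mean(wins), 0.95)
  # tau large: quality approaches the best available value
  strong <- qual(simulate_bites(av, tt, "P1", mk(25), 400, seed = 22))
  expect_gt(strong, 7.9)
})

test_that("weight change is linear in diet quality around maintenance", {
  bp <- breed_params("T", weight_meanlog = log(500), weight_sdlog = 0.1,
                     claw_coef = 2, intake_efficiency = 0.2,
                     maintenance_quality = 5)
  # at maintenance, no noise: exactly zero change
  expect_equal(simulate_weights(480, 5, bp, 70, seed = 23, noise_sd = 0), 480)
  w_hi <- simulate_weights(480, 7, bp, 70, seed = 23, noise_sd = 0)
  w_lo <- simulate_weights(480, 3, bp, 70, seed = 23, noise_sd = 0)
  expect_equal(w_hi - 480, 0.2 * 2 * 70)
  expect_equal(480 - w_lo, 0.2 * 2 * 70)
  # breed-specific thresholds reproduce gain-on-poor / loss-on-fair pattern
  hc <- default_breed_params()$HC
  ah <- default_breed_params()$AH
  expect_gt(mean(simulate_weights(rep(358, 50), 3, hc, 70, seed = 24)), 358)
  expect_lt(mean(simulate_weights(rep(679, 50), 5, ah, 70, seed = 25)), 679)
})

test_that("the full study bundle is deterministic in (seed, config)", {
  b1 <- tiny_bundle()
  b2 <- simulate_study(sim_config(seed = 7, n_cows_per_breed = 3,
                                  track_hours = 1, bites_per_bout = 120))
  expect_identical(b1$cows, b2$cows)
  expect_identical(b1$gps, b2$gps)
  expect_identical(b1$bites, b2$bites)
  expect_identical(b1$pedometer, b2$pedometer)
  b3 <- simulate_study(sim_config(seed = 8, n_cows_per_breed = 3,
                                  track_hours = 1, bites_per_bout = 120))
  expect_false(identical(b1$gps$x, b3$gps$x))
})
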