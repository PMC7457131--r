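test_that("SMA fit matches closed-form slope, intercept and r^2", {
  exact <- sma_fit(data.frame(x = c(1, 2, 3), y = c(2, 4, 6)), x, y)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4))
  f <- sma_fit(d, x, y)
  expect_equal(f$slope, sqrt(7 / 3), tolerance = 1e-6) # 1.5275
  expect_equal(f$intercept, 7 / 3 - 2 * sqrt(7 / 3), tolerance = 1e-6)
  expect_equal(f$r_squared, 0.9643, tolerance = 1e-4)
  expect_true(f$ci_lower <= f$slope && f$slope <= f$ci_upper)
})

test_that("swapping x and y inverts the SMA slope", {
  set.seed(21)
  x <- rnorm(40); y <- 1.7 * x + rnorm(40, sd = 0.4)
  d <- data.frame(x = x, y = y)
  b_xy <- sma_fit(d, x, y)$slope
  b_yx <- sma_fit(d, y, x)$slope
  expect_equal(b_yx, 1 / b_xy, tolerance = 1e-12)
})

test_that("SMA equals the standardized-PCA construction on random data", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, sd = runif(1, 0.2, 2))
    f <- sma_fit(data.frame(x = x, y = y), x, y)
    expect_equal(f$slope, sma_slope_pca(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate SMA inputs are rejected", {
  expect_error(sma_fit(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(sma_fit(data.frame(x = 1:2, y = 1:2), x, y), "at least 3")
})

test_that("identical groups give a null common-slope test", {
  set.seed(23)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.3)
  d <- data.frame(x = rep(x, 2), y = rep(y, 2),
                  g = rep(c("a", "b"), each = 30))
  res <- sma_group_test(d, x, y, g)
  expect_lt(res$slope_test$statistic, 1e-6)
  expect_gt(res$slope_test$p.value, 0.99)
  expect_gt(res$shift_test$p.value, 0.99)
  expect_gt(res$elevation_test$p.value, 0.99)
  expect_false(res$slope_forced)
})

test_that("clearly different slopes are detected with high power", {
  set.seed(24)
  rej <- replicate(60, {
    x1 <- rnorm(50); y1 <- 1 * x1 + rnorm(50, sd = 0.3)
    x2 <- rnorm(50); y2 <- 3 * x2 + rnorm(50, sd = 0.9)
    d <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = rep(c("a", "b"), each = 50))
    sma_group_test(d, x, y, g)$slope_test$p.value < 0.01
  })
  expect_gte(mean(rej), 0.9)
})

test_that("translation along the common line moves shift, not elevation", {
  set.seed(25)
  # population SMA slope of (x, x + e), e ~ N(0, 0.25^2), is sqrt(1.0625)
  b_pop <- sqrt(1 + 0.25^2)
  shift_hits <- 0; elev_hits <- 0
  for (i in 1:30) {
    x1 <- rnorm(60); y1 <- x1 + rnorm(60, sd = 0.25)
    d_along <- data.frame(
      x = c(x1, x1 + 3), y = c(y1, y1 + 3 * b_pop),
      g = rep(c("a", "b"), each = 60)
    )
    r1 <- sma_group_test(d_along, x, y, g)
    if (r1$shift_test$p.value < 0.05) shift_hits <- shift_hits + 1
    if (r1$elevation_test$p.value < 0.05) elev_hits <- elev_hits + 1
  }
  expect_gte(shift_hits, 28)    # translation along the line: shift fires
  expect_lte(elev_hits, 6)      # ... but elevation stays null
})

test_that("translation across the fitted axis moves elevation, not shift", {
  set.seed(26)
  b_pop <- sqrt(1 + 0.25^2)
  shift_hits <- 0; elev_hits <- 0
  for (i in 1:30) {
    x1 <- rnorm(60); y1 <- x1 + rnorm(60, sd = 0.25)
    # displacement with zero change in the fitted-axis score y + b x
    d_perp <- data.frame(
      x = c(x1, x1 + 1.5), y = c(y1, y1 - 1.5 * b_pop),
      g = rep(c("a", "b"), each = 60)
    )
    r2 <- sma_group_test(d_perp, x, y, g)
    if (r2$shift_test$p.value < 0.05) shift_hits <- shift_hits + 1
    if (r2$elevation_test$p.value < 0.05) elev_hits <- elev_hits + 1
  }
  expect_gte(elev_hits, 28)
  expect_lte(shift_hits, 6)
})

test_that("an intercept offset is flagged as an elevation difference", {
  set.seed(27)
  hits <- replicate(40, {
    x1 <- rnorm(50); y1 <- 2 * x1 + rnorm(50, sd = 0.3)
    x2 <- rnorm(50); y2 <- 2 * x2 + 5 + rnorm(50, sd = 0.3)
    d <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = rep(c("a", "b"), each = 50))
    sma_group_test(d, x, y, g)$elevation_test$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("SMA group tests are invariant to affine rescaling of the axes", {
  set.seed(28)
  x <- rnorm(90); g <- rep(c("a", "b", "c"), each = 30)
  y <- x + rnorm(90, sd = 0.4) + (g == "b") * 0.5
  d1 <- data.frame(x = x, y = y, g = g)
  d2 <- data.frame(x = 3 + 10 * x, y = -2 + 0.5 * y, g = g)
  r1 <- sma_group_test(d1, x, y, g)
  r2 <- sma_group_test(d2, x, y, g)
  expect_equal(r2$common_slope, r1$common_slope * 0.5 / 10, tolerance = 1e-5)
  expect_equal(r2$slope_test$p.value, r1$slope_test$p.value, tolerance = 1e-5)
  expect_equal(r2$shift_test$p.value, r1$shift_test$p.value, tolerance = 1e-4)
  expect_equal(r2$elevation_test$p.value, r1$elevation_test$p.value,
               tolerance = 1e-4)
})

test_that("tidy and glance summarise grouped SMA fits", {
  set.seed(29)
  d <- data.frame(x = rnorm(60), g = rep(c("a", "b"), each = 30))
  d$y <- 1.2 * d$x + rnorm(60, sd = 0.3)
  res <- sma_group_test(d, x, y, g)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_true(all(c("group", "slope", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_groups, 2)
  expect_true(is.finite(gl$shift_p) && is.finite(gl$elevation_p))
})

test_that("Tukey range test reduces to the pooled t-test for two groups", {
  set.seed(30)
  d <- data.frame(v = c(rnorm(12, 0), rnorm(15, 0.8)),
                  g = rep(c("a", "b"), c(12, 15)))
  tk <- tukey_pairwise(d, v, g)
  tt <- t.test(v ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey detects a single displaced group", {
  set.seed(31)
  d <- data.frame(v = c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 5)),
                  g = rep(c("a", "b", "c"), each = 10))
  tk <- tukey_pairwise(d, v, g)
  pc <- tk[tk$group1 == "c" | tk$group2 == "c", ]
  expect_true(all(pc$adj.p.value < 0.001))
  pab <- tk[tk$group1 != "c" & tk$group2 != "c", ]
  expect_true(all(pab$adj.p.value > 0.05))
  # three identical groups: all p ~ 1
  d2 <- data.frame(v = rep(rnorm(10), 3), g = rep(c("a", "b", "c"), each = 10))
  expect_true(all(tukey_pairwise(d2, v, g)$adj.p.value > 0.999))
  expect_error(tukey_pairwise(data.frame(v = 1:3, g = c("a", "a", "b")),
                              v, g), "fewer than 2")
})

test_that("breed x size ANOVA attributes variance to the right terms", {
  set.seed(32)
  d <- expand.grid(breed = c("A", "B", "C"), rep = 1:12,
                   size = c(0.3, 0.7, 1.7))
  # response depends on size only
  d$resp <- 2 * d$size + rnorm(nrow(d), sd = 0.2)
  an <- anova_breed_size(d, resp, breed, size)
  expect_lt(an$p.value[an$term == "size"], 1e-6)
  expect_gt(an$p.value[an$term == "breed:size"], 0.01)
  expect_error(anova_breed_size(dplyr::mutate(d, size = 1), resp, breed, size),
               "vary")
})

test_that("sequential ANOVA p-values are uniform under the null", {
  set.seed(36)
  d0 <- expand.grid(breed = c("A", "B", "C"), rep = 1:9,
                    size = c(0.3, 0.7, 1.7))
  ps <- replicate(300, {
    d0$resp <- rnorm(nrow(d0))
    an <- anova_breed_size(d0, resp, breed, size)
    an$p.value[an$term == "breed"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
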