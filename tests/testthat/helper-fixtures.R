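# shared fixtures and independent oracles, built in code at test time

# brute-force Camargo evenness by explicit pairwise enumeration
camargo_brute <- function(counts) {
  p <- counts / sum(counts)
  s <- length(p)
  1 - sum(abs(outer(p, p, "-"))[upper.tri(diag(s))]) / s
}

# direct Shannon-based Pielou evenness
pielou_brute <- function(p) {
  p <- p[p > 0]; p <- p / sum(p)
  -sum(p * log(p)) / log(length(p))
}

# SMA slope via the standardized-PCA construction: first principal axis of
# the z-scored variables, back-transformed to the original scale
sma_slope_pca <- function(x, y) {
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  ev <- eigen(cov(cbind(zx, zy)))$vectors[, 1]
  (ev[2] / ev[1]) * sd(y) / sd(x)
}

# hand-rolled Newton solver for the Poisson log-linear model
# log(mu) = b0 + b1 * z, used as an independent oracle for the IRLS fit
poisson_newton <- function(y, z, tol = 1e-12, maxit = 50) {
  b <- c(log(mean(y) + 0.1), 0)
  X <- cbind(1, z)
  for (i in seq_len(maxit)) {
    mu <- exp(X %*% b)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * as.vector(mu))
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  as.vector(b)
}

# square flat-DEM paddock with a single water point, for movement tests
flat_paddock <- function(side = 50, cell = 5, water = c(5, 5),
                         id = "pad1", pasture = "P1") {
  n <- side / cell
  dem <- list(z = matrix(0, n, n), xll = 0, yll = 0, cellsize = cell,
              nodata = -9999)
  paddock(id, pasture, cbind(c(0, side, side, 0), c(0, 0, side, side)),
          dem, matrix(water, ncol = 2))
}

# minimal two-species taxon table plus one group taxon
tiny_taxa <- function() {
  taxon_table(
    tibble::tibble(
      taxon_id = c("good_grass", "poor_shrub", "thistle_sp", "grass_group",
                   "grass_a", "grass_b"),
      kind = c("species", "species", "species", "group", "species", "species"),
      quality = c(8, 2, 2, NA, 8, 6),
      plant_group = c("broad_grass", "shrub", "thistle", "broad_grass",
                      "broad_grass", "broad_grass")
    ),
    tibble::tibble(
      group_id = "grass_group", member_id = c("grass_a", "grass_b"),
      pasture_id = "P1", abundance = c(0.75, 0.25)
    )
  )
}

# small cached synthetic study used by io/pipeline tests
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7, n_cows_per_breed = 3, track_hours = 1,
                        bites_per_bout = 120)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# square claw outline of a given area, as total_claw_base() input rows
square_outline <- function(cow_id, foot, claw, area) {
  s <- sqrt(area)
  tibble::tibble(cow_id = cow_id, foot = foot, claw = claw,
                 vertex_index = 1:4,
                 x_cm = c(0, s, s, 0), y_cm = c(0, 0, s, s))
}
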