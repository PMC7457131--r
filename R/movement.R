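# movement module: trajectory and pedometer summaries, 5 m grid occupancy,
# Camargo evenness of space use, habitat-covariate regressions

#' Speed and path length of a GPS track
#'
#' Sums Euclidean inter-fix distances and divides by the elapsed time.
#' Segments longer than `max_step_m`, or implying a speed above
#' `max_speed_kmh`, are treated as receiver error and dropped from the
#' distance (the elapsed time is kept, so the estimate is conservative).
#'
#' @param fixes A data frame with columns `timestamp` (seconds, strictly
#'   increasing), `x`, `y` (projected metres); >= 2 rows.
#' @param max_step_m Absolute segment-length cutoff in metres
#'   (default `Inf` = off).
#' @param max_speed_kmh Segment speed cutoff in km/h (default `Inf` = off);
#'   scales with the segment's time gap, so it also handles logging gaps.
#' @return A one-row tibble: `distance_m`, `elapsed_h`, `speed_m_h`,
#'   `n_segments`, `n_dropped`.
#' @export
track_speed <- function(fixes, max_step_m = Inf, max_speed_kmh = Inf) {
  check_cols(fixes, c("timestamp", "x", "y"), "fixes")
  if (nrow(fixes) < 2) abort_bad_arg("need at least 2 fixes.")
  t <- fixes$timestamp
  if (any(diff(t) <= 0)) {
    abort_bad_arg("timestamps must be strictly increasing.",
                  class = "grazemetry_validation_error")
  }
  dx <- diff(fixes$x); dy <- diff(fixes$y); dt <- diff(t)
  d <- sqrt(dx^2 + dy^2)
  speed_ms <- d / dt
  keep <- d <= max_step_m & speed_ms <= max_speed_kmh / 3.6
  elapsed_h <- (t[length(t)] - t[1]) / 3600
  tibble(
    distance_m = sum(d[keep]),
    elapsed_h = elapsed_h,
    speed_m_h = sum(d[keep]) / elapsed_h,
    n_segments = length(d),
    n_dropped = sum(!keep)
  )
}

#' Pedometer summary: step rate and lying ratio
#'
#' Duration-weighted aggregation of pedometer logging intervals into the
#' average number of steps per hour and the proportion of time spent lying.
#'
#' @param intervals A data frame with columns `duration_s`, `steps`,
#'   `lying_s` (0 <= lying_s <= duration_s).
#' @return A one-row tibble: `steps_per_h`, `lying_ratio`, `total_h`.
#' @export
pedometer_summary <- function(intervals) {
  check_cols(intervals, c("duration_s", "steps", "lying_s"), "intervals")
  if (any(intervals$lying_s < 0 | intervals$lying_s > intervals$duration_s)) {
    abort_bad_arg("`lying_s` must lie in [0, duration_s].",
                  class = "grazemetry_validation_error")
  }
  if (any(intervals$steps < 0)) abort_bad_arg("`steps` must be >= 0.")
  total_s <- sum(intervals$duration_s)
  if (total_s <= 0) abort_bad_arg("total duration must be positive.")
  tibble(
    steps_per_h = sum(intervals$steps) / (total_s / 3600),
    lying_ratio = sum(intervals$lying_s) / total_s,
    total_h = total_s / 3600
  )
}

#' Grid occupancy of GPS fixes in a paddock
#'
#' Counts fixes in half-open square cells (default 5 x 5 m) anchored at the
#' paddock bounding-box lower-left corner, and attaches per-cell percentage
#' slope (Horn finite differences on the paddock DEM) and Euclidean distance
#' to the nearest water point. Cells whose centre lies inside the boundary
#' form the paddock mask; fixes falling outside the mask are counted in
#' `n_outside` and reported, never dropped silently.
#'
#' @param fixes Data frame with columns `x`, `y` (projected metres).
#' @param pad A [paddock()] object.
#' @param cell_size Cell edge length in metres (default 5).
#' @return An `occupancy_grid` object; see [as_tibble.occupancy_grid()].
#' @export
rasterize_fixes <- function(fixes, pad, cell_size = 5) {
  stopifnot(inherits(pad, "paddock"))
  check_cols(fixes, c("x", "y"), "fixes")
  gs <- grid_spec(pad, cell_size)
  j <- floor((fixes$x - gs$x0) / cell_size) + 1
  i <- floor((fixes$y - gs$y0) / cell_size) + 1
  in_grid <- i >= 1 & i <= gs$ny & j >= 1 & j <= gs$nx
  in_mask <- in_grid
  in_mask[in_grid] <- gs$mask[cbind(i[in_grid], j[in_grid])]
  counts <- matrix(0L, gs$ny, gs$nx)
  if (any(in_mask)) {
    tab <- table(factor((j[in_mask] - 1) * gs$ny + i[in_mask],
                        levels = seq_len(gs$ny * gs$nx)))
    counts <- matrix(as.integer(tab), gs$ny, gs$nx)
  }
  slope_full <- slope_raster(pad$dem)
  slope_pct <- matrix(sample_raster(pad$dem, slope_full,
                                    as.vector(gs$centers_x),
                                    as.vector(gs$centers_y)),
                      gs$ny, gs$nx)
  wd <- water_distance_raster(pad, cell_size)
  structure(
    list(paddock_id = pad$paddock_id, cell_size = cell_size,
         x0 = gs$x0, y0 = gs$y0, nx = gs$nx, ny = gs$ny,
         counts = counts, mask = gs$mask,
         slope_pct = slope_pct, water_dist_m = wd,
         n_inside = sum(in_mask), n_outside = sum(!in_mask)),
    class = "occupancy_grid"
  )
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(
    "<occupancy_grid %s: %d x %d cells (%g m), %d fixes inside, %d outside>\n",
    x$paddock_id, x$nx, x$ny, x$cell_size, x$n_inside, x$n_outside))
  invisible(x)
}

#' Tidy view of an occupancy grid
#'
#' @param x An `occupancy_grid`.
#' @param ... Unused.
#' @return A tibble with one row per cell: centre coordinates, `count`,
#'   `slope_pct`, `water_dist_m`, `inside` (paddock mask).
#' @export
as_tibble.occupancy_grid <- function(x, ...) {
  cs <- x$cell_size
  tibble(
    cell_x = rep(x$x0 + (seq_len(x$nx) - 0.5) * cs, each = x$ny),
    cell_y = rep(x$y0 + (seq_len(x$ny) - 0.5) * cs, times = x$nx),
    count = as.vector(x$counts),
    slope_pct = as.vector(x$slope_pct),
    water_dist_m = as.vector(x$water_dist_m),
    inside = as.vector(x$mask)
  )
}

#' Percentage slope from a DEM (Horn's method)
#'
#' Eight-neighbour finite differences (Horn 1981) on a square-celled DEM,
#' reported as percent slope (100 * tan of the steepest-descent angle).
#' Edge cells use replicated-edge padding.
#'
#' @param dem A list with `z` (matrix, south row first) and `cellsize`.
#' @return A matrix of percent slope, same shape as `dem$z`.
#' @export
slope_raster <- function(dem) {
  z <- dem$z
  h <- dem$cellsize
  if (nrow(z) < 3 || ncol(z) < 3) abort_bad_arg("DEM must be at least 3 x 3.")
  # replicate-pad edges
  zp <- rbind(z[1, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, ncol(zp), drop = FALSE])
  nr <- nrow(z); nc <- ncol(z)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  nw <- zp[ri + 1, ci - 1]; n_ <- zp[ri + 1, ci]; ne <- zp[ri + 1, ci + 1]
  w_ <- zp[ri, ci - 1];                            e_ <- zp[ri, ci + 1]
  sw <- zp[ri - 1, ci - 1]; s_ <- zp[ri - 1, ci]; se <- zp[ri - 1, ci + 1]
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * h)
  dzdy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * h)
  100 * sqrt(dzdx^2 + dzdy^2)
}

#' Distance-to-water raster for a paddock grid
#'
#' Minimum Euclidean distance from each grid-cell centre to any water point.
#'
#' @param pad A [paddock()] object.
#' @param cell_size Cell edge length in metres.
#' @return A matrix aligned with the [rasterize_fixes()] grid.
#' @export
water_distance_raster <- function(pad, cell_size = 5) {
  stopifnot(inherits(pad, "paddock"))
  gs <- grid_spec(pad, cell_size)
  px <- as.vector(gs$centers_x); py <- as.vector(gs$centers_y)
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(pad$water))) {
    d <- pmin(d, sqrt((px - pad$water[k, 1])^2 + (py - pad$water[k, 2])^2))
  }
  matrix(d, gs$ny, gs$nx)
}

#' Standardized habitat-covariate effect on grid occupancy
#'
#' Regresses per-cell fix counts on a z-scored covariate with a log-linear
#' quasi-Poisson model (Poisson IRLS point estimates; standard errors
#' inflated by the estimated overdispersion), over the cells inside the
#' paddock mask. The z-scoring makes coefficients comparable across
#' paddocks and individuals. This is a deliberately simplified stand-in for
#' a latent-Gaussian spatial model: the spatially structured error term is
#' absorbed into the overdispersion factor.
#'
#' @param grid An `occupancy_grid`.
#' @param covariate `"slope"` or `"water"`.
#' @return A one-row tibble: `covariate`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `dispersion`, `n_cells`.
#' @export
covariate_effect <- function(grid, covariate = c("slope", "water")) {
  stopifnot(inherits(grid, "occupancy_grid"))
  covariate <- match.arg(covariate)
  m <- as.vector(grid$mask)
  if (sum(m) < 10) abort_bad_arg("need >= 10 cells inside the paddock mask.",
                                 class = "grazemetry_degenerate_error")
  y <- as.vector(grid$counts)[m]
  v <- switch(covariate,
              slope = as.vector(grid$slope_pct)[m],
              water = as.vector(grid$water_dist_m)[m])
  z <- zscore(v)
  fit <- glm(y ~ z, family = quasipoisson(link = "log"),
             control = list(maxit = 100, epsilon = 1e-12))
  if (!fit$converged) {
    abort_bad_arg("IRLS did not converge within 100 iterations.",
                  class = "grazemetry_degenerate_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients["z", ]
  tibble(
    covariate = covariate,
    estimate = unname(co[1]),
    std.error = unname(co[2]),
    statistic = unname(co[3]),
    p.value = unname(co[4]),
    dispersion = sm$dispersion,
    n_cells = sum(m)
  )
}

#' Per-cow movement metrics
#'
#' Combines GPS tracks, pedometer intervals and paddock geometry into one
#' row per cow x paddock: speed (m/h), steps per hour, lying ratio, Camargo
#' evenness of space use over all cells inside the paddock (zero-count
#' cells included), and standardized slope / water-distance coefficients.
#'
#' @param gps Data frame of fixes: `cow_id`, `paddock_id`, `timestamp`,
#'   `x`, `y`.
#' @param pedometer Data frame of intervals: `cow_id`, `paddock_id`,
#'   `duration_s`, `steps`, `lying_s`; may be `NULL` (step/lying columns
#'   come back `NA`, e.g. for cows without a pedometer).
#' @param paddocks Named list of [paddock()] objects, names = paddock ids.
#' @param cell_size Grid cell edge (m).
#' @param max_speed_kmh GPS error cutoff passed to [track_speed()]
#'   (default 10 km/h).
#' @return A tibble, one row per cow x paddock.
#' @export
movement_metrics <- function(gps, pedometer, paddocks, cell_size = 5,
                             max_speed_kmh = 10) {
  check_cols(gps, c("cow_id", "paddock_id", "timestamp", "x", "y"), "gps")
  if (!is.null(pedometer)) {
    check_cols(pedometer, c("cow_id", "paddock_id", "duration_s", "steps",
                            "lying_s"), "pedometer")
  }
  unknown <- setdiff(unique(gps$paddock_id), names(paddocks))
  if (length(unknown)) {
    abort_bad_arg(sprintf("GPS fixes reference unknown paddock(s): %s.",
                          paste(unknown, collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  gps |>
    group_by(.data$cow_id, .data$paddock_id) |>
    dplyr::group_modify(function(df, key) {
      pad <- paddocks[[key$paddock_id]]
      sp <- track_speed(df, max_speed_kmh = max_speed_kmh)
      grid <- rasterize_fixes(df, pad, cell_size)
      ev <- camargo_evenness(as.vector(grid$counts)[as.vector(grid$mask)])
      slope_fit <- covariate_effect(grid, "slope")
      water_fit <- covariate_effect(grid, "water")
      ped <- if (is.null(pedometer)) NULL else {
        pedometer |>
          filter(.data$cow_id == key$cow_id,
                 .data$paddock_id == key$paddock_id)
      }
      ped_sum <- if (!is.null(ped) && nrow(ped) > 0) pedometer_summary(ped) else {
        tibble(steps_per_h = NA_real_, lying_ratio = NA_real_, total_h = NA_real_)
      }
      tibble(
        speed_m_h = sp$speed_m_h,
        distance_m = sp$distance_m,
        steps_per_h = ped_sum$steps_per_h,
        lying_ratio = ped_sum$lying_ratio,
        camargo_evenness = ev,
        slope_coef = slope_fit$estimate,
        water_coef = water_fit$estimate,
        n_fixes = nrow(df),
        n_outside = grid$n_outside
      )
    }) |>
    ungroup()
}
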