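# standardized major axis (SMA) line fitting and multi-group inference:
# per-group fits, common-slope likelihood-ratio test, and Wald tests for
# shift along / elevation between allometric lines.
#
# Notation: for slope b, the "residual axis" score is r = y - b*x and the
# "fitted axis" score is f = y + b*x. At the SMA slope of a group these two
# scores are uncorrelated, which is what the profile likelihood below
# exploits (Warton-style errors-in-variables framework).

# ---- numeric kernels -------------------------------------------------------

sma_ab <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    abort_bad_arg("zero variance in x or y; SMA slope undefined.",
                  class = "grazemetry_degenerate_error")
  }
  r <- cor(x, y)
  sign_flag <- r == 0
  b <- if (sign_flag) sy / sx else sign(r) * sy / sx
  list(slope = b, intercept = mean(y) - b * mean(x), r = r,
       sign_undefined = sign_flag)
}

# Bartlett-corrected -2 log-likelihood contribution of all groups at slope b
sma_lr_profile <- function(groups, b) {
  s <- 0
  for (g in groups) {
    rho <- cor(g$y - b * g$x, g$y + b * g$x)
    s <- s + (length(g$x) - 2.5) * (-log(1 - rho^2))
  }
  s
}

sma_common_slope_fit <- function(groups) {
  bs <- vapply(groups, function(g) sma_ab(g$x, g$y)$slope, numeric(1))
  # the LR profile has twin minima at +/-|b|; fix the sign from the group
  # fits and search on the log magnitude, which is also scale-robust
  sign_b <- sign(sum(sign(bs)))
  if (sign_b == 0) sign_b <- sign(bs[1])
  opt <- optimize(function(u) sma_lr_profile(groups, sign_b * exp(u)),
                  interval = log(c(min(abs(bs)) / 8, max(abs(bs)) * 8)),
                  tol = 1e-10)
  b_c <- sign_b * exp(opt$minimum)
  # curvature of the profile -2logL gives the large-sample Var(b_c)
  h <- max(1e-6, abs(b_c) * 1e-5)
  d2 <- (sma_lr_profile(groups, b_c + h) +
           sma_lr_profile(groups, b_c - h) - 2 * opt$objective) / h^2
  list(b_c = b_c, lr = opt$objective,
       var_b = if (d2 > 0) 2 / d2 else NA_real_)
}

# Wald statistic for group differences in mean axis scores. `direction` is
# +1 for the fitted axis (shift along the line) and -1 for the residual
# axis (elevation). Per-group score variances use n - 2 degrees of freedom;
# uncertainty in the common slope enters through var_b and the group means
# of x (covariance x_i * x_j * var_b between group score means).
sma_axis_wald <- function(groups, b_c, var_b, direction) {
  g <- length(groups)
  n <- vapply(groups, function(gr) length(gr$x), numeric(1))
  xbar <- vapply(groups, function(gr) mean(gr$x), numeric(1))
  score_mean <- numeric(g); score_var <- numeric(g)
  for (i in seq_len(g)) {
    s <- groups[[i]]$y + direction * b_c * groups[[i]]$x
    score_mean[i] <- mean(s)
    score_var[i] <- sum((s - mean(s))^2) / (n[i] - 2)
  }
  V <- diag(score_var / n) + outer(xbar, xbar) * var_b
  L <- cbind(-1, diag(g - 1))
  d <- drop(L %*% score_mean)
  stat <- drop(t(d) %*% solve(L %*% V %*% t(L)) %*% d)
  # F reference with the pooled group-wise residual df (n_i - 2 each):
  # finite-sample analogue of the chi-squared Wald
  df2 <- sum(n - 2)
  list(statistic = stat, df = g - 1,
       p.value = pf(stat / (g - 1), g - 1, df2, lower.tail = FALSE))
}

# ---- user-facing fits ------------------------------------------------------

#' Fit a standardized major axis
#'
#' The SMA line minimizes residuals in both variables (both are treated as
#' measured with error, as is appropriate for allometric trait pairs):
#' slope b = sign(r) * s_y / s_x, intercept a = mean(y) - b * mean(x).
#' The slope confidence interval is the standard F-based interval
#' b * (sqrt(B + 1) +/- sqrt(B)) with
#' B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2).
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two traits.
#' @param alpha Confidence level for the slope interval (default 0.05 for
#'   a 95% CI).
#' @return An object of class `sma_fit` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' d <- data.frame(w = c(1, 2, 3), a = c(1, 2, 4))
#' sma_fit(d, w, a)
#' @export
sma_fit <- function(data, x, y, alpha = 0.05) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  sma_fit_xy(xv, yv, alpha = alpha,
             x_name = rlang::as_name(rlang::enquo(x)),
             y_name = rlang::as_name(rlang::enquo(y)))
}

# numeric-vector backend of sma_fit
sma_fit_xy <- function(xv, yv, alpha = 0.05, x_name = "x", y_name = "y") {
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort_bad_arg("SMA needs at least 3 complete observations.")
  ab <- sma_ab(xv, yv)
  r2 <- ab$r^2
  B <- qf(1 - alpha, 1, n - 2) * (1 - r2) / (n - 2)
  ci <- ab$slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  structure(
    list(n = n, slope = ab$slope, intercept = ab$intercept,
         r = ab$r, r_squared = r2,
         ci_lower = min(ci), ci_upper = max(ci), alpha = alpha,
         sign_undefined = ab$sign_undefined,
         x_name = x_name, y_name = y_name,
         data = tibble(x = xv, y = yv)),
    class = "sma_fit"
  )
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit: %s ~ %s (n = %d)\n", x$y_name, x$x_name, x$n))
  cat(sprintf("  slope     %8.4f  [%0.4f, %0.4f]\n",
              x$slope, x$ci_lower, x$ci_upper))
  cat(sprintf("  intercept %8.4f\n", x$intercept))
  cat(sprintf("  r^2       %8.4f\n", x$r_squared))
  if (x$sign_undefined) cat("  (r = 0: slope sign undefined)\n")
  invisible(x)
}

#' @rdname sma_fit
#' @param x An `sma_fit` object.
#' @param ... Unused.
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$ci_lower, NA_real_),
    conf.high = c(x$ci_upper, NA_real_)
  )
}

#' @rdname sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  tibble(n = x$n, r = x$r, r.squared = x$r_squared,
         slope = x$slope, intercept = x$intercept)
}

#' Multi-group SMA: common slope, shift and elevation tests
#'
#' Fits an SMA line per group, then tests whether the groups share a common
#' slope via a profile likelihood ratio (Bartlett-corrected group weights
#' n_i - 2.5, chi-squared with g - 1 df). Conditional on the common slope
#' b_c, two Wald tests compare the groups:
#'
#' * **shift** -- differences in the mean fitted-axis score y + b_c x,
#'   i.e. displacement of the point clouds *along* the common line;
#' * **elevation** -- differences in the mean residual-axis score
#'   y - b_c x, i.e. parallel offset *between* the lines.
#'
#' Both Wald tests use per-group score variances (n_i - 2 df) plus the
#' common-slope sampling variance, and are reported even when the common
#' slope is rejected, flagged via `slope_forced` (the common slope is then
#' a forced compromise, as when allometric lines of different slope are
#' still compared at a forced common slope).
#'
#' @param data A data frame in long form.
#' @param x,y Unquoted trait columns.
#' @param group Unquoted grouping column (>= 2 groups, each n >= 3).
#' @param alpha_common Significance level above which the common slope is
#'   considered tenable (default 0.05).
#' @return An object of class `sma_group` with [tidy()], [glance()] and
#'   [autoplot()] methods. Fields include `fits` (per-group [sma_fit()]s),
#'   `common_slope`, `slope_test`, `shift_test`, `elevation_test`.
#' @export
sma_group_test <- function(data, x, y, group, alpha_common = 0.05) {
  gv <- as.character(dplyr::pull(data, {{ group }}))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- complete.cases(xv, yv, gv)
  d <- tibble(x = xv[ok], y = yv[ok], g = gv[ok])
  labels <- unique(d$g)
  if (length(labels) < 2) abort_bad_arg("need at least 2 groups.")
  groups <- lapply(labels, function(l) {
    sub <- d[d$g == l, ]
    if (nrow(sub) < 3) {
      abort_bad_arg(sprintf("group '%s' has fewer than 3 observations.", l),
                    class = "grazemetry_degenerate_error")
    }
    list(x = sub$x, y = sub$y)
  })
  names(groups) <- labels
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  fits <- lapply(labels, function(l) {
    sma_fit_xy(groups[[l]]$x, groups[[l]]$y, x_name = x_name, y_name = y_name)
  })
  names(fits) <- labels
  cs <- sma_common_slope_fit(groups)
  slope_test <- list(statistic = cs$lr, df = length(groups) - 1,
                     p.value = pchisq(cs$lr, length(groups) - 1,
                                      lower.tail = FALSE))
  shift <- sma_axis_wald(groups, cs$b_c, cs$var_b, direction = +1)
  elev <- sma_axis_wald(groups, cs$b_c, cs$var_b, direction = -1)
  structure(
    list(labels = labels, groups = groups, fits = fits,
         common_slope = cs$b_c, common_slope_var = cs$var_b,
         slope_test = slope_test, shift_test = shift, elevation_test = elev,
         slope_forced = slope_test$p.value < alpha_common,
         alpha_common = alpha_common,
         x_name = x_name, y_name = y_name),
    class = "sma_group"
  )
}

#' @export
print.sma_group <- function(x, ...) {
  cat(sprintf("Grouped SMA: %s ~ %s, %d groups (%s)\n",
              x$y_name, x$x_name, length(x$labels),
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  common slope b_c = %.4f%s\n", x$common_slope,
              if (x$slope_forced) "  [forced: slopes differ]" else ""))
  cat(sprintf("  %-10s LR(%d)   = %8.3f, p = %.4g\n", "slope",
              x$slope_test$df, x$slope_test$statistic,
              x$slope_test$p.value))
  fmt <- function(t, lab) {
    cat(sprintf("  %-10s Wald(%d) = %8.3f, p = %.4g\n",
                lab, t$df, t$statistic, t$p.value))
  }
  fmt(x$shift_test, "shift")
  fmt(x$elevation_test, "elevation")
  invisible(x)
}

#' @rdname sma_group_test
#' @param x An `sma_group` object.
#' @param ... Unused.
#' @export
tidy.sma_group <- function(x, ...) {
  purrr::map2_dfr(x$fits, names(x$fits), function(f, l) {
    tibble(group = l, n = f$n, slope = f$slope, intercept = f$intercept,
           r.squared = f$r_squared,
           conf.low = f$ci_lower, conf.high = f$ci_upper)
  })
}

#' @rdname sma_group_test
#' @export
glance.sma_group <- function(x, ...) {
  tibble(
    n_groups = length(x$labels),
    common_slope = x$common_slope,
    slope_statistic = x$slope_test$statistic,
    slope_p = x$slope_test$p.value,
    shift_statistic = x$shift_test$statistic,
    shift_p = x$shift_test$p.value,
    elevation_statistic = x$elevation_test$statistic,
    elevation_p = x$elevation_test$p.value,
    slope_forced = x$slope_forced
  )
}
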