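# ggplot2 visualisations for the main result types

#' @export
autoplot.sma_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      title = sprintf("SMA: %s ~ %s", object$y_name, object$x_name),
      subtitle = sprintf("slope = %.3f, r² = %.2f",
                         object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sma_group <- function(object, ...) {
  d <- purrr::map2_dfr(object$fits, names(object$fits), function(f, l) {
    mutate(f$data, group = l)
  })
  lines <- tidy(object)
  # common-slope lines through each group's centroid
  centroids <- d |>
    group_by(.data$group) |>
    summarise(mx = mean(.data$x), my = mean(.data$y), .groups = "drop") |>
    mutate(slope = object$common_slope,
           intercept = .data$my - object$common_slope * .data$mx)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group),
      linetype = "dashed"
    ) +
    ggplot2::geom_abline(
      data = centroids,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group)
    ) +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      title = sprintf("Grouped SMA: %s ~ %s", object$y_name, object$x_name),
      subtitle = sprintf(
        "common slope %.3f | slope p = %.3g, shift p = %.3g, elevation p = %.3g",
        object$common_slope, object$slope_test$p.value,
        object$shift_test$p.value, object$elevation_test$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occupancy_grid <- function(object, ...) {
  d <- as_tibble(object) |> filter(.data$inside)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_x, y = .data$cell_y,
                                  fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "fixes",
                  title = sprintf("Occupancy, paddock %s (%g m cells)",
                                  object$paddock_id, object$cell_size)) +
    ggplot2::theme_minimal()
}

#' Boxplots of a per-cow variable by breed
#'
#' @param report A `study_report`.
#' @param variable Unquoted column of the cow-means table.
#' @return A ggplot object.
#' @export
plot_breed_metric <- function(report, variable) {
  stopifnot(inherits(report, "study_report"))
  v <- rlang::enquo(variable)
  ggplot2::ggplot(report$cow_means,
                  ggplot2::aes(x = .data$breed, y = !!v,
                               fill = .data$breed)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "breed", y = rlang::as_name(v)) +
    ggplot2::theme_minimal()
}
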