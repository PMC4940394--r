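# ggplot2 visualizations of design-space slices, trajectory classes,
# basins and trajectories.

#' Plot a classified design-space slice
#'
#' @param slice result of [classify_slice()].
#' @return a ggplot object (log-log raster of case-set labels).
#' @export
plot_slice <- function(slice) {
  ggplot2::ggplot(slice[!is.na(slice$label) & slice$label != "", ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(fill = "cases") +
    ggplot2::theme_minimal()
}

#' Plot the positive-eigenvalue count across a slice
#'
#' @param slice result of [positive_roots_slice()].
#' @return a ggplot object.
#' @export
plot_positive_roots <- function(slice) {
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = factor(.data$positive_roots))) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(fill = "positive roots") +
    ggplot2::theme_minimal()
}

#' Plot state-space trajectory classes
#'
#' @param classes result of [trajectory_classes()].
#' @param fixed_points optional [find_fixed_points()] result to overlay.
#' @return a ggplot object.
#' @export
plot_trajectory_classes <- function(classes, fixed_points = NULL) {
  p <- ggplot2::ggplot(classes, ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(NE = "#5778a4", NW = "#e49444",
                                          SE = "#6a9f58", SW = "#85609c")) +
    ggplot2::theme_minimal()
  if (!is.null(fixed_points) && nrow(fixed_points)) {
    xy <- names(fixed_points)[1:2]
    p <- p + ggplot2::geom_point(
      data = fixed_points,
      ggplot2::aes(x = .data[[xy[1]]], y = .data[[xy[2]]],
                   shape = .data$stable),
      inherit.aes = FALSE, size = 2
    ) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1))
  }
  p
}

#' Plot basins of attraction
#'
#' @param basin_grid result of [basins()].
#' @return a ggplot object.
#' @export
plot_basins <- function(basin_grid) {
  ggplot2::ggplot(basin_grid, ggplot2::aes(x = .data$x, y = .data$y,
                                           fill = factor(.data$attractor))) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(fill = "attractor") +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' @param trajectory result of [simulate_gma()].
#' @param vars variables to show (default: all).
#' @return a ggplot object (log concentration vs time).
#' @export
plot_trajectory <- function(trajectory, vars = NULL) {
  vars <- vars %||% setdiff(names(trajectory), "time")
  long <- do.call(rbind, lapply(vars, function(v) {
    tibble::tibble(time = trajectory$time, variable = v, value = trajectory[[v]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}
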