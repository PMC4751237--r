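#' Stability chart of the characteristic equation
#'
#' Draws the D-partition of the \eqn{(\alpha_1,\alpha_2)}-plane for a given
#' \eqn{\alpha_3}: the boundary curves L, C0 and \eqn{C_k^\pm}, optionally a
#' shaded classification grid with per-cell unstable-root counts.
#'
#' @inheritParams build_all_curves
#' @param grid optional [classify_grid()] tibble (with an `n_unstable`
#'   column) to shade.
#' @param window plotting window `c(xmin, xmax, ymin, ymax)`.
#' @return a ggplot object.
#' @export
plot_region <- function(alpha3, grid = NULL, k_max = 3,
                        window = c(-8, 8, -8, 8)) {
  curves <- build_all_curves(alpha3, k_max = k_max,
                             alpha1_range = window[1:2] + c(-1, 1))
  p <- ggplot2::ggplot()
  if (!is.null(grid) && "n_unstable" %in% names(grid)) {
    p <- p + ggplot2::geom_tile(
      data = grid,
      ggplot2::aes(x = .data$alpha1, y = .data$alpha2,
                   fill = factor(.data$n_unstable)),
      alpha = 0.6
    ) +
      ggplot2::scale_fill_viridis_d(name = "unstable roots")
  }
  p +
    ggplot2::geom_path(
      data = curves,
      ggplot2::aes(x = .data$alpha1, y = .data$alpha2,
                   group = interaction(.data$branch, .data$k),
                   colour = .data$branch)
    ) +
    ggplot2::annotate("point", x = 1 - alpha3, y = alpha3 - 1, shape = 21,
                      fill = "white") +
    ggplot2::coord_cartesian(xlim = window[1:2], ylim = window[3:4]) +
    ggplot2::labs(
      x = expression(alpha[1]), y = expression(alpha[2]),
      title = bquote("Stability chart," ~ alpha[3] == .(round(alpha3, 4)))
    ) +
    ggplot2::theme_minimal()
}

#' Fig-style chart of a mapped stability boundary
#'
#' Plots [map_to_model_plane()] images (C0 boundary and, typically, the
#' C1_plus curve inside the unstable region) in the (steepness, theta) plane.
#'
#' @param mapped one or more mapped-curve tibbles, row-bound.
#' @param slope_max clip for the steepness axis.
#' @return a ggplot object.
#' @export
plot_model_plane <- function(mapped, slope_max = NULL) {
  dat <- dplyr::filter(mapped, .data$in_range, .data$slope > 0)
  if (!is.null(slope_max)) dat <- dplyr::filter(dat, .data$slope <= slope_max)
  lab <- if (all(dat$case == "beta1_regulated")) {
    expression(beta[1] * minute(bar(E)))
  } else {
    expression(G * minute(bar(E)))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slope, y = .data$theta,
                                    colour = .data$source_branch)) +
    ggplot2::geom_path() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = lab, y = expression(theta),
                  colour = "boundary") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_trajectory
autoplot.trajectory <- function(object, ...) plot_trajectory(object, ...)

#' Plot a simulated trajectory
#'
#' Time series of p, Q and E from [integrate_model()], facetted by variable.
#'
#' @param object,traj a `trajectory` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
plot_trajectory <- function(traj, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(traj), c("p", "Q", "E"),
                              names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (cell-cycle units)", y = NULL) +
    ggplot2::theme_minimal()
}
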