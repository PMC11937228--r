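# ggplot2 display methods for the main result types.

#' Plot marginal increment density profiles
#'
#' @param object A `vj_density_profile` from [density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vj_density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dy, y = .data$density,
                                       colour = factor(.data$order))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * y), y = "density",
                  colour = "up-to-m switches") +
    ggplot2::theme_minimal()
}

#' Plot filtered hidden-state probabilities along a track
#'
#' @param object A `vj_filter` from [forward_filter()].
#' @param ... Unused.
#' @return A ggplot of `P(state at interval start | past increments)`.
#' @export
autoplot.vj_filter <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$interval, y = .data$prob,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "interval", y = "filtered state probability") +
    ggplot2::theme_minimal()
}

#' Plot an approximation/empirical comparison
#'
#' @param comparison Result of [compare_marginal()].
#' @return A ggplot overlaying the empirical histogram density and the
#'   analytic approximations.
#' @export
plot_marginal_comparison <- function(comparison) {
  grid <- comparison$grid
  long <- tidyr::pivot_longer(grid, -"dy", names_to = "which",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dy, y = .data$density,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * y), y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a joint two-increment density surface
#'
#' @param surface Tibble from [joint_pair_density()].
#' @param which Column to show (`"joint"` or `"product"`).
#' @return A ggplot raster on a log colour scale.
#' @export
plot_joint_density <- function(surface, which = c("joint", "product")) {
  which <- match.arg(which)
  ggplot2::ggplot(surface,
                  ggplot2::aes(x = .data$dy2, y = .data$dy1,
                               fill = log10(.data[[which]] + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] * " density")) +
    ggplot2::labs(x = expression(Delta * y[2]), y = expression(Delta * y[1])) +
    ggplot2::theme_minimal()
}
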