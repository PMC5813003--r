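#' Plot a free-energy profile
#'
#' @param object An `fe_profile`.
#' @param ... Unused.
#' @return A ggplot: F(z) with an uncertainty ribbon where available.
#' @export
autoplot.fe_profile <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$F)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "z (Å)",
                  y = expression(F ~ (k[B] * T)),
                  title = paste0("Free-energy profile (",
                                 attr(object, "source"), ")")) +
    ggplot2::theme_minimal()
  if (!all(is.na(d$se)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$F - .data$se, ymax = .data$F + .data$se),
      alpha = 0.25, na.rm = TRUE)
  p
}

#' Plot a 2D free-energy map
#'
#' @param object An `fe_map` from [density_free_energy_2d()].
#' @param ... Unused.
#' @return A ggplot raster of F(z, d_xy).
#' @export
autoplot.fe_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$z, y = .data$d_xy,
                               fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = expression(F ~ (k[B] * T))) +
    ggplot2::labs(x = "z (Å)", y = expression(d[xy] ~ ("Å"))) +
    ggplot2::theme_minimal()
}

#' Plot the collective permeation coordinate
#'
#' @param object A `net_permeation` series.
#' @param ... Unused.
#' @return A ggplot of n(t) per monomer.
#' @export
autoplot.net_permeation <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time / 1000, y = .data$n,
                               colour = factor(.data$monomer))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "n(t)", colour = "monomer") +
    ggplot2::theme_minimal()
}

#' Plot a classified gate series
#'
#' @param x The result of [classify_gate()].
#' @param ... Unused.
#' @return A ggplot of the dihedral series coloured by state.
#' @export
plot_gate_states <- function(x, ...) {
  stopifnot(is.list(x), "states" %in% names(x))
  ggplot2::ggplot(x$states,
                  ggplot2::aes(x = .data$time, y = .data$angle,
                               colour = .data$state)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "time", y = "dihedral (deg)") +
    ggplot2::theme_minimal()
}
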