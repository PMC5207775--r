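#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the time evolution of an aster simulation
#'
#' Growing plus-end density profiles at each snapshot, colored by time; a
#' stationary aster collapses onto a single confined profile, a traveling wave
#' shows equally spaced shape-invariant fronts.
#'
#' @param object An `aster_sim` from [simulate_aster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aster_sim
#' @export
autoplot.aster_sim <- function(object, ...) {
  ggplot2::ggplot(object$snapshots,
                  ggplot2::aes(x = .data$x, y = .data$density,
                               colour = .data$t, group = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from centrosome (um)",
      y = "growing plus-end density (1/um)",
      colour = "time (min)",
      title = sprintf("%s (front velocity %.2g um/min)",
                      gsub("_", " ", object$regime),
                      object$velocity$velocity)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted front-position trace
#'
#' Front (or radius) positions against time with the fitted velocity line.
#'
#' @param object A `front_fit` from [velocity_from_radii()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot front_fit
#' @export
autoplot.front_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$radius)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "time (min)", y = "aster radius (um)",
                  title = sprintf("V = %.3g um/min (RMSE %.2g um)",
                                  object$velocity, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Phase-diagram curve of aster velocity against nucleation rate
#'
#' The analytic aster velocity over the validity window `(rc, fcat)`, showing
#' the explosive onset at `Vgap`: the velocity jumps discontinuously from 0 to
#' `Vgap` at the critical nucleation rate.
#'
#' @param params A [dynamics_params()] object with `J < 0`.
#' @param n Number of rate values sampled across the window.
#' @return A ggplot object.
#' @export
plot_velocity_curve <- function(params, n = 200) {
  p <- as_dynamics_params(params)
  rc <- critical_nucleation_rate(p)
  r <- seq(rc, p$fcat, length.out = n + 2L)[2:(n + 1L)]
  df <- tibble::tibble(r = r, V = aster_velocity(p, r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$V)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::tibble(r = rc, V = gap_velocity(p)),
                        shape = 1) +
    ggplot2::geom_segment(
      data = tibble::tibble(r = rc, V = gap_velocity(p)),
      ggplot2::aes(xend = .data$r, yend = 0), linetype = "dotted") +
    ggplot2::labs(x = "nucleation rate r (1/min)",
                  y = "aster velocity V (um/min)",
                  title = sprintf("explosive onset: Vgap = %.3g um/min at rc = %.3g /min",
                                  gap_velocity(p), rc)) +
    ggplot2::theme_minimal()
}
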