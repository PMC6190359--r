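# ggplot2 quick-look plots for the tabular result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_path
#'   geom_point geom_hline geom_vline labs scale_fill_viridis_c facet_wrap
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a force-versus-size curve
#'
#' Lines for the small-particle, closed-form finite-size and quadrature
#' forces against \eqn{D_p/\lambda}.
#'
#' @param object A [force_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("ratio", "f_small", "f_closed", "f_quad")],
    cols = c("f_small", "f_closed", "f_quad"),
    names_to = "model", values_to = "force"
  )
  ggplot(long, aes(x = .data$ratio, y = .data$force,
                   colour = .data$model)) +
    geom_line() +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = expression(D[p] / lambda), y = "force (N)",
         colour = NULL) +
    theme_minimal()
}

#' Plot a force map
#'
#' Raster of the force magnitude over the sampled grid.
#'
#' @param object A [force_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_grid <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y,
                                fill = .data$f_mag)) +
    geom_raster() +
    scale_fill_viridis_c(name = "|F| (N)") +
    labs(x = "x (m)", y = "y (m)",
         title = attr(object, "model")) +
    theme_minimal()
}

#' Plot a trajectory
#'
#' @param object An [advance_trajectory()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y)) +
    geom_path() +
    geom_point(data = as_tibble(object)[1, ], colour = "red") +
    labs(x = "x (m)", y = "y (m)", title = attr(object, "model")) +
    theme_minimal()
}

#' Plot separation outcomes
#'
#' Final lateral positions per model with the outlet cut lines.
#'
#' @param object A [simulate_separation()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.separation_report <- function(object, ...) {
  ggplot(object$assignments,
         aes(x = .data$model, y = .data$final_y,
             colour = .data$outlet, shape = .data$particle)) +
    geom_point(size = 3) +
    geom_hline(yintercept = object$channel$cuts, linetype = 2) +
    labs(x = NULL, y = "final lateral position (m)") +
    theme_minimal()
}

#' @rdname force_curve
#' @param x A `force_curve` object.
#' @param ... Unused.
#' @export
tidy.force_curve <- function(x, ...) {
  as_tibble(x)[, c("ratio", "chi", "f_small", "f_closed", "f_quad", "f_m")]
}

#' @rdname force_curve
#' @export
glance.force_curve <- function(x, ...) {
  tibble(
    wavelength = attr(x, "wavelength"),
    peak_pressure = attr(x, "peak_pressure"),
    h = attr(x, "h"),
    n_ratios = nrow(x),
    difference_closed_quad = attr(x, "difference_closed_quad"),
    zero_crossing_ratio = zero_crossing_ratio()
  )
}
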