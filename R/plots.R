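#' Plot sampled chains
#'
#' Draws the planar paths of (a subset of) a chain ensemble.
#'
#' @param object A `wlc_ensemble` tibble from [sample_wlc2d()] or
#'   [sample_arcarc()].
#' @param max_chains Plot at most this many chains (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wlc_ensemble <- function(object, max_chains = 20, ...) {
  ids <- unique(object$chain_id)
  sub <- dplyr::filter(object, .data$chain_id %in% ids[seq_len(min(max_chains, length(ids)))])
  ggplot2::ggplot(sub, ggplot2::aes(.data$x, .data$y,
                                    group = .data$chain_id,
                                    colour = factor(.data$chain_id))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' Plot a deflection-angle distribution
#'
#' @param object A [deflection_pdf()] result.
#' @param ... Unused.
#' @return A ggplot object; unsmoothed edge atoms are marked by vertical
#'   lines at `+/- omega S`.
#' @export
autoplot.deflection_distribution <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$theta, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = expression(P(theta)))
  if (!attr(object, "with_flexure")) {
    tm <- attr(object, "theta_max")
    p <- p + ggplot2::geom_vline(xintercept = c(-tm, tm), linetype = 2)
  }
  p
}

#' Plot a persistence-length fit
#'
#' Ensemble correlation on a log scale with the fitted window shaded.
#'
#' @param object A `plfit` from [estimate_persistence_length()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plfit <- function(object, ...) {
  p <- ggplot2::ggplot(object$correlation, ggplot2::aes(.data$s, .data$C)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "s", y = "C(s)")
  if (!is.null(object$window)) {
    p <- p + ggplot2::annotate("rect", xmin = object$window[1],
                               xmax = object$window[2], ymin = 0, ymax = Inf,
                               alpha = 0.15)
  }
  p
}

#' Plot a reconstructed filament shape
#'
#' @param shape A tibble from [reconstruct_shape()].
#' @return A ggplot object with equal coordinates.
#' @export
plot_shape <- function(shape) {
  ggplot2::ggplot(shape, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' Plot a polymorphic phase diagram
#'
#' Tiles the `(f, m)` grid by the minimum-energy state.
#'
#' @param pd A tibble from [phase_diagram()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(pd) {
  ggplot2::ggplot(pd, ggplot2::aes(.data$f, .data$m, fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "generalised force f", y = "generalised torque m",
                  fill = "state")
}
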