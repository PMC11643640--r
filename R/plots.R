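# ggplot2 display methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trace
#'
#' @param object A `kndy_trace`.
#' @param ... Unused.
#' @return A ggplot: membrane potential (or clamp current) over time.
#' @export
autoplot.kndy_trace <- function(object, ...) {
  if (identical(attr(object, "mode"), "voltage")) {
    ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$total)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "clamp current (pA)")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$vm_mV)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)")
  }
}

#' Plot an I-V curve
#'
#' @param object A `kndy_ivcurve`.
#' @param ... Unused.
#' @return A ggplot of current (density) against command voltage.
#' @export
autoplot.kndy_ivcurve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$voltage_mV, .data$current)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "command voltage (mV)",
                  y = paste0("current (", attr(object, "units"), ")"))
}

#' Plot an F-I curve
#'
#' @param object A `kndy_fi`.
#' @param ... Unused.
#' @return A ggplot of firing rate against injected current.
#' @export
autoplot.kndy_fi <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$level_pA, .data$rate_Hz)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)")
}

#' Plot a regime grid
#'
#' @param object A `kndy_regime_grid`.
#' @param boundary Optional `kndy_boundary` overlay.
#' @param ... Unused.
#' @return A ggplot tile map of firing-regime labels over the two
#'   conductance axes (log scales).
#' @export
autoplot.kndy_regime_grid <- function(object, boundary = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                            fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0(attr(object, "x_param"), " (nS)"),
                  y = paste0(attr(object, "y_param"), " (nS)"),
                  fill = "firing mode")
  if (!is.null(boundary)) {
    p <- p + ggplot2::geom_path(
      data = boundary, ggplot2::aes(.data$x, .data$y),
      inherit.aes = FALSE, linewidth = 0.8)
  }
  p
}

#' Plot a Boltzmann fit
#'
#' @param object A `kndy_boltzmann`.
#' @param ... Unused.
#' @return A ggplot of the data and fitted sigmoid.
#' @export
autoplot.kndy_boltzmann <- function(object, ...) {
  vg <- seq(min(object$data$voltage_mV), max(object$data$voltage_mV),
            length.out = 200)
  fit <- tibble::tibble(
    voltage_mV = vg,
    response = 1 / (1 + exp((object$v_half - vg) / object$slope_k))
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$voltage_mV, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit) +
    ggplot2::labs(x = "voltage (mV)", y = "normalized response")
}
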