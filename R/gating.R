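# Hodgkin-Huxley gating kinetics: Boltzmann steady states and first-order
# relaxation with constant or bell-shaped voltage-dependent time constants.

#' Define a gating variable
#'
#' A gating variable is described by a Boltzmann steady-state curve
#' \eqn{x_\infty(V) = floor + (1 - floor) / (1 + \exp((V_{1/2} - V)/k))}
#' and a time constant that is either constant (`tau_amp = 0`) or bell-shaped,
#' \eqn{\tau(V) = \tau_{min} + \tau_{amp} / \cosh((V - \tau_{vh})/\tau_k)}.
#' A positive slope `slope_k` gives a gate that opens with depolarization
#' (activation); a negative slope gives inactivation. `floor` is the
#' non-(in)activating residual fraction.
#'
#' @param name Label.
#' @param v_half Midpoint (mV).
#' @param slope_k Signed slope factor (mV).
#' @param exponent Integer power the gate enters the current with (>= 1).
#' @param floor Residual open fraction in `[0, 1)`.
#' @param tau_min,tau_amp,tau_vh,tau_k Time-constant model (ms, ms, mV, mV).
#' @return A `kndy_gating_spec` object.
#' @examples
#' sp <- gating_spec("m", v_half = -50, slope_k = 5)
#' steady_state_gate(-40, sp)
#' @export
gating_spec <- function(name, v_half, slope_k, exponent = 1, floor = 0,
                        tau_min = 1, tau_amp = 0, tau_vh = -50, tau_k = 15) {
  if (exponent < 1) stop("exponent must be >= 1", call. = FALSE)
  if (slope_k == 0) stop("slope_k must be nonzero", call. = FALSE)
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)", call. = FALSE)
  spec <- list(
    name = name, v_half = v_half, slope_k = slope_k,
    exponent = as.integer(round(exponent)), floor = floor,
    tau_min = tau_min, tau_amp = tau_amp, tau_vh = tau_vh, tau_k = tau_k
  )
  if (any(gate_tau(seq(-120, 60, by = 2), spec) <= 0)) {
    stop("tau(V) must be > 0 over [-120, 60] mV", call. = FALSE)
  }
  structure(spec, class = "kndy_gating_spec")
}

gating_spec_from_params <- function(params, gate) {
  v <- unclass(params)
  f <- function(field) v[[paste0(gate, "_", field)]]
  structure(list(
    name = gate, v_half = f("vh"), slope_k = f("k"),
    exponent = as.integer(f("exp")), floor = f("floor"),
    tau_min = f("tau_min"), tau_amp = f("tau_amp"),
    tau_vh = f("tau_vh"), tau_k = f("tau_k")
  ), class = "kndy_gating_spec")
}

#' Gating table for a parameter set
#'
#' @param params A [kndy_params] object.
#' @return A tibble with one row per gating variable and its Boltzmann /
#'   time-constant parameters.
#' @export
gating_table <- function(params) {
  stopifnot(inherits(params, "kndy_params"))
  purrr::map_dfr(.kndy_gates, function(g) {
    sp <- gating_spec_from_params(params, g)
    tibble::as_tibble(unclass(sp))
  })
}

#' Boltzmann steady-state open fraction
#'
#' @param V Membrane potential (mV); vectorized.
#' @param spec A [gating_spec()].
#' @return `x_inf(V)`, in `(0, 1)`.
#' @examples
#' sp <- gating_spec("mCa", v_half = -32.3, slope_k = 10)
#' steady_state_gate(-32.3, sp) # 0.5
#' @export
steady_state_gate <- function(V, spec) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  spec$floor + (1 - spec$floor) / (1 + exp((spec$v_half - V) / spec$slope_k))
}

#' Gating time constant
#'
#' @inheritParams steady_state_gate
#' @return `tau(V)` in ms.
#' @export
gate_tau <- function(V, spec) {
  spec$tau_min + spec$tau_amp / cosh((V - spec$tau_vh) / spec$tau_k)
}

#' First-order gate relaxation rate
#'
#' `dx/dt = (x_inf(V) - x) / tau(V)`; zero exactly at the fixed point.
#'
#' @param x Current open fraction in `[0, 1]`.
#' @inheritParams steady_state_gate
#' @return Rate in 1/ms.
#' @export
gate_derivative <- function(x, V, spec) {
  if (any(x < 0 | x > 1)) stop("gate value outside [0, 1]", call. = FALSE)
  tau <- gate_tau(V, spec)
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  (steady_state_gate(V, spec) - x) / tau
}
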