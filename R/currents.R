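# Ionic currents of the KNDy neuron model. Sign convention: outward currents
# are positive; 1 nS x 1 mV = 1 pA. This file is the reference (pure-R)
# implementation; the compiled right-hand side in src/ mirrors it and the two
# are cross-checked in the test suite.

#' Ohmic current through a (partially) open conductance
#'
#' @param g Maximal conductance (nS), `>= 0`.
#' @param open_fraction Open probability in `[0, 1]` (product of gates).
#' @param V Membrane potential (mV).
#' @param E_rev Reversal potential (mV).
#' @return Current in pA, outward positive.
#' @examples
#' ohmic_current(28.1, 1, 40, -90) # 3653 pA
#' @export
ohmic_current <- function(g, open_fraction, V, E_rev) {
  if (any(g < 0)) stop("conductance must be >= 0", call. = FALSE)
  if (any(!is.finite(V)) || any(!is.finite(E_rev))) {
    stop("V and E_rev must be finite", call. = FALSE)
  }
  g * open_fraction * (V - E_rev)
}

.hill <- function(x, K, n) {
  xn <- pmax(x, 0)^n
  xn / (xn + K^n)
}

#' SK channel open fraction
#'
#' Voltage-independent Hill activation by cytosolic calcium with half-maximal
#' activation at `K_SK` (default 0.3 uM).
#'
#' @param Ca_i Cytosolic calcium (uM), `> 0`.
#' @param K_SK Half-activation (uM).
#' @param n_SK Hill coefficient.
#' @return Open fraction in `[0, 1)`.
#' @examples
#' sk_open_fraction(0.3) # 0.5
#' @export
sk_open_fraction <- function(Ca_i, K_SK = 0.3, n_SK = 2) {
  if (K_SK <= 0) stop("K_SK must be > 0", call. = FALSE)
  .hill(Ca_i, K_SK, n_SK)
}

# BK voltage gate midpoint, shifted leftward as calcium rises above rest
# (bk_ca_shift mV per decade, negative).
bk_v_half_eff <- function(params, Ca_i) {
  v <- unclass(params)
  ca <- pmax(Ca_i, 1e-4)
  v[["bBK_vh"]] + v[["bk_ca_shift"]] * log10(ca / v[["Ca_rest"]])
}

# TRPC5 open fraction: receptor drive (with basal openness c_base) times
# calcium facilitation.
trpc5_open_fraction <- function(Ca_i, a_NKB, params) {
  v <- unclass(params)
  drive <- v[["c_base"]] + (1 - v[["c_base"]]) * a_NKB
  drive * .hill(Ca_i, v[["K_TRPC5_Ca"]], v[["n_TRPC5"]])
}

#' TRPC5 current
#'
#' Calcium-facilitated, receptor-driven non-selective cation current
#' (the model's I_CAN). Basal openness `c_base` keeps the channel weakly
#' active without NKB, which is what couples TRPC5 conductance to the
#' resting membrane potential and rheobase.
#'
#' @param V Membrane potential (mV).
#' @param Ca_i Cytosolic calcium (uM).
#' @param a_NKB NKB receptor drive in `[0, 1]`.
#' @param params A [kndy_params] object.
#' @return Current in pA (inward negative below `E_TRPC5`).
#' @export
trpc5_current <- function(V, Ca_i, a_NKB, params) {
  v <- unclass(params)
  ohmic_current(v[["g_TRPC5"]], trpc5_open_fraction(Ca_i, a_NKB, params),
                V, v[["E_TRPC5"]])
}

#' GIRK current
#'
#' Dynorphin-driven, inwardly rectifying potassium current. Rectification is
#' a fixed sigmoid of voltage `r(V) = 1/(1 + exp((V - v_r)/k_r))`.
#'
#' @param V Membrane potential (mV).
#' @param a_Dyn Dynorphin receptor drive in `[0, 1]`.
#' @param params A [kndy_params] object.
#' @return Current in pA (outward for `V > E_K`).
#' @export
girk_current <- function(V, a_Dyn, params) {
  v <- unclass(params)
  r <- 1 / (1 + exp((V - v[["girk_v_half"]]) / v[["girk_k"]]))
  ohmic_current(v[["g_GIRK"]], a_Dyn * r, V, v[["E_K"]])
}

#' Instantaneous neuron state
#'
#' @param V_m Membrane potential (mV).
#' @param gates Named vector of the 12 gating fractions (names as in
#'   `kndysim:::.kndy_gates`); defaults to steady state at `V_m` when `params`
#'   is supplied.
#' @param Ca_i Cytosolic calcium (uM), `> 0`.
#' @param a_NKB,a_Dyn Receptor drives in `[0, 1]`.
#' @param params Optional [kndy_params] used to fill `gates` at steady state.
#' @return A `kndy_state` list.
#' @export
neuron_state <- function(V_m, gates = NULL, Ca_i = 0.05, a_NKB = 0, a_Dyn = 0,
                         params = NULL) {
  if (is.null(gates)) {
    if (is.null(params)) stop("supply gates or params", call. = FALSE)
    gates <- vapply(.kndy_gates, function(g) {
      steady_state_gate(V_m, gating_spec_from_params(params, g))
    }, numeric(1))
  }
  gates <- gates[.kndy_gates]
  if (anyNA(gates)) stop("gates must be named by gating variable", call. = FALSE)
  if (any(gates < 0 | gates > 1)) stop("every gate must lie in [0, 1]", call. = FALSE)
  if (Ca_i <= 0) stop("Ca_i must be > 0", call. = FALSE)
  if (a_NKB < 0 || a_NKB > 1 || a_Dyn < 0 || a_Dyn > 1) {
    stop("receptor drives must lie in [0, 1]", call. = FALSE)
  }
  structure(list(V_m = V_m, gates = gates, Ca_i = Ca_i,
                 a_NKB = a_NKB, a_Dyn = a_Dyn),
            class = "kndy_state")
}

#' All twelve ionic currents at one state
#'
#' @param state A [neuron_state()].
#' @param params A [kndy_params] object.
#' @return A one-row tibble with one column per current (pA, outward
#'   positive) and a `total` column equal to their sum.
#' @examples
#' p <- kndy_params("OVX")
#' s <- neuron_state(-65, params = p)
#' total_current(s, p)
#' @export
total_current <- function(state, params) {
  stopifnot(inherits(state, "kndy_state"), inherits(params, "kndy_params"))
  v <- unclass(params)
  g <- state$gates
  if (any(g < 0 | g > 1)) stop("every gate must lie in [0, 1]", call. = FALSE)
  V <- state$V_m

  # each gate enters its current raised to its integer exponent
  gp <- function(gname) g[[gname]]^v[[paste0(gname, "_exp")]]
  I <- c(
    I_NaT = ohmic_current(v[["g_NaT"]], gp("mNaT") * gp("hNaT"), V, v[["E_Na"]]),
    I_NaP = ohmic_current(v[["g_NaP"]], gp("pNaP"), V, v[["E_Na"]]),
    I_A   = ohmic_current(v[["g_A"]], gp("mA") * gp("hA"), V, v[["E_K"]]),
    I_BK  = ohmic_current(v[["g_BK"]], gp("bBK"), V, v[["E_K"]]),
    I_h   = ohmic_current(v[["g_h"]], gp("rh"), V, v[["E_h"]]),
    I_SK  = ohmic_current(v[["g_SK"]],
                          sk_open_fraction(state$Ca_i, v[["K_SK"]], v[["n_SK"]]),
                          V, v[["E_K"]]),
    I_M   = ohmic_current(v[["g_M"]], gp("wM"), V, v[["E_K"]]),
    I_T   = ohmic_current(v[["g_T"]], gp("mT") * gp("hT"), V, v[["E_Ca"]]),
    I_Ca  = ohmic_current(v[["g_Ca"]], gp("mCa") * gp("hCa"), V, v[["E_Ca"]]),
    I_TRPC5 = trpc5_current(V, state$Ca_i, state$a_NKB, params),
    I_GIRK  = girk_current(V, state$a_Dyn, params),
    I_leak  = ohmic_current(v[["g_leak"]], 1, V, v[["E_leak"]])
  )
  tibble::as_tibble(as.list(c(I, total = sum(I))))
}

#' Calcium balance
#'
#' Single-compartment calcium: influx converted from the calcium-carrying
#' currents (T-type, lumped HVA, and a fraction `f_TRPC5` of TRPC5) plus
#' first-order extrusion toward `Ca_rest`. Inward currents are negative, so
#' influx raises calcium.
#'
#' @param state A [neuron_state()].
#' @param breakdown One-row tibble from [total_current()] at this state.
#' @param params A [kndy_params] object.
#' @return dCa/dt in uM/ms.
#' @export
calcium_derivative <- function(state, breakdown, params) {
  v <- unclass(params)
  if (v[["tau_Ca"]] <= 0) stop("tau_Ca must be > 0", call. = FALSE)
  influx <- -v[["alpha_Ca"]] *
    (breakdown$I_T + breakdown$I_Ca + v[["f_TRPC5"]] * breakdown$I_TRPC5)
  influx - (state$Ca_i - v[["Ca_rest"]]) / v[["tau_Ca"]]
}

#' Full state derivative (reference implementation)
#'
#' In current clamp `dV/dt = (-I_total + I_inj)/C_m`; in voltage clamp the
#' membrane potential is pinned to the command and `dV/dt = 0` (the recorded
#' quantity is the total ionic current). Gates relax toward their steady
#' states (the BK midpoint is shifted by calcium); receptor drives follow
#' first-order kinetics toward the stimulus targets.
#'
#' @param t Time (ms), used only for ramp stimuli.
#' @param state A [neuron_state()].
#' @param params A [kndy_params] object.
#' @param stimulus A list: `mode` ("current" or "voltage"), `I_inj` (pA) or
#'   `V_cmd` (mV), optional `ramp_rate` (pA/s, from `t = t0`), `t0` (ms),
#'   `nkb_target`, `dyn_target`, `ca_clamp` (logical).
#' @return Named list: `dV`, `dgates` (named), `dCa`, `da_NKB`, `da_Dyn`,
#'   plus the current `breakdown`.
#' @export
state_derivative <- function(t, state, params, stimulus = list(mode = "current", I_inj = 0)) {
  v <- unclass(params)
  mode <- stimulus$mode %||% "current"
  if (!mode %in% c("current", "voltage")) {
    stop("unknown stimulus mode: ", mode, call. = FALSE)
  }
  brk <- total_current(state, params)
  dgates <- vapply(.kndy_gates, function(gname) {
    sp <- gating_spec_from_params(params, gname)
    if (gname == "bBK") sp$v_half <- bk_v_half_eff(params, state$Ca_i)
    gate_derivative(state$gates[[gname]], state$V_m, sp)
  }, numeric(1))
  dCa <- if (isTRUE(stimulus$ca_clamp)) 0 else calcium_derivative(state, brk, params)
  nkb_t <- stimulus$nkb_target %||% 0
  dyn_t <- stimulus$dyn_target %||% 0
  da_NKB <- (nkb_t - state$a_NKB) /
    (if (nkb_t > state$a_NKB) v[["tau_NKB_rise"]] else v[["tau_NKB_decay"]])
  da_Dyn <- (dyn_t - state$a_Dyn) /
    (if (dyn_t > state$a_Dyn) v[["tau_Dyn_rise"]] else v[["tau_Dyn_decay"]])
  if (mode == "current") {
    I_inj <- (stimulus$I_inj %||% 0) +
      (stimulus$ramp_rate %||% 0) * (t - (stimulus$t0 %||% 0)) / 1000
    dV <- (-brk$total + I_inj) / v[["C_m"]]
  } else {
    dV <- 0
  }
  list(dV = dV, dgates = dgates, dCa = dCa,
       da_NKB = da_NKB, da_Dyn = da_Dyn, breakdown = brk)
}
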