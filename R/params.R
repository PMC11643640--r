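# Model parameterization for the arcuate kisspeptin (KNDy) neuron model.
#
# Units used throughout the package: mV, ms, nS, pA, pF, uM.
# 1 nS * 1 mV = 1 pA; 1 pA / 1 pF = 1 mV/ms.

# Names of the twelve gating variables, in canonical state-vector order.
.kndy_gates <- c(
  "mNaT", "hNaT", "pNaP", "mA", "hA", "bBK",
  "rh", "wM", "mT", "hT", "mCa", "hCa"
)

# Per-gate parameter suffixes: Boltzmann midpoint and signed slope, integer
# exponent, non-inactivating floor, and a bell-shaped (hyperbolic-secant)
# voltage-dependent time constant tau(V) = tau_min + tau_amp / cosh((V - tau_vh)/tau_k).
.kndy_gate_fields <- c("vh", "k", "exp", "floor", "tau_min", "tau_amp", "tau_vh", "tau_k")

# Scalar (non-gating) parameters, canonical order shared with the C code.
.kndy_scalars <- c(
  "g_NaT", "g_NaP", "g_A", "g_BK", "g_h", "g_SK",
  "g_M", "g_T", "g_Ca", "g_TRPC5", "g_GIRK", "g_leak",
  "E_Na", "E_K", "E_Ca", "E_h", "E_TRPC5", "E_leak",
  "C_m",
  "Ca_rest", "tau_Ca", "alpha_Ca", "f_TRPC5",
  "K_SK", "n_SK",
  "K_TRPC5_Ca", "n_TRPC5", "c_base",
  "bk_ca_shift",
  "girk_v_half", "girk_k",
  "tau_NKB_rise", "tau_NKB_decay", "tau_Dyn_rise", "tau_Dyn_decay"
)

.kndy_param_names <- function() {
  c(.kndy_scalars,
    as.vector(t(outer(.kndy_gates, .kndy_gate_fields, paste, sep = "_"))))
}

.kndy_current_names <- c(
  "I_NaT", "I_NaP", "I_A", "I_BK", "I_h", "I_SK",
  "I_M", "I_T", "I_Ca", "I_TRPC5", "I_GIRK", "I_leak"
)

# Channel names accepted by apply_block(), mapped to conductance parameters.
.kndy_channels <- c(
  NaT = "g_NaT", NaP = "g_NaP", A = "g_A", BK = "g_BK", h = "g_h",
  SK = "g_SK", M = "g_M", T = "g_T", Ca = "g_Ca", TRPC5 = "g_TRPC5",
  GIRK = "g_GIRK", leak = "g_leak"
)

# Gating parameterization shared by both hormonal states. Midpoints for the
# lumped high-voltage-activated Ca current are the printed whole-cell
# Boltzmann fits (-32.3 mV activation, -48.9 mV inactivation); everything
# else is this package's calibrated fallback (see the methods vignette).
.kndy_gating_defaults <- function() {
  g <- list(
    #        vh      k    exp floor tau_min tau_amp tau_vh tau_k
    mNaT = c(-45,    6.0, 3,  0,    0.05,   0.10,  -30,   10),
    hNaT = c(-54,   -4.5, 1,  0,    0.30,   3.864, -55,   15),
    pNaP = c(-50,    6.0, 1,  0,    5.0,    0.0,   -50,   15),
    mA   = c(-20,   10.0, 1,  0,    1.5,    2.573, -45,   10),
    hA   = c(-60,   -8.0, 1,  0.15, 30,     50,    -60,   20),
    bBK  = c( 46.15, 12.0, 1, 0,    1.0,    2.0,     0,   20),
    rh   = c(-70,   -8.0, 1,  0,    50,     150,   -85,   15),
    wM   = c(-45,    6.0, 1,  0,    108.9,  100,   -50,   20),
    mT   = c(-50.5,  5.0, 1,  0,    2.0,    4.0,   -50,   15),
    hT   = c(-75.5, -5.0, 1,  0,    8,      73.9,  -75,   10),
    mCa  = c(-32.3,  7.0, 1,  0,    1.0,    6.0,   -30,   15),
    hCa  = c(-48.9, -6.2, 1,  0.25, 300,    0,     -50,   15)
  )
  out <- unlist(g)
  names(out) <- as.vector(t(outer(.kndy_gates, .kndy_gate_fields, paste, sep = "_")))
  out
}

.kndy_scalar_defaults <- function(state = c("OVX", "OVX_E2")) {
  state <- match.arg(state)
  base <- c(
    g_NaT = 160, g_NaP = 0.45, g_A = 23.6, g_BK = 20 * 32.8 / 90, g_h = 0.3,
    g_SK = 28.1, g_M = 0.635, g_T = 0.66, g_Ca = 2.1, g_TRPC5 = 11,
    g_GIRK = 2.5, g_leak = 2,
    E_Na = 60, E_K = -90, E_Ca = 60, E_h = -30, E_TRPC5 = 0, E_leak = -70,
    C_m = 19,
    Ca_rest = 0.05, tau_Ca = 150, alpha_Ca = 6.93e-5, f_TRPC5 = 0.02,
    K_SK = 0.3, n_SK = 4,
    K_TRPC5_Ca = 0.25, n_TRPC5 = 3, c_base = 0.15,
    bk_ca_shift = -20,
    girk_v_half = -50, girk_k = 15,
    tau_NKB_rise = 200, tau_NKB_decay = 1000,
    tau_Dyn_rise = 200, tau_Dyn_decay = 1000
  )
  if (state == "OVX_E2") {
    base[["g_NaT"]] <- 260
    base[["g_NaP"]] <- 0.9969
    base[["g_BK"]] <- 20.0
    base[["g_h"]] <- 4.002
    base[["g_M"]] <- 4 * 0.635
    base[["g_T"]] <- 5
    base[["g_Ca"]] <- 2.8
    base[["g_TRPC5"]] <- 6.6
    base[["g_GIRK"]] <- 1.2
    base[["g_leak"]] <- 1
    base[["E_leak"]] <- -76.8
    base[["c_base"]] <- 0.2977
    base[["f_TRPC5"]] <- 0.1
    base[["tau_Ca"]] <- 336.6
    base[["alpha_Ca"]] <- 0.008 / 336.6
  }
  base
}

#' Construct a model parameter set
#'
#' Builds the full parameter vector of the KNDy neuron model for one hormonal
#' state. The two shipped states pin the conductances the source
#' electrophysiology fixes (`g_SK` = 28.1 nS, `g_BK`(OVX+E2) = 20.0 nS,
#' `g_Ca` = 2.1/2.8 nS, `g_T` = 0.66/5 nS) and the whole-cell calcium
#' Boltzmann midpoints (-32.3 / -48.9 mV); all remaining values are
#' calibration products of this package.
#'
#' @param state `"OVX"`, `"OVX_E2"` or `"custom"` (with `custom` all values
#'   come from `...` on top of the OVX template).
#' @param ... Named overrides, e.g. `g_TRPC5 = 0.9` or `mCa_vh = -33`.
#'   Unknown names are an error.
#' @return An object of class `kndy_params`: a named numeric vector with the
#'   full model parameterization plus a `state_label` attribute.
#' @examples
#' p <- kndy_params("OVX")
#' p[["g_SK"]]
#' p2 <- kndy_params("OVX", g_TRPC5 = 0.9)
#' @export
kndy_params <- function(state = c("OVX", "OVX_E2", "custom"), ...) {
  state <- match.arg(state)
  base_state <- if (state == "OVX_E2") "OVX_E2" else "OVX"
  values <- c(.kndy_scalar_defaults(base_state), .kndy_gating_defaults())
  values <- values[.kndy_param_names()]
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(values))
    if (length(bad)) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    values[names(overrides)] <- overrides
  }
  new_kndy_params(values, state)
}

new_kndy_params <- function(values, state_label = "custom") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  values <- values[.kndy_param_names()]
  if (anyNA(values)) {
    stop("parameter vector is incomplete; missing: ",
         paste(.kndy_param_names()[is.na(values)], collapse = ", "),
         call. = FALSE)
  }
  structure(values, state_label = state_label, class = c("kndy_params", "numeric"))
}

#' @export
print.kndy_params <- function(x, ...) {
  cat("<kndy_params> state:", attr(x, "state_label"), "\n")
  g <- x[startsWith(names(x), "g_")]
  cat("conductances (nS):\n")
  print(round(unclass(g), 3))
  cat("C_m:", x[["C_m"]], "pF;  Ca_rest:", x[["Ca_rest"]],
      "uM;  tau_Ca:", x[["tau_Ca"]], "ms\n")
  invisible(x)
}

validate_kndy_params <- function(p) {
  v <- unclass(p)
  g <- v[startsWith(names(v), "g_")]
  if (any(g < 0)) stop("all conductances must be >= 0", call. = FALSE)
  if (v[["C_m"]] <= 0) stop("C_m must be > 0", call. = FALSE)
  if (v[["tau_Ca"]] <= 0) stop("tau_Ca must be > 0", call. = FALSE)
  if (v[["K_SK"]] <= 0) stop("K_SK must be > 0", call. = FALSE)
  if (!(v[["E_K"]] < v[["E_leak"]] && v[["E_leak"]] < v[["E_Na"]])) {
    stop("require E_K < E_leak < E_Na", call. = FALSE)
  }
  exps <- v[paste0(.kndy_gates, "_exp")]
  if (any(exps < 1)) stop("gate exponents must be >= 1", call. = FALSE)
  vgrid <- seq(-120, 60, by = 5)
  for (gname in .kndy_gates) {
    spec <- gating_spec_from_params(p, gname)
    if (any(gate_tau(vgrid, spec) <= 0)) {
      stop("tau(V) must be positive on [-120, 60] mV for gate ", gname,
           call. = FALSE)
    }
  }
  invisible(p)
}

#' Shipped hormonal-state parameter presets
#'
#' Returns the two calibrated parameter sets used throughout the package:
#' `OVX` (ovariectomized, low estradiol) and `OVX_E2` (estradiol-replaced).
#' The OVX+E2 state carries the larger calcium (`g_Ca`, `g_T`), BK, M and
#' h-current conductances and the smaller TRPC5/GIRK conductances, matching
#' the measured density and transcript directions.
#'
#' @return A named list with elements `OVX` and `OVX_E2`, each a
#'   [kndy_params] object.
#' @examples
#' ps <- shipped_state_sets()
#' ps$OVX[["g_T"]]
#' @export
shipped_state_sets <- function() {
  list(OVX = kndy_params("OVX"), OVX_E2 = kndy_params("OVX_E2"))
}

#' Modify parameters
#'
#' @param params A [kndy_params] object.
#' @param ... Named replacements (parameter name = value).
#' @return A modified copy; the input is untouched.
#' @export
param_set <- function(params, ...) {
  stopifnot(inherits(params, "kndy_params"))
  overrides <- c(...)
  v <- unclass(params)
  bad <- setdiff(names(overrides), names(v))
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v[names(overrides)] <- overrides
  new_kndy_params(v, attr(params, "state_label"))
}

#' Parameters as a tidy tibble
#'
#' @param x A [kndy_params] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`.
#' @export
as_tibble.kndy_params <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)), value = as.numeric(x))
}

# ---- YAML serialization ----------------------------------------------------

#' Read / write parameter sets as YAML
#'
#' Parameter files use one flat `values:` map keyed by the canonical
#' parameter names plus a `state_label` entry, so files round-trip exactly.
#'
#' @param path File path.
#' @return `read_params_yaml()` returns a [kndy_params] object;
#'   `write_params_yaml()` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$values)) stop("parameter file lacks a 'values' map", call. = FALSE)
  vals <- unlist(doc$values)
  new_kndy_params(vals, state_label = doc$state_label %||% "custom")
}

#' @rdname read_params_yaml
#' @param params A [kndy_params] object.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "kndy_params"))
  doc <- list(
    state_label = attr(params, "state_label"),
    values = as.list(stats::setNames(as.numeric(params), names(unclass(params))))
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
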