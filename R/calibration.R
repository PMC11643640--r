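# Bounded least-squares calibration of free model parameters against
# measured-density targets, with multi-start and parameter-recovery support.

#' Define a calibration target
#'
#' A target binds a measurement function to a desired value. The measurement
#' function receives the candidate parameter set and returns one number
#' (e.g. a current density from a simulated protocol).
#'
#' @param name Target label.
#' @param value Target value.
#' @param measure Function `function(params) -> numeric(1)`.
#' @param tolerance Relative tolerance used for reporting (> 0).
#' @param units Unit label.
#' @return A `kndy_target` object.
#' @export
calibration_target <- function(name, value, measure, tolerance = 0.1,
                               units = "") {
  stopifnot(is.function(measure), tolerance > 0)
  structure(list(name = name, value = value, measure = measure,
                 tolerance = tolerance, units = units),
            class = "kndy_target")
}

# Default calibration bounds (conductances in nS, C_m in pF, midpoints
# within +/- 40 mV of the starting point).
.calibration_bounds <- function(params, free) {
  v <- unclass(params)
  lower <- upper <- numeric(length(free))
  names(lower) <- names(upper) <- free
  for (nm in free) {
    if (startsWith(nm, "g_")) {
      lower[nm] <- 0; upper[nm] <- 100
    } else if (nm == "C_m") {
      lower[nm] <- 5; upper[nm] <- 60
    } else if (grepl("_vh$", nm)) {
      lower[nm] <- v[[nm]] - 40; upper[nm] <- v[[nm]] + 40
    } else if (nm %in% c("alpha_Ca")) {
      lower[nm] <- 1e-7; upper[nm] <- 1e-2
    } else if (nm %in% c("tau_Ca")) {
      lower[nm] <- 10; upper[nm] <- 5000
    } else {
      lower[nm] <- v[[nm]] / 10; upper[nm] <- v[[nm]] * 10
    }
  }
  list(lower = lower, upper = upper)
}

#' Calibrate free parameters against targets
#'
#' Bounded Levenberg-Marquardt least squares on relative residuals
#' `(measured - target)/target`, with seeded multi-start. Pinned
#' (non-free) parameters are never moved. Deterministic for a fixed seed
#' and starting point; the best solution found is returned even when the
#' optimizer did not flag convergence.
#'
#' @param params0 Starting [kndy_params].
#' @param free Character vector of free parameter names (may be empty).
#' @param targets List of [calibration_target()]s.
#' @param seed Integer seed for the multi-start perturbations.
#' @param n_starts Number of starts (first start is `params0` itself).
#' @param bounds Optional list(lower, upper) named by free parameters.
#' @return A `kndy_calibration` object: `params` (fitted), `fitted_values`,
#'   `residuals` (relative, one per target), `converged`, `objective`,
#'   `free`, `n_starts`; supports [tidy()] and [glance()].
#' @export
calibrate <- function(params0, free, targets, seed = 1, n_starts = 8,
                      bounds = NULL) {
  stopifnot(inherits(params0, "kndy_params"))
  if (length(free)) {
    bad <- setdiff(free, names(unclass(params0)))
    if (length(bad)) {
      stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(all(vapply(targets, inherits, logical(1), "kndy_target")))
  tvals <- vapply(targets, function(tg) tg$value, numeric(1))

  measure_all <- function(p) {
    vapply(seq_along(targets), function(i) {
      m <- try(targets[[i]]$measure(p), silent = TRUE)
      if (inherits(m, "try-error") || !is.finite(m)) {
        stop("target '", targets[[i]]$name, "' failed to evaluate",
             call. = FALSE)
      }
      m
    }, numeric(1))
  }

  if (length(free) == 0) {
    fitted <- measure_all(params0)
    res <- (fitted - tvals) / tvals
    return(structure(list(
      params = params0, fitted_values = stats::setNames(fitted, names(tvals)),
      residuals = res, converged = TRUE, objective = sum(res^2),
      free = character(0), n_starts = 0, targets = targets
    ), class = "kndy_calibration"))
  }

  b <- bounds %||% .calibration_bounds(params0, free)
  x0 <- as.numeric(unclass(params0)[free])
  resid_fn <- function(x) {
    p <- param_set(params0, stats::setNames(x, free))
    (measure_all(p) - tvals) / tvals
  }

  starts <- withr::with_seed(seed, {
    c(list(x0), purrr::map(seq_len(max(n_starts - 1, 0)), function(i) {
      pmax(pmin(x0 * stats::runif(length(x0), 0.6, 1.4),
                b$upper[free]), pmax(b$lower[free], 1e-12))
    }))
  })

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      lower = as.numeric(b$lower[free]), upper = as.numeric(b$upper[free]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj) {
      best <- list(fit = fit, obj = obj)
    }
  }
  if (is.null(best)) stop("all calibration starts failed", call. = FALSE)

  p_fit <- param_set(params0, stats::setNames(best$fit$par, free))
  fitted <- measure_all(p_fit)
  res <- (fitted - tvals) / tvals
  structure(list(
    params = p_fit,
    fitted_values = stats::setNames(fitted,
                                    vapply(targets, `[[`, "", "name")),
    residuals = stats::setNames(res, vapply(targets, `[[`, "", "name")),
    converged = best$fit$info %in% 1:4,
    objective = sum(res^2),
    free = free, n_starts = length(starts), targets = targets
  ), class = "kndy_calibration")
}

#' @export
print.kndy_calibration <- function(x, ...) {
  cat("<kndy_calibration>", length(x$free), "free parameter(s);",
      length(x$residuals), "target(s); converged:", x$converged, "\n")
  if (length(x$free)) {
    print(round(unclass(x$params)[x$free], 5))
  }
  cat("relative residuals:\n")
  print(round(x$residuals, 5))
  invisible(x)
}

#' @export
tidy.kndy_calibration <- function(x, ...) {
  tibble::tibble(term = x$free,
                 estimate = as.numeric(unclass(x$params)[x$free]))
}

#' @export
glance.kndy_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_targets = length(x$residuals), n_starts = x$n_starts)
}

# ---- shipped density measurements -----------------------------------------

#' Standard current-density measurements
#'
#' The density readouts used by the shipped calibrations and the anchor
#' reproduction: drug-sensitive or total end-of-step K-current density at a
#' chosen step of the K-step protocol, and the peak whole-cell calcium
#' density at a chosen step of the calcium I-V protocol. All are computed in
#' voltage clamp under the recording cocktail (sodium currents blocked) and
#' normalized by `C_m`.
#'
#' @param params A [kndy_params] object.
#' @param at_mV Step level to read (mV).
#' @param channel Channel name for the drug-sensitive variant.
#' @param ... Passed to [simulate_sweeps()] (e.g. `init_ms`, `dt_out`).
#' @return Density in pA/pF.
#' @export
density_ksens <- function(params, channel, at_mV = 40, ...) {
  p <- recording_cocktail(params)
  proto <- k_step_protocol()
  ctrl <- iv_from_step_family(simulate_sweeps(p, proto, ...),
                              rule = "end", density = TRUE)
  blk <- iv_from_step_family(
    simulate_sweeps(apply_block(p, stats::setNames(1, channel)), proto, ...),
    rule = "end", density = TRUE)
  sens <- subtract_family(ctrl, blk)
  sens$current[sens$voltage_mV == at_mV]
}

#' @rdname density_ksens
#' @export
density_ktotal <- function(params, at_mV = 40, ...) {
  p <- recording_cocktail(params)
  curve <- iv_from_step_family(simulate_sweeps(p, k_step_protocol(), ...),
                               rule = "end", density = TRUE)
  curve$current[curve$voltage_mV == at_mV]
}

#' Calcium-isolation cocktail (TTX + Cs/TEA internal)
#'
#' Blocks sodium and potassium currents, leaving the calcium-carrying and
#' unblocked cation currents, as in whole-cell calcium recordings.
#'
#' @param params A [kndy_params] object.
#' @return Parameters with Na and K conductances zeroed.
#' @export
ca_isolation_cocktail <- function(params) {
  apply_block(params, c(NaT = 1, NaP = 1, A = 1, BK = 1, SK = 1, M = 1,
                        GIRK = 1))
}

#' @rdname density_ksens
#' @details The calcium density is the cadmium-sensitive component: the
#'   per-sweep difference between the isolation-cocktail family and the same
#'   family with the calcium channels additionally blocked, read at its
#'   signed peak.
#' @export
density_ca_peak <- function(params, at_mV = -10, ...) {
  p <- ca_isolation_cocktail(params)
  proto <- ca_iv_protocol()
  ctrl <- simulate_sweeps(p, proto, ...)
  cd <- simulate_sweeps(apply_block(p, c(Ca = 1, T = 1)), proto, ...)
  diff_tr <- ctrl
  diff_tr$total <- ctrl$total - cd$total
  curve <- iv_from_step_family(diff_tr, rule = "peak", density = TRUE)
  curve$current[curve$voltage_mV == at_mV]
}

#' Anchor calibration targets for a hormonal state
#'
#' The printed density anchors: apamin-sensitive SK density and total
#' outward density at +40 mV, iberiotoxin-sensitive BK density at +40 mV
#' (OVX+E2), and peak calcium density at -10 mV.
#'
#' @param state `"OVX"` or `"OVX_E2"`.
#' @param ... Passed down to the measurement functions.
#' @return A list of [calibration_target()]s.
#' @export
anchor_targets <- function(state = c("OVX", "OVX_E2"), ...) {
  state <- match.arg(state)
  fast <- list(...)
  if (state == "OVX") {
    list(
      calibration_target("sk_density_40", 60.2,
                         function(p) do.call(density_ksens,
                                             c(list(p, "SK"), fast)),
                         units = "pA/pF"),
      calibration_target("total_outward_40", 125.5,
                         function(p) do.call(density_ktotal, c(list(p), fast)),
                         units = "pA/pF"),
      calibration_target("ca_peak_minus10", -7.2,
                         function(p) do.call(density_ca_peak, c(list(p), fast)),
                         units = "pA/pF")
    )
  } else {
    list(
      calibration_target("bk_density_40", 90.0,
                         function(p) do.call(density_ksens,
                                             c(list(p, "BK"), fast)),
                         units = "pA/pF"),
      calibration_target("total_outward_40", 195.4,
                         function(p) do.call(density_ktotal, c(list(p), fast)),
                         units = "pA/pF"),
      calibration_target("ca_peak_minus10", -13.4,
                         function(p) do.call(density_ca_peak, c(list(p), fast)),
                         units = "pA/pF")
    )
  }
}
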