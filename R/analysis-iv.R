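# I-V measurement, drug subtraction, Boltzmann fits, M-current relaxation,
# slow-EPSP amplitude and repolarization decomposition.

#' I-V curve from a voltage-clamp step family
#'
#' Per step level, reads either the signed peak current (extremum of largest
#' magnitude during the step) or the end-of-step current (mean over the last
#' 10 ms).
#'
#' @param sweeps A `kndy_sweeps` from a voltage-clamp protocol.
#' @param rule `"peak"` or `"end"`.
#' @param density Divide by membrane capacitance (pA/pF)? Default FALSE.
#' @param end_window Averaging window for the end rule (ms).
#' @return A `kndy_ivcurve` tibble: `voltage_mV`, `current` (pA or pA/pF),
#'   with attributes `rule` and `units`.
#' @export
iv_from_step_family <- function(sweeps, rule = c("peak", "end"),
                                density = FALSE, end_window = 10) {
  rule <- match.arg(rule)
  if (!identical(attr(sweeps, "mode"), "voltage")) {
    stop("I-V extraction needs a voltage-clamp family", call. = FALSE)
  }
  cm <- attr(sweeps, "C_m")
  steps <- dplyr::filter(sweeps, .data$epoch == "step")
  out <- steps |>
    dplyr::group_by(voltage_mV = .data$level) |>
    dplyr::group_modify(function(df, key) {
      i <- df$total
      val <- if (rule == "peak") {
        i[which.max(abs(i))]
      } else {
        t_end <- max(df$time_ms)
        mean(i[df$time_ms >= t_end - end_window])
      }
      tibble::tibble(current = val)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$voltage_mV)
  if (density) out$current <- out$current / cm
  structure(out, class = c("kndy_ivcurve", class(tibble::tibble())),
            rule = rule, units = if (density) "pA/pF" else "pA",
            measure = "total")
}

#' Construct an I-V curve from raw vectors
#'
#' @param voltage_mV Command voltages (mV).
#' @param current Currents (pA or pA/pF).
#' @param rule Measurement rule label.
#' @param units Unit label.
#' @return A `kndy_ivcurve` tibble.
#' @export
iv_curve <- function(voltage_mV, current, rule = "peak", units = "pA") {
  stopifnot(length(voltage_mV) == length(current))
  structure(tibble::tibble(voltage_mV = voltage_mV, current = current),
            class = c("kndy_ivcurve", class(tibble::tibble())),
            rule = rule, units = units)
}

#' Drug-subtraction of two I-V curves
#'
#' Pointwise control minus blocked, the standard isolation of a
#' drug-sensitive current component.
#'
#' @param control,blocked `kndy_ivcurve`s on identical voltage grids.
#' @return A `kndy_ivcurve` of the sensitive component.
#' @export
subtract_family <- function(control, blocked) {
  if (!isTRUE(all.equal(control$voltage_mV, blocked$voltage_mV))) {
    stop("voltage grids differ between control and blocked curves",
         call. = FALSE)
  }
  out <- control
  out$current <- control$current - blocked$current
  attr(out, "measure") <- "drug_sensitive"
  out
}

#' Boltzmann fit of normalized activation/inactivation data
#'
#' Fits \eqn{y = 1/(1 + \exp((V_{1/2} - V)/k))} by nonlinear least squares.
#' For `form = "activation"` the fit starts from a positive slope (curve
#' rising with depolarization); for `form = "inactivation"` from a negative
#' slope (availability falling with depolarization) -- the two printed
#' Methods forms are the same sigmoid up to the sign of `k`.
#'
#' @param data Tibble with columns `voltage_mV` and `response` (normalized,
#'   values in `[0, 1.05]`).
#' @param form `"activation"` or `"inactivation"`.
#' @return A `kndy_boltzmann` object with elements `v_half`, `slope_k`,
#'   `r_squared`, `fitted`, `form`; supports [tidy()] and [glance()].
#' @examples
#' d <- gen_activation_dataset(-32.3, 5, seq(-80, 0, 5), noise_sd = 0, seed = 1)
#' fit_boltzmann(d)$v_half
#' @export
fit_boltzmann <- function(data, form = c("activation", "inactivation")) {
  form <- match.arg(form)
  stopifnot(all(c("voltage_mV", "response") %in% names(data)))
  if (nrow(data) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(data$response < -0.05 | data$response > 1.05)) {
    stop("responses must be normalized to [0, 1.05]", call. = FALSE)
  }
  if (stats::sd(data$response) < 1e-8) {
    stop("degenerate data: responses are constant; fit cannot converge",
         call. = FALSE)
  }
  v <- data$voltage_mV
  y <- data$response
  # starting values: midpoint from the half-crossing, slope sign from form
  ord <- order(v)
  v0 <- stats::approx(y[ord] + seq_along(y) * 1e-12, v[ord], xout = 0.5,
                      rule = 2)$y
  k0 <- if (form == "activation") 8 else -8
  fit <- minpack.lm::nlsLM(
    response ~ 1 / (1 + exp((v_half - voltage_mV) / slope_k)),
    data = data, start = list(v_half = v0, slope_k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$convInfo$isConv) {
    stop("Boltzmann fit did not converge; residual sum of squares = ",
         signif(sum(stats::resid(fit)^2), 4), call. = FALSE)
  }
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    v_half = unname(co[["v_half"]]), slope_k = unname(co[["slope_k"]]),
    r_squared = 1 - ss_res / ss_tot, form = form,
    fitted = stats::fitted(fit), data = data
  ), class = "kndy_boltzmann")
}

#' @export
print.kndy_boltzmann <- function(x, ...) {
  cat(sprintf("<kndy_boltzmann> %s fit: V1/2 = %.2f mV, k = %.2f mV, r2 = %.4f\n",
              x$form, x$v_half, x$slope_k, x$r_squared))
  invisible(x)
}

#' @export
tidy.kndy_boltzmann <- function(x, ...) {
  tibble::tibble(term = c("v_half", "slope_k"),
                 estimate = c(x$v_half, x$slope_k))
}

#' @export
glance.kndy_boltzmann <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = nrow(x$data), form = x$form)
}

#' M-current relaxation amplitude of one deactivation sweep
#'
#' Difference between the initial (< 10 ms) and sustained (> 475 ms) current
#' of the 500 ms deactivation step.
#'
#' @param trace One sweep of the [m_deactivation_protocol()] (step epoch
#'   present), or any trace whose step epoch is at least 500 ms.
#' @return Amplitude in pA (positive when the initial current exceeds the
#'   sustained current).
#' @export
m_current_amplitude <- function(trace) {
  step <- if ("epoch" %in% names(trace)) {
    dplyr::filter(trace, .data$epoch == "step")
  } else trace
  t0 <- min(step$time_ms)
  dur <- max(step$time_ms) - t0
  if (dur < 500 - 1e-6) {
    stop("deactivation sweep must be at least 500 ms (got ", round(dur, 1),
         " ms)", call. = FALSE)
  }
  rel <- step$time_ms - t0
  mean(step$total[rel <= 10]) - mean(step$total[rel >= 475 & rel <= 500])
}

#' Slow-EPSP amplitude
#'
#' Zero-phase low-pass filters the membrane potential (default 2 Hz,
#' 2nd-order Butterworth) and reports the maximum filtered depolarization
#' during and after the drive epoch relative to the pre-stimulus baseline.
#'
#' @param trace A current-clamp trace containing a `drive` epoch.
#' @param cutoff_Hz Low-pass corner (Hz).
#' @return Amplitude in mV.
#' @export
slow_epsp_amplitude <- function(trace, cutoff_Hz = 2) {
  if (!"epoch" %in% names(trace) || !any(trace$epoch == "drive")) {
    stop("trace has no drive epoch", call. = FALSE)
  }
  dt <- stats::median(diff(trace$time_ms))
  stride <- max(1L, round(1 / dt)) # ~1 kHz is ample for a 2 Hz corner
  idx <- seq(1, nrow(trace), by = stride)
  v <- trace$vm_mV[idx]
  ep <- trace$epoch[idx]
  fs <- 1000 / (dt * stride)
  bf <- signal::butter(2, min(cutoff_Hz / (fs / 2), 0.99), type = "low")
  sm <- signal::filtfilt(bf, v - v[1]) + v[1]
  base <- mean(sm[ep == "baseline"])
  max(sm[ep != "baseline"]) - base
}

#' Paired-response ratio
#'
#' Ratio of two slow-EPSP amplitudes (second over first), the R2/R1 paired
#' stimulation readout.
#'
#' @param r1,r2 Amplitudes (mV).
#' @return `r2 / r1`.
#' @export
epsp_ratio <- function(r1, r2) r2 / r1

#' Decompose the repolarizing (outward) current
#'
#' At each sample, the share of each outward K-carrying current in the total
#' outward current: `share_i = max(I_i, 0) / sum_j max(I_j, 0)`.
#'
#' @param trace A `kndy_trace` with per-current columns.
#' @param currents Which currents count as the repolarizing set (default BK,
#'   SK, M, A, GIRK and leak).
#' @return A tibble `time_ms` + one share column per current; shares sum to 1
#'   wherever any outward current flows.
#' @export
repolarization_decomposition <- function(trace,
                                         currents = c("I_BK", "I_SK", "I_M",
                                                      "I_A", "I_GIRK", "I_leak")) {
  missing <- setdiff(currents, names(trace))
  if (length(missing)) {
    stop("trace lacks current columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mat <- pmax(as.matrix(trace[, currents]), 0)
  tot <- rowSums(mat)
  if (all(tot <= 0)) stop("no outward current anywhere in the trace", call. = FALSE)
  shares <- mat / ifelse(tot > 0, tot, NA_real_)
  out <- tibble::as_tibble(as.data.frame(shares))
  names(out) <- sub("^I_", "share_", currents)
  dplyr::bind_cols(tibble::tibble(time_ms = trace$time_ms), out)
}
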