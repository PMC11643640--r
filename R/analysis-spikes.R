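# Spike/burst measurement operators for current-clamp traces.

#' Detect spikes by threshold crossing
#'
#' Upward crossings of `threshold` with a 2 ms refractory merge.
#'
#' @param trace A current-clamp `kndy_trace` (or any tibble with `time_ms`,
#'   `vm_mV`).
#' @param threshold Detection threshold (mV), default 0.
#' @param refractory Merge window (ms).
#' @return A `kndy_spikes` tibble with column `time_ms`, plus attributes
#'   `threshold` and `duration_ms`.
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2) {
  if (identical(attr(trace, "mode"), "voltage")) {
    stop("spike detection needs a current-clamp trace", call. = FALSE)
  }
  v <- trace$vm_mV
  t <- trace$time_ms
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  times <- t[up]
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) > refractory)
    times <- times[keep]
  }
  structure(
    tibble::tibble(time_ms = times),
    class = c("kndy_spikes", class(tibble::tibble())),
    threshold = threshold,
    duration_ms = diff(range(t))
  )
}

# Split spike times into bursts: ISI < isi_continue keeps a burst going,
# ISI > isi_terminate ends it; a burst needs >= min_spikes spikes.
split_bursts <- function(times, isi_continue = 80, isi_terminate = 300,
                         min_spikes = 3) {
  if (length(times) == 0) return(list())
  gaps <- diff(times)
  grp <- cumsum(c(0, gaps > isi_terminate))
  groups <- split(times, grp)
  Filter(function(g) {
    length(g) >= min_spikes && all(diff(g) < isi_continue)
  }, groups)
}

#' Classify the firing mode of a trace
#'
#' Implements the five-way firing taxonomy: `silent` (< 0.1 Hz),
#' `phasic_burst` (recurrent bursts with regular periods and alternating
#' depolarized/hyperpolarized membrane states), `irregular_burst` (bursting
#' without that regularity), `tonic` (regular non-burst firing,
#' ISI CV < 0.5) and `irregular` (everything else). A burst is at least
#' `min_spikes` spikes with ISIs < `isi_continue` ms, terminated by an ISI
#' exceeding `isi_terminate` ms.
#'
#' @param spikes A `kndy_spikes` object from [detect_spikes()].
#' @param trace The current-clamp trace the spikes came from.
#' @param isi_continue,isi_terminate,min_spikes Burst criteria (ms, ms, count).
#' @param cv_regular CV threshold separating regular from irregular (0.5).
#' @param updown_range_mV Minimum peak-to-trough excursion of the low-pass
#'   membrane envelope for "up/down states" (mV).
#' @return A one-row tibble: `label`, `n_spikes`, `rate_Hz`, `n_bursts`,
#'   `isi_cv`, `burst_period_cv`, `intra_burst_rate_Hz`, `updown_range_mV`.
#' @export
classify_firing <- function(spikes, trace,
                            isi_continue = 80, isi_terminate = 300,
                            min_spikes = 3, cv_regular = 0.5,
                            updown_range_mV = 8) {
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  dur_s <- diff(range(trace$time_ms)) / 1000
  times <- spikes$time_ms
  rate <- length(times) / dur_s
  bursts <- split_bursts(times, isi_continue, isi_terminate, min_spikes)
  n_bursts <- length(bursts)
  isi <- diff(times)
  isi_cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_
  onset <- vapply(bursts, function(b) b[1], numeric(1))
  period <- diff(onset)
  period_cv <- if (length(period) >= 2) stats::sd(period) / mean(period) else
    if (length(period) == 1) 0 else NA_real_
  intra <- if (n_bursts > 0) {
    mean(vapply(bursts, function(b) 1000 * (length(b) - 1) / diff(range(b)),
                numeric(1)))
  } else NA_real_

  # subthreshold membrane envelope: subsample to ~1 kHz, then a running
  # median (~51 ms) that strips spikes without attenuating the slow wave
  updown <- local({
    dt <- stats::median(diff(trace$time_ms))
    stride <- max(1L, round(1 / dt))
    v <- trace$vm_mV[seq(1, nrow(trace), by = stride)]
    if (length(v) < 60) return(0)
    sm <- stats::runmed(v, k = 51)
    as.numeric(stats::quantile(sm, 0.98) - stats::quantile(sm, 0.02))
  })

  label <- if (rate < 0.1) {
    "silent"
  } else if (n_bursts >= 2) {
    if (!is.na(period_cv) && period_cv < cv_regular && updown >= updown_range_mV) {
      "phasic_burst"
    } else {
      "irregular_burst"
    }
  } else if (!is.na(isi_cv) && isi_cv < cv_regular) {
    "tonic"
  } else {
    "irregular"
  }
  tibble::tibble(
    label = label, n_spikes = length(times), rate_Hz = rate,
    n_bursts = n_bursts, isi_cv = isi_cv, burst_period_cv = period_cv,
    intra_burst_rate_Hz = intra, updown_range_mV = updown
  )
}

#' Rheobase from a current-ramp trace
#'
#' The injected current at the first spike; `rate x latency + start` for a
#' linear ramp.
#'
#' @param trace A current-clamp ramp trace (`stim` column present).
#' @param ramp The [ramp_protocol()] that produced it.
#' @param threshold Spike threshold (mV).
#' @return A one-row tibble: `rheobase_pA` (NA if no spike), `latency_ms`,
#'   `fired`.
#' @export
rheobase_from_ramp <- function(trace, ramp, threshold = 0) {
  sp <- detect_spikes(trace, threshold = threshold)
  if (nrow(sp) == 0) {
    return(tibble::tibble(rheobase_pA = NA_real_, latency_ms = NA_real_,
                          fired = FALSE))
  }
  lat <- sp$time_ms[1] - trace$time_ms[1]
  tibble::tibble(
    rheobase_pA = ramp$start + ramp$rate * lat / 1000,
    latency_ms = lat, fired = TRUE
  )
}

#' Firing-rate versus injected-current (F-I) curve
#'
#' Counts spikes during the step epoch of each current-clamp sweep and
#' divides by the step duration.
#'
#' @param sweeps A `kndy_sweeps` object from a current-clamp step family, or
#'   a tibble with `level`, `epoch`, `time_ms`, `vm_mV` columns.
#' @param threshold Spike threshold (mV).
#' @return A `kndy_fi` tibble: `level_pA`, `rate_Hz`.
#' @export
fi_curve <- function(sweeps, threshold = 0) {
  if (identical(attr(sweeps, "mode"), "voltage")) {
    stop("F-I needs a current-clamp step family", call. = FALSE)
  }
  steps <- dplyr::filter(sweeps, .data$epoch == "step")
  durs <- dplyr::summarise(dplyr::group_by(steps, .data$level),
                           dur = diff(range(.data$time_ms)))
  if (length(unique(round(durs$dur, 6))) > 1) {
    stop("mixed step durations in F-I family", call. = FALSE)
  }
  out <- steps |>
    dplyr::group_by(.data$level) |>
    dplyr::group_modify(function(df, key) {
      sp <- detect_spikes(df, threshold = threshold)
      dur_s <- diff(range(df$time_ms)) / 1000
      tibble::tibble(rate_Hz = nrow(sp) / dur_s)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(level_pA = "level")
  structure(out, class = c("kndy_fi", class(tibble::tibble())))
}
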