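# Constructed traces and small helpers shared across tests.

# A current-clamp trace tibble with triangular spikes at given times.
make_spike_trace <- function(spike_times, duration = 10000, dt = 0.5,
                             baseline = -65, peak = 20, width = 2) {
  t <- seq(0, duration, by = dt)
  v <- rep(baseline, length(t))
  for (ts in spike_times) {
    idx <- which(t >= ts - width & t <= ts + width)
    v[idx] <- pmax(v[idx], peak - abs(t[idx] - ts) * (peak - baseline) / width)
  }
  structure(tibble::tibble(time_ms = t, vm_mV = v),
            mode = "current")
}

# A phasic-burst style waveform: n_bursts bursts of n_spikes at intra_isi ms,
# riding on a depolarized plateau, separated by hyperpolarized gaps.
make_burst_trace <- function(n_bursts = 4, n_spikes = 5, intra_isi = 20,
                             period = 1000, dt = 0.5, down = -75, up = -50) {
  duration <- n_bursts * period + 500
  t <- seq(0, duration, by = dt)
  v <- rep(down, length(t))
  spikes <- c()
  for (b in seq_len(n_bursts)) {
    t0 <- (b - 1) * period + 200
    plateau <- n_spikes * intra_isi + 40
    v[t >= t0 - 20 & t <= t0 + plateau] <- up
    spikes <- c(spikes, t0 + (seq_len(n_spikes) - 1) * intra_isi)
  }
  for (ts in spikes) {
    idx <- which(t >= ts - 1.5 & t <= ts + 1.5)
    v[idx] <- pmax(v[idx], 20 - abs(t[idx] - ts) * 60)
  }
  structure(tibble::tibble(time_ms = t, vm_mV = v), mode = "current")
}

# Short current-clamp segment table.
cc_segments <- function(duration, level = 0, nkb = 0, dyn = 0, epoch = "step") {
  tibble::tibble(duration = duration, mode = "current", level = level,
                 rate = 0, nkb_target = nkb, dyn_target = dyn, epoch = epoch)
}

# Random valid neuron state under a fixed seed (for property loops).
random_state <- function(params, seed) {
  withr::with_seed(seed, {
    V <- stats::runif(1, -90, 30)
    gates <- stats::setNames(stats::runif(12), kndysim:::.kndy_gates)
    neuron_state(V, gates, Ca_i = stats::runif(1, 0.02, 1),
                 a_NKB = stats::runif(1), a_Dyn = stats::runif(1))
  })
}
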