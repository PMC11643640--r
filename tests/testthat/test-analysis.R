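test_that("spike detection finds threshold crossings with a refractory merge", {
  flat <- make_spike_trace(numeric(0), duration = 2000)
  expect_equal(nrow(detect_spikes(flat)), 0)
  tr <- make_spike_trace(c(100, 500, 900), duration = 2000)
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$time_ms, c(100, 500, 900), tolerance = 2)
  expect_equal(nrow(detect_spikes(tr, threshold = 50)), 0)
  vc <- structure(tr, mode = "voltage")
  expect_error(detect_spikes(vc), "current-clamp")
})

test_that("firing-mode classification separates the five classes", {
  quiet <- make_spike_trace(numeric(0), duration = 12000)
  expect_equal(classify_firing(detect_spikes(quiet), quiet)$label, "silent")
  tonic <- make_spike_trace(seq(200, 11800, by = 200), duration = 12000)
  expect_equal(classify_firing(detect_spikes(tonic), tonic)$label, "tonic")
  bursty <- make_burst_trace(n_bursts = 4, n_spikes = 5, intra_isi = 20,
                             period = 1000)
  cls <- classify_firing(detect_spikes(bursty), bursty)
  expect_equal(cls$label, "phasic_burst")
  expect_equal(cls$n_bursts, 4)
  expect_gt(cls$intra_burst_rate_Hz, 12.5)
  # irregular: same number of spikes, shuffled irregular timing
  irr_times <- withr::with_seed(5, sort(stats::runif(25, 0, 12000)))
  irr <- make_spike_trace(irr_times, duration = 12000)
  expect_true(classify_firing(detect_spikes(irr), irr)$label %in%
                c("irregular", "irregular_burst"))
  expect_error(classify_firing(detect_spikes(quiet), quiet[0, ]), "empty")
})

test_that("classification is invariant to time shifts and sampling doubling", {
  bursty <- make_burst_trace(n_bursts = 4)
  ref <- classify_firing(detect_spikes(bursty), bursty)$label
  shifted <- bursty
  shifted$time_ms <- shifted$time_ms + 5000
  shifted <- structure(shifted, mode = "current")
  expect_equal(classify_firing(detect_spikes(shifted), shifted)$label, ref)
  fine <- make_burst_trace(n_bursts = 4, dt = 0.25)
  expect_equal(classify_firing(detect_spikes(fine), fine)$label, ref)
})

test_that("rheobase is the injected current at the first spike of a ramp", {
  r <- ramp_protocol(rate = 50)
  tr <- make_spike_trace(622, duration = 2000)
  tr$stim <- r$start + r$rate * tr$time_ms / 1000
  rb <- rheobase_from_ramp(tr, r)
  expect_equal(rb$rheobase_pA, 31.1, tolerance = 0.01)
  t0 <- make_spike_trace(0.5, duration = 2000)
  expect_equal(rheobase_from_ramp(t0, r)$rheobase_pA, r$start, tolerance = 0.1)
  none <- make_spike_trace(numeric(0), duration = 2000)
  out <- rheobase_from_ramp(none, r)
  expect_false(out$fired)
  expect_true(is.na(out$rheobase_pA))
})

test_that("F-I curves count spikes during the step epoch", {
  mk_sweep <- function(level, spike_times) {
    tr <- make_spike_trace(spike_times, duration = 500)
    tr$level <- level
    tr$epoch <- "step"
    tr
  }
  fam <- dplyr::bind_rows(mk_sweep(10, numeric(0)),
                          mk_sweep(30, seq(25, 475, by = 50)))
  fam <- structure(fam, mode = "current")
  fi <- fi_curve(fam)
  expect_equal(fi$rate_Hz[fi$level_pA == 10], 0)
  expect_equal(fi$rate_Hz[fi$level_pA == 30], 20)
  bad <- dplyr::bind_rows(fam, {
    x <- mk_sweep(50, 100); x$time_ms <- x$time_ms * 2; x
  })
  expect_error(fi_curve(structure(bad, mode = "current")), "mixed step durations")
})

test_that("I-V extraction applies the peak and end-of-step rules", {
  mk_vc <- function(level, i_fun) {
    t <- seq(0, 500, by = 0.5)
    tibble::tibble(time_ms = t, vm_mV = level, level = level, epoch = "step",
                   total = i_fun(t))
  }
  fam <- dplyr::bind_rows(
    mk_vc(-10, function(t) -100 * exp(-t / 50)),        # inward, relaxing
    mk_vc(40, function(t) 200 - 150 * exp(-t / 20))     # outward, growing
  )
  fam <- structure(fam, mode = "voltage", C_m = 20)
  pk <- iv_from_step_family(fam, "peak")
  expect_equal(pk$current[pk$voltage_mV == -10], -100, tolerance = 1)
  expect_equal(pk$current[pk$voltage_mV == 40], 200, tolerance = 1)
  en <- iv_from_step_family(fam, "end")
  expect_equal(en$current[en$voltage_mV == -10], 0, tolerance = 0.01)
  expect_equal(en$current[en$voltage_mV == 40], 200, tolerance = 0.5)
  den <- iv_from_step_family(fam, "end", density = TRUE)
  expect_equal(den$current[den$voltage_mV == 40], 10, tolerance = 0.05)
  zero <- fam
  zero$total <- 0
  expect_true(all(iv_from_step_family(structure(zero, mode = "voltage"),
                                      "peak")$current == 0))
})

test_that("drug subtraction of I-V curves is pointwise and antisymmetric", {
  v <- seq(-60, 40, by = 10)
  ctrl <- iv_curve(v, seq(0, 125.5, length.out = 11), units = "pA/pF")
  blocked <- ctrl
  blocked$current[11] <- 125.5 - 60.2
  sens <- subtract_family(ctrl, blocked)
  expect_equal(sens$current[11], 60.2)
  expect_equal(subtract_family(ctrl, ctrl)$current, rep(0, 11))
  swapped <- subtract_family(blocked, ctrl)
  expect_equal(swapped$current, -sens$current)
  expect_error(subtract_family(ctrl, iv_curve(v + 5, ctrl$current)),
               "voltage grids")
})

test_that("Boltzmann fits recover the printed activation/inactivation midpoints", {
  act <- gen_activation_dataset(-32.3, 5, seq(-80, 0, by = 5), noise_sd = 0,
                                seed = 1)
  fit <- fit_boltzmann(act, form = "activation")
  expect_equal(fit$v_half, -32.3, tolerance = 0.01)
  expect_equal(fit$slope_k, 5, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)
  inact <- gen_activation_dataset(-48.9, -6.2, seq(-100, -10, by = 5),
                                  noise_sd = 0, seed = 1)
  fit2 <- fit_boltzmann(inact, form = "inactivation")
  expect_equal(fit2$v_half, -48.9, tolerance = 0.01)
  expect_lt(fit2$slope_k, 0)
  flat <- tibble::tibble(voltage_mV = seq(-80, 0, 5),
                         response = rep(0.5, 17))
  expect_error(fit_boltzmann(flat), "degenerate")
  expect_error(fit_boltzmann(act[1:3, ]), "at least 4")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "v_half"], fit$v_half)
  expect_equal(glance(fit)$nobs, nrow(act))
})

test_that("the Boltzmann fit is a consistent estimator under noise", {
  est <- vapply(1:200, function(s) {
    d <- gen_activation_dataset(-32.3, 5, seq(-80, 0, by = 5), noise_sd = 0.02,
                                seed = s)
    fit_boltzmann(d)$v_half
  }, numeric(1))
  expect_lt(abs(mean(est) + 32.3), 0.5)
})

test_that("M-current relaxation amplitude is initial minus sustained", {
  t <- seq(0, 500, by = 0.5)
  flat <- tibble::tibble(time_ms = t, total = rep(5, length(t)), epoch = "step")
  expect_equal(m_current_amplitude(flat), 0)
  A <- 40
  relax <- tibble::tibble(time_ms = t, total = 10 + A * exp(-t / 30),
                          epoch = "step")
  expect_equal(m_current_amplitude(relax), A, tolerance = 0.05 * A)
  expect_gt(m_current_amplitude(relax), 0)
  short <- dplyr::filter(relax, time_ms < 400)
  expect_error(m_current_amplitude(short), "at least 500 ms")
})

test_that("slow-EPSP amplitude is read from the low-passed membrane", {
  t <- seq(0, 40000, by = 1)
  epoch <- ifelse(t < 5000, "baseline", ifelse(t < 35000, "drive", "post"))
  flat <- tibble::tibble(time_ms = t, vm_mV = -65, epoch = epoch)
  expect_equal(slow_epsp_amplitude(flat), 0, tolerance = 1e-6)
  plateau <- flat
  plateau$vm_mV <- ifelse(t >= 5000 & t < 35000, -55, -65)
  expect_equal(slow_epsp_amplitude(plateau), 10, tolerance = 0.3)
  expect_equal(epsp_ratio(8, 8), 1)
  expect_error(slow_epsp_amplitude(dplyr::filter(flat, epoch == "baseline")),
               "drive epoch")
})

test_that("repolarization decomposition yields normalized, scale-invariant shares", {
  t <- seq(0, 100, by = 1)
  tr <- tibble::tibble(
    time_ms = t, I_BK = 50, I_SK = 50, I_M = 0, I_A = 0, I_GIRK = 0,
    I_leak = 0
  )
  sh <- repolarization_decomposition(tr)
  expect_equal(sh$share_BK, rep(0.5, length(t)))
  expect_equal(sh$share_SK, rep(0.5, length(t)))
  only_bk <- tr
  only_bk$I_SK <- -10 # inward contributions are clipped at zero
  sh2 <- repolarization_decomposition(only_bk)
  expect_equal(sh2$share_BK, rep(1, length(t)))
  sums <- rowSums(as.matrix(sh[, -1]))
  expect_equal(sums, rep(1, length(t)))
  scaled <- tr
  scaled[, -1] <- scaled[, -1] * 7
  expect_equal(repolarization_decomposition(scaled)$share_BK, sh$share_BK)
  none <- tr
  none[, -1] <- -1
  expect_error(repolarization_decomposition(none), "no outward")
})
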