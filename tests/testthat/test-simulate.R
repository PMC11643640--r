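p_ovx <- kndy_params("OVX")
p_e2 <- kndy_params("OVX_E2")

test_that("a zero-stimulus simulation from steady state stays at rest", {
  tr <- simulate_neuron(p_ovx, cc_segments(1000), dt_out = 0.5, init_ms = 6000)
  expect_lt(max(abs(tr$vm_mV - tr$vm_mV[1])), 0.01)
})

test_that("voltage clamp pins the membrane to the command", {
  sw <- simulate_sweeps(p_ovx, ca_iv_protocol(), init_ms = 1000, dt_out = 0.5)
  steps <- dplyr::filter(sw, epoch == "step")
  expect_equal(steps$vm_mV, steps$level)
  expect_equal(steps$stim, steps$level)
})

test_that("the per-current breakdown sums to the total at every sample", {
  tr <- simulate_neuron(p_e2, cc_segments(2000), dt_out = 0.5, init_ms = 3000)
  comp <- rowSums(as.matrix(tr[, kndysim:::.kndy_current_names]))
  denom <- pmax(abs(tr$total), 1)
  expect_lt(max(abs(comp - tr$total) / denom), 1e-9)
})

test_that("gates, drives and calcium stay in their physical ranges", {
  protos <- list(
    cc_segments(3000),
    cc_segments(3000, nkb = 1),
    cc_segments(3000, level = 30)
  )
  for (p in list(p_ovx, p_e2)) {
    for (segs in protos) {
      tr <- simulate_neuron(p, segs, dt_out = 1, init_ms = 2000)
      expect_true(all(tr$ca_uM > 0))
      expect_true(all(tr$a_nkb >= 0 & tr$a_nkb <= 1))
      expect_true(all(tr$a_dyn >= 0 & tr$a_dyn <= 1))
      expect_true(all(is.finite(tr$vm_mV)))
    }
  }
})

test_that("the adaptive solution matches brute-force fixed-step integration", {
  # 2 s window of spontaneous OVX+E2 bursting
  init <- steady_state(p_e2, 0, "current", 5000)
  a <- simulate_neuron(p_e2, cc_segments(2000), dt_out = 0.5,
                       method = "ode45", init_state = init)
  b <- simulate_neuron(p_e2, cc_segments(2000), dt_out = 0.5,
                       method = "rk4", rk4_dt = 0.01, init_state = init)
  expect_lt(max(abs(a$vm_mV - b$vm_mV)), 0.5)
})

test_that("simulations are deterministic, and noise is seed-controlled", {
  a <- simulate_neuron(p_ovx, cc_segments(500), dt_out = 0.5, init_ms = 500)
  b <- simulate_neuron(p_ovx, cc_segments(500), dt_out = 0.5, init_ms = 500)
  expect_identical(a$vm_mV, b$vm_mV)
  n1 <- simulate_neuron(p_ovx, cc_segments(500), dt_out = 0.5, init_ms = 500,
                        noise = list(sigma = 5, tau = 5), seed = 11)
  n2 <- simulate_neuron(p_ovx, cc_segments(500), dt_out = 0.5, init_ms = 500,
                        noise = list(sigma = 5, tau = 5), seed = 11)
  n3 <- simulate_neuron(p_ovx, cc_segments(500), dt_out = 0.5, init_ms = 500,
                        noise = list(sigma = 5, tau = 5), seed = 12)
  expect_identical(n1$vm_mV, n2$vm_mV)
  expect_false(identical(n1$vm_mV, n3$vm_mV))
  expect_error(simulate_neuron(p_ovx, cc_segments(500), init_ms = 200,
                               noise = list(sigma = 5, tau = 5)),
               "seed is mandatory")
})

test_that("divergent simulations fail loudly, naming the bad variable", {
  expect_error(
    suppressWarnings(
      simulate_neuron(p_ovx, cc_segments(50, level = 1e308), init_ms = 1,
                      dt_out = 1)),
    "diverged|system is singular|unable")
})

test_that("trace CSV export writes tidy columns plus a JSON sidecar", {
  tr <- simulate_neuron(p_ovx, cc_segments(100), dt_out = 1, init_ms = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_true(all(c("time_ms", "vm_mV", "ca_uM", "stim",
                    kndysim:::.kndy_current_names) %in% names(back)))
  expect_equal(nrow(back), nrow(tr))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$mode, "current")
  expect_equal(meta$C_m, 19)
})

test_that("the OU background current has the configured moments", {
  ou <- kndysim:::ou_path(0, 20000, dt = 0.5, sigma = 8, tau = 10, seed = 3)
  x <- ou[, 2]
  expect_lt(abs(mean(x)), 1)             # zero mean
  expect_equal(stats::sd(x), 8, tolerance = 0.15) # stationary sd
})
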