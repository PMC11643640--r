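p_ovx <- kndy_params("OVX")

test_that("ohmic currents follow the nS x mV = pA convention", {
  expect_equal(ohmic_current(5, 0.5, -30, -30), 0)          # at reversal
  expect_equal(ohmic_current(28.1, 1, 40, -90), 3653)       # g_SK full open
  expect_equal(ohmic_current(10, 0, 40, -90), 0)            # closed channel
  expect_error(ohmic_current(-1, 1, 0, 0), ">= 0")
})

test_that("SK opening is a Hill function of calcium with K = 0.3 uM", {
  expect_equal(sk_open_fraction(0.3), 0.5)
  expect_lt(sk_open_fraction(1e-6), 1e-10)
  expect_equal(sk_open_fraction(0.6, K_SK = 0.3, n_SK = 4), 16 / 17)
  expect_error(sk_open_fraction(0.1, K_SK = 0), "K_SK")
})

test_that("TRPC5 current vanishes without drive or at its reversal, and is linear in g", {
  p0 <- param_set(p_ovx, c_base = 0)
  expect_equal(trpc5_current(-60, 0.5, 0, p0), 0)
  expect_equal(trpc5_current(p_ovx[["E_TRPC5"]], 0.5, 1, p_ovx), 0)
  i1 <- trpc5_current(-60, 0.4, 0.7, p_ovx)
  i2 <- trpc5_current(-60, 0.4, 0.7, param_set(p_ovx, g_TRPC5 = 2 * p_ovx[["g_TRPC5"]]))
  expect_lt(i1, 0) # inward below reversal
  expect_equal(i2, 2 * i1)
  # strictly increasing magnitude in calcium and in receptor drive
  ca <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(abs(trpc5_current(-60, ca, 1, p_ovx))) > 0))
  aa <- seq(0, 1, by = 0.1)
  expect_true(all(diff(abs(trpc5_current(-60, 0.3, aa, p_ovx))) > 0))
  # basal calcium-gated opening persists at zero drive when c_base > 0
  expect_lt(trpc5_current(-60, 0.3, 0, p_ovx), 0)
})

test_that("GIRK current requires dynorphin drive and is outward above E_K", {
  expect_equal(girk_current(-60, 0, p_ovx), 0)
  expect_equal(girk_current(p_ovx[["E_K"]], 1, p_ovx), 0)
  expect_gt(girk_current(-60, 1, p_ovx), 0)
})

test_that("the breakdown sums to the total and respects zero conductances", {
  s <- neuron_state(-55, params = p_ovx, Ca_i = 0.2, a_NKB = 0.5, a_Dyn = 0.3)
  brk <- total_current(s, p_ovx)
  comp <- sum(as.numeric(brk[1, kndysim:::.kndy_current_names]))
  expect_equal(brk$total, comp, tolerance = 1e-12)
  gzero <- param_set(p_ovx, stats::setNames(rep(0, 12), paste0("g_", c(
    "NaT", "NaP", "A", "BK", "h", "SK", "M", "T", "Ca", "TRPC5", "GIRK", "leak"))))
  brk0 <- total_current(s, gzero)
  expect_true(all(abs(as.numeric(brk0)) < 1e-12))
  # leak only: 1 nS from -55 to E_leak -65 -> 10 pA
  pleak <- param_set(gzero, g_leak = 1, E_leak = -65)
  s2 <- neuron_state(-55, params = pleak)
  expect_equal(total_current(s2, pleak)$total, 10)
})

test_that("states with gates outside [0,1] are rejected", {
  expect_error(neuron_state(-60, stats::setNames(rep(1.2, 12), kndysim:::.kndy_gates)),
               "\\[0, 1\\]")
  expect_error(neuron_state(-60, params = p_ovx, Ca_i = -0.1), "Ca_i")
})

test_that("calcium balance has the stated fixed points", {
  s <- neuron_state(-65, params = p_ovx, Ca_i = p_ovx[["Ca_rest"]])
  brk <- total_current(s, p_ovx)
  brk[1, ] <- 0 # zero all calcium-carrying currents
  expect_equal(calcium_derivative(s, brk, p_ovx), 0)
  s2 <- neuron_state(-65, params = p_ovx, Ca_i = p_ovx[["Ca_rest"]] + 1)
  p100 <- param_set(p_ovx, tau_Ca = 100)
  expect_equal(calcium_derivative(s2, brk, p100), -0.01)
  # constant influx J settles at Ca_rest + J * tau_Ca
  J <- 2e-4 # uM/ms
  brkJ <- brk
  brkJ$I_Ca <- -J / p100[["alpha_Ca"]]
  ca_ss <- p100[["Ca_rest"]] + J * 100
  sss <- neuron_state(-65, params = p100, Ca_i = ca_ss)
  expect_equal(calcium_derivative(sss, brkJ, p100), 0, tolerance = 1e-10)
})

test_that("state derivative implements both clamp modes", {
  ss <- steady_state(p_ovx, 0, "current", duration = 6000)
  s <- neuron_state(ss[["V"]], ss[kndysim:::.kndy_gates], ss[["Ca"]])
  d <- state_derivative(0, s, p_ovx, list(mode = "current", I_inj = 0))
  expect_lt(abs(d$dV), 0.005) # at rest
  # 20 pA onto 20 pF with no net ionic current -> 1 mV/ms
  p20 <- param_set(p_ovx, C_m = 20)
  gz <- param_set(p20, stats::setNames(rep(0, 12), paste0("g_", c(
    "NaT", "NaP", "A", "BK", "h", "SK", "M", "T", "Ca", "TRPC5", "GIRK", "leak"))))
  d2 <- state_derivative(0, s, gz, list(mode = "current", I_inj = 20))
  expect_equal(d2$dV, 1)
  d3 <- state_derivative(0, s, p_ovx, list(mode = "voltage", V_cmd = -40))
  expect_equal(d3$dV, 0)
  expect_error(state_derivative(0, s, p_ovx, list(mode = "banana")),
               "unknown stimulus mode")
})

test_that("the compiled right-hand side matches the R reference implementation", {
  # property check over random states under a fixed seed
  for (seed in 1:8) {
    s <- random_state(p_ovx, seed)
    brk_r <- total_current(s, p_ovx)
    y <- c(s$V_m, s$gates, s$Ca_i, s$a_NKB, s$a_Dyn)
    names(y) <- kndysim:::.kndy_state_names()
    parms <- kndysim:::.c_parms(p_ovx, "current", nkb = s$a_NKB, dyn = s$a_Dyn)
    out <- deSolve::ode(y, c(0, 0.001), func = "kndy_derivs", parms = parms,
                        dllname = "kndysim", initfunc = "kndy_initparms",
                        initforc = "kndy_initforc",
                        forcings = kndysim:::.zero_forcing(0, 1),
                        nout = 13, outnames = c(kndysim:::.kndy_current_names, "total"),
                        method = "rk4")
    for (cn in kndysim:::.kndy_current_names) {
      expect_equal(unname(out[1, cn]), brk_r[[cn]], tolerance = 1e-9,
                   info = paste(cn, "seed", seed))
    }
    expect_equal(unname(out[1, "total"]), brk_r$total, tolerance = 1e-9)
  }
})
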