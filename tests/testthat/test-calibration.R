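# Calibration uses fast measurement functions (single short sweeps) so the
# optimizer is exercised end-to-end without long simulations.

fast_density <- function(at_mV) {
  force(at_mV)
  function(params) {
    p <- recording_cocktail(params)
    segs <- tibble::tibble(duration = c(20, 500), mode = "voltage",
                           level = c(-70, at_mV), rate = 0,
                           nkb_target = 0, dyn_target = 0,
                           epoch = c("baseline", "step"))
    tr <- simulate_neuron(p, segs, dt_out = 1, init_ms = 800)
    step <- dplyr::filter(tr, .data$epoch == "step")
    mean(step$total[step$time_ms >= max(step$time_ms) - 10]) / params[["C_m"]]
  }
}

test_that("zero free parameters returns the starting point with its residuals", {
  p0 <- kndy_params("OVX")
  tg <- list(calibration_target("x", 1, function(p) 1.1))
  res <- calibrate(p0, character(0), tg)
  expect_identical(as.numeric(res$params), as.numeric(p0))
  expect_equal(unname(res$residuals), 0.1, tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("noiseless synthetic targets are recovered within 1%", {
  truth <- kndy_params("OVX")
  measures <- list(fast_density(40), fast_density(0))
  target_vals <- vapply(measures, function(f) f(truth), numeric(1))
  targets <- list(
    calibration_target("dens40", target_vals[1], measures[[1]]),
    calibration_target("dens0", target_vals[2], measures[[2]])
  )
  # perturb the free parameters by about +/-30% and recover
  start <- param_set(truth, g_A = truth[["g_A"]] * 1.3,
                     g_M = truth[["g_M"]] * 0.7)
  res <- calibrate(start, c("g_A", "g_M"), targets, seed = 1, n_starts = 2)
  expect_lt(abs(res$params[["g_A"]] - truth[["g_A"]]) / truth[["g_A"]], 0.01)
  expect_lt(abs(res$params[["g_M"]] - truth[["g_M"]]) / truth[["g_M"]], 0.01)
  # pinned (printed) conductances never move
  expect_equal(res$params[["g_SK"]], 28.1)
  expect_equal(res$params[["g_Ca"]], 2.1)
})

test_that("5% target noise still recovers parameters within 10%", {
  truth <- kndy_params("OVX")
  # drug-sensitive (A-type) density has unit leverage on g_A
  measure_asens <- function(params) {
    fast_density(40)(params) - fast_density(40)(apply_block(params, c(A = 1)))
  }
  clean <- measure_asens(truth)
  noisy <- withr::with_seed(8, clean * (1 + stats::rnorm(1, 0, 0.05)))
  targets <- list(calibration_target("asens40", noisy, measure_asens))
  start <- param_set(truth, g_A = truth[["g_A"]] * 0.75)
  res <- calibrate(start, "g_A", targets, seed = 2, n_starts = 2)
  expect_lt(abs(res$params[["g_A"]] - truth[["g_A"]]) / truth[["g_A"]], 0.10)
})

test_that("the objective is invariant to target ordering", {
  p0 <- kndy_params("OVX")
  t1 <- calibration_target("a", 2, function(p) p[["g_leak"]])
  t2 <- calibration_target("b", 25, function(p) p[["g_A"]])
  r12 <- calibrate(p0, "g_leak", list(t1, t2), seed = 3, n_starts = 1)
  r21 <- calibrate(p0, "g_leak", list(t2, t1), seed = 3, n_starts = 1)
  expect_equal(r12$objective, r21$objective, tolerance = 1e-10)
})

test_that("failing targets raise an error naming the target", {
  p0 <- kndy_params("OVX")
  bad <- calibration_target("doomed", 1, function(p) stop("boom"))
  expect_error(calibrate(p0, character(0), list(bad)), "doomed")
})

test_that("calibration results support tidy and glance", {
  p0 <- kndy_params("OVX")
  tg <- list(calibration_target("a", p0[["g_leak"]], function(p) p[["g_leak"]]))
  res <- calibrate(p0, "g_leak", tg, seed = 1, n_starts = 1)
  expect_equal(tidy(res)$term, "g_leak")
  expect_equal(glance(res)$n_targets, 1)
  expect_output(print(res), "kndy_calibration")
})

test_that("shipped anchor targets evaluate against the printed densities", {
  at <- anchor_targets("OVX")
  expect_equal(vapply(at, function(t) t$value, numeric(1)),
               c(60.2, 125.5, -7.2))
  at2 <- anchor_targets("OVX_E2")
  expect_equal(vapply(at2, function(t) t$value, numeric(1)),
               c(90.0, 195.4, -13.4))
})
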