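template <- iv_curve(seq(-80, 30, 10),
                     -c(0.4, 3, 10, 26, 48, 70, 89, 105, 118, 128, 134, 136) / 10)

test_that("generators are pure functions of their seed", {
  a <- gen_iv_dataset(template, 5, seed = 42)
  b <- gen_iv_dataset(template, 5, seed = 42)
  c <- gen_iv_dataset(template, 5, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
  q1 <- gen_qpcr_dataset(tibble::tibble(gene = "Tac2", group = "OVX", fold = 1),
                         seed = 7)
  q2 <- gen_qpcr_dataset(tibble::tibble(gene = "Tac2", group = "OVX", fold = 1),
                         seed = 7)
  expect_identical(q1, q2)
  # no global RNG pollution
  withr::with_seed(1, {
    before <- stats::runif(1)
  })
  withr::with_seed(1, {
    invisible(gen_iv_dataset(template, 3, seed = 9))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("noise-free generation reproduces the template exactly", {
  d <- gen_iv_dataset(template, 4, noise_cv = 0, scale_sdlog = 0, seed = 1)
  for (i in 1:4) {
    expect_equal(d$current[d$cell == i], template$current)
  }
  expect_error(gen_iv_dataset(template, 4, noise_cv = -0.1), ">= 0")
})

test_that("cell means converge to the template (law of large numbers)", {
  n <- 10000
  d <- gen_iv_dataset(template, n, noise_cv = 0.05, scale_sdlog = 0.1, seed = 2)
  m <- d |>
    dplyr::group_by(.data$voltage_mV) |>
    dplyr::summarise(mean = mean(.data$current), se = stats::sd(.data$current) / sqrt(n))
  # lognormal scale has mean exp(sdlog^2/2)
  expected <- template$current * exp(0.1^2 / 2)
  expect_true(all(abs(m$mean - expected) < 4 * m$se + 1e-9))
})

test_that("blocker experiments recover the designed subtype fractions", {
  fr_ovx <- subtype_fractions("OVX")
  expect_equal(unname(fr_ovx[["L"]]), 0.261)
  expect_equal(unname(fr_ovx[["R"]]), 0.311)
  fr_e2 <- subtype_fractions("OVX_E2")
  expect_equal(unname(fr_e2[["R"]]), 0.270)
  exp1 <- gen_blocker_experiment(template, fr_ovx, "L", n_cells = 40,
                                 noise_cv = 0.02, seed = 3)
  expect_equal(recover_blocked_fraction(exp1), 0.261, tolerance = 1e-9)
  exp2 <- gen_blocker_experiment(template, fr_e2, "R", n_cells = 40,
                                 noise_cv = 0.02, seed = 3)
  expect_equal(recover_blocked_fraction(exp2), 0.270, tolerance = 1e-9)
  zero <- gen_blocker_experiment(template, c(fr_ovx, X = 0), "X", n_cells = 3,
                                 seed = 1)
  ctrl <- dplyr::filter(zero, .data$condition == "control")
  drug <- dplyr::filter(zero, .data$condition == "drug")
  expect_equal(ctrl$current, drug$current)
  expect_error(gen_blocker_experiment(template, fr_ovx, "Q"), "unknown drug")
})

test_that("synthetic activation data feeds the Boltzmann recovery round trip", {
  d <- gen_activation_dataset(-33.6, 5, seq(-80, 0, 5), noise_sd = 0, seed = 1)
  expect_equal(fit_boltzmann(d)$v_half, -33.6, tolerance = 0.01)
  expect_equal(d$response[d$voltage_mV == -80], 0, tolerance = 1e-3)
  expect_error(gen_activation_dataset(-30, 5, c(-40, -30, -20)), "4 voltages")
})

test_that("qPCR direction recovery holds in at least 95% of seeded replicates", {
  design <- tibble::tibble(
    gene = rep(c("Tac2", "Slc17a6"), each = 2),
    group = rep(c("OVX", "OVX_E2"), 2),
    fold = c(1, 0.4, 1, 2.2)
  )
  ok <- vapply(1:200, function(s) {
    dat <- gen_qpcr_dataset(design, sd_animal = 0.3, sd_pool = 0.2,
                            n_animals = 4, n_pools = 3, seed = s)
    sm <- ddct_analysis(dat)$summary
    down <- sm$mean_fold[sm$group == "OVX_E2" & sm$gene == "Tac2"] < 1
    up <- sm$mean_fold[sm$group == "OVX_E2" & sm$gene == "Slc17a6"] > 1
    down && up
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("synthetic cells have positive lognormal capacitance and scale", {
  cells <- gen_cells(500, seed = 4)
  expect_true(all(cells$C_m > 0))
  expect_true(all(cells$scale > 0))
  expect_equal(stats::median(cells$C_m), 20, tolerance = 1)
})
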