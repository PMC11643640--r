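# Seeded generators for synthetic "experimental" datasets with the
# statistical structure the analyses assume: per-cell I-V families with
# lognormal cell-to-cell scale and capacitance, drug-subtraction experiments
# with fixed subtype fractions, Boltzmann activation points, and pooled qPCR
# CT datasets with animal and pool variance components. Every generator is a
# pure function of (arguments, seed): RNG state is localized.

#' Synthetic cell roster
#'
#' Per-cell capacitance and multiplicative scale factor, both lognormal.
#'
#' @param n_cells Number of cells.
#' @param cm_mean Median capacitance (pF).
#' @param cm_sdlog,scale_sdlog Lognormal sigma of capacitance / scale.
#' @param group Group label.
#' @param seed Integer seed.
#' @return Tibble: `cell`, `C_m`, `scale`, `group`.
#' @export
gen_cells <- function(n_cells, cm_mean = 20, cm_sdlog = 0.25,
                      scale_sdlog = 0.2, group = "OVX", seed = 1) {
  stopifnot(n_cells >= 1)
  withr::with_seed(seed, {
    tibble::tibble(
      cell = seq_len(n_cells),
      C_m = stats::rlnorm(n_cells, log(cm_mean), cm_sdlog),
      scale = stats::rlnorm(n_cells, 0, scale_sdlog),
      group = group
    )
  })
}

#' Synthetic per-cell I-V dataset
#'
#' Each cell's curve is `template x cell_scale x (1 + eps)` with
#' `eps ~ N(0, noise_cv)` independently per voltage.
#'
#' @param template A `kndy_ivcurve` (or tibble with `voltage_mV`, `current`).
#' @param n_cells Number of cells.
#' @param noise_cv Per-voltage coefficient of variation (>= 0).
#' @param scale_sdlog Lognormal sigma of the cell scale factor.
#' @param seed Integer seed.
#' @return Tidy tibble: `cell`, `voltage_mV`, `current`.
#' @export
gen_iv_dataset <- function(template, n_cells, noise_cv = 0.05,
                           scale_sdlog = 0.2, seed = 1) {
  stopifnot(n_cells >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      sc <- stats::rlnorm(1, 0, scale_sdlog)
      eps <- stats::rnorm(nrow(template), 0, noise_cv)
      tibble::tibble(
        cell = i,
        voltage_mV = template$voltage_mV,
        current = template$current * sc * (1 + eps)
      )
    })
  })
}

#' Calcium-channel subtype fractions
#'
#' The measured drug-sensitive fractions of the whole-cell calcium current.
#' Defaults are the OVX-state fractions (L 26.1%, N 25.1%, P/Q 3.9%,
#' R 31.1%, T 6.7%); `subtype_fractions("OVX_E2")` gives the E2-state set
#' (24.9 / 24.6 / 11.0 / 27.0 / 11.1%).
#'
#' @param group `"OVX"` or `"OVX_E2"`.
#' @return Named numeric vector of fractions (sum <= 1).
#' @export
subtype_fractions <- function(group = c("OVX", "OVX_E2")) {
  group <- match.arg(group)
  f <- if (group == "OVX") {
    c(L = 0.261, N = 0.251, `P/Q` = 0.039, R = 0.311, T = 0.067)
  } else {
    c(L = 0.249, N = 0.246, `P/Q` = 0.110, R = 0.270, T = 0.111)
  }
  stopifnot(all(f >= 0), sum(f) <= 1)
  f
}

#' Synthetic subtype-blocker experiment
#'
#' Paired control/drug I-V families: the drug curve is the control curve
#' scaled by `(1 - fraction_drug)`, per cell, with cell scale and per-voltage
#' noise as in [gen_iv_dataset()]. Peak-based analysis at -10 mV recovers
#' the designed fraction.
#'
#' @param template A `kndy_ivcurve` template (whole-cell calcium I-V).
#' @param fractions Named subtype fractions (see [subtype_fractions()]).
#' @param drug Which subtype the drug blocks (name into `fractions`).
#' @param n_cells Number of cells.
#' @param noise_cv Per-voltage noise CV.
#' @param seed Integer seed.
#' @return Tidy tibble: `cell`, `condition` (control/drug), `voltage_mV`,
#'   `current`.
#' @export
gen_blocker_experiment <- function(template, fractions, drug, n_cells = 8,
                                   noise_cv = 0.03, seed = 1) {
  if (!drug %in% names(fractions)) {
    stop("unknown drug target '", drug, "'; expected one of: ",
         paste(names(fractions), collapse = ", "), call. = FALSE)
  }
  frac <- fractions[[drug]]
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(i) {
      sc <- stats::rlnorm(1, 0, 0.2)
      eps <- stats::rnorm(nrow(template), 0, noise_cv)
      ctrl <- template$current * sc * (1 + eps)
      tibble::tibble(
        cell = i,
        voltage_mV = rep(template$voltage_mV, 2),
        condition = rep(c("control", "drug"), each = nrow(template)),
        current = c(ctrl, ctrl * (1 - frac))
      )
    })
  })
}

#' Recover a blocked fraction from a paired experiment
#'
#' Fraction = 1 - (mean drug peak) / (mean control peak), with the peak read
#' at the given voltage (default -10 mV, the whole-cell calcium peak).
#'
#' @param experiment Output of [gen_blocker_experiment()].
#' @param at_voltage Readout voltage (mV).
#' @return Recovered fraction.
#' @export
recover_blocked_fraction <- function(experiment, at_voltage = -10) {
  at <- dplyr::filter(experiment, .data$voltage_mV == at_voltage)
  means <- at |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(m = mean(.data$current))
  1 - means$m[means$condition == "drug"] / means$m[means$condition == "control"]
}

#' Synthetic normalized activation/inactivation points
#'
#' Boltzmann curve plus Gaussian noise, clipped to `[0, 1.05]`.
#'
#' @param v_half Midpoint (mV).
#' @param k Slope factor (mV; negative for a falling availability curve).
#' @param voltages Sample voltages (>= 4).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return Tibble: `voltage_mV`, `response`.
#' @examples
#' gen_activation_dataset(-32.3, 5, seq(-80, 0, 5), 0, seed = 1)
#' @export
gen_activation_dataset <- function(v_half, k, voltages, noise_sd = 0, seed = 1) {
  if (length(voltages) < 4) stop("need at least 4 voltages", call. = FALSE)
  y <- 1 / (1 + exp((v_half - voltages) / k))
  withr::with_seed(seed, {
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  })
  tibble::tibble(voltage_mV = voltages,
                 response = pmin(pmax(y, 0), 1.05))
}

#' Synthetic pooled qPCR dataset
#'
#' Generates 10-cell-pool CT values with the designed per-gene group fold
#' changes, an animal-level random effect and pool-level noise:
#' `CT_target = CT_ref + dCT_base - log2(fold) + animal + pool` noise.
#' The ddCT workflow applied to the output recovers the designed folds in
#' expectation.
#'
#' @param design Tibble with columns `gene`, `group`, `fold` (> 0; the
#'   control group rows should have fold 1).
#' @param ct_ref_mean Reference-gene mean CT.
#' @param dct_base Baseline dCT of each target gene (recycled).
#' @param sd_animal,sd_pool CT noise components (default 0.3 / 0.2 cycles).
#' @param n_animals Animals per group.
#' @param n_pools Pools per animal.
#' @param reference Reference gene name.
#' @param seed Integer seed.
#' @return Tidy tibble: `group`, `animal`, `pool`, `gene`, `ct`.
#' @export
gen_qpcr_dataset <- function(design, ct_ref_mean = 20, dct_base = 6,
                             sd_animal = 0.3, sd_pool = 0.2,
                             n_animals = 5, n_pools = 3,
                             reference = "Gapdh", seed = 1) {
  stopifnot(all(design$fold > 0))
  genes <- unique(design$gene)
  base <- stats::setNames(rep_len(dct_base, length(genes)), genes)
  withr::with_seed(seed, {
    purrr::map_dfr(unique(design$group), function(grp) {
      purrr::map_dfr(seq_len(n_animals), function(an) {
        a_eff <- stats::rnorm(length(genes), 0, sd_animal)
        names(a_eff) <- genes
        purrr::map_dfr(seq_len(n_pools), function(pl) {
          ct_ref <- ct_ref_mean + stats::rnorm(1, 0, sd_pool)
          rows <- dplyr::filter(design, .data$group == grp)
          tibble::tibble(
            group = grp, animal = paste0(grp, "_a", an), pool = pl,
            gene = c(reference, rows$gene),
            ct = c(ct_ref,
                   ct_ref + base[rows$gene] - log2(rows$fold) +
                     a_eff[rows$gene] + stats::rnorm(nrow(rows), 0, sd_pool))
          )
        })
      })
    })
  })
}

#' Write a generated dataset as tidy CSV with a schema header
#'
#' @param data A tibble.
#' @param path Output path.
#' @param spec Generation spec (list) recorded in `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path, spec = NULL) {
  utils::write.csv(data, path, row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(spec, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
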