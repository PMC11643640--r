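# Comparative-CT (delta-delta-CT) qPCR quantification utilities.

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/m) - 1`, where `m` is the slope of CT versus log10 template
#' dilution. A slope of `-1/log10(2)` (about -3.32) is exact doubling
#' (E = 1, i.e. 100%).
#'
#' @param slope Standard-curve slope (must be negative); vectorized.
#' @return A tibble: `slope`, `efficiency` (fraction), `percent` (rounded
#'   half-up to integer percent).
#' @examples
#' qpcr_efficiency(-3.352)$percent # 99
#' @export
qpcr_efficiency <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative", call. = FALSE)
  eff <- 10^(-1 / slope) - 1
  tibble::tibble(
    slope = slope,
    efficiency = eff,
    # round half-up, matching integer-percent reporting
    percent = floor(100 * eff + 0.5)
  )
}

#' Relative expression by the 2^-ddCT method
#'
#' `dCT = CT_target - CT_ref`; `ddCT = dCT - calibrator`;
#' `fold = 2^(-ddCT)`. One cycle of difference is a two-fold change in
#' expression. The calibrator is conventionally the mean dCT of the control
#' group.
#'
#' @param ct_target Target-gene CT values.
#' @param ct_reference Reference-gene (housekeeping) CT values, same length.
#' @param calibrator Calibrator dCT (scalar).
#' @return A tibble: `dct`, `ddct`, `fold_change`.
#' @examples
#' relative_expression_ddct(24, 20, calibrator = 4)$fold_change # 1
#' @export
relative_expression_ddct <- function(ct_target, ct_reference, calibrator = 0) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      !is.finite(calibrator)) {
    stop("CT values must be finite", call. = FALSE)
  }
  dct <- ct_target - ct_reference
  ddct <- dct - calibrator
  tibble::tibble(dct = dct, ddct = ddct, fold_change = 2^(-ddct))
}

#' Group-level ddCT analysis of a pooled qPCR dataset
#'
#' Applies the comparative-CT workflow to a tidy pool-level dataset: per-pool
#' dCT against the reference gene, calibrator = mean control-group dCT per
#' gene, fold change per pool, and group summaries.
#'
#' @param data Tidy tibble with columns `group`, `animal`, `pool`, `gene`,
#'   `ct`, and the reference gene named by `reference`.
#' @param reference Reference gene name (default `"Gapdh"`).
#' @param control_group Calibrator group label (default `"OVX"`).
#' @return A list with `pools` (per-pool fold changes) and `summary`
#'   (per group x gene mean fold change).
#' @export
ddct_analysis <- function(data, reference = "Gapdh", control_group = "OVX") {
  stopifnot(all(c("group", "animal", "pool", "gene", "ct") %in% names(data)))
  if (!reference %in% data$gene) {
    stop("reference gene '", reference, "' absent from data", call. = FALSE)
  }
  ref <- data |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::select("group", "animal", "pool", ct_ref = "ct")
  pools <- data |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::inner_join(ref, by = c("group", "animal", "pool")) |>
    dplyr::mutate(dct = .data$ct - .data$ct_ref)
  calib <- pools |>
    dplyr::filter(.data$group == control_group) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(calibrator = mean(.data$dct))
  pools <- pools |>
    dplyr::inner_join(calib, by = "gene") |>
    dplyr::mutate(ddct = .data$dct - .data$calibrator,
                  fold_change = 2^(-.data$ddct))
  summary <- pools |>
    dplyr::group_by(.data$group, .data$gene) |>
    dplyr::summarise(mean_fold = mean(.data$fold_change),
                     n_pools = dplyr::n(), .groups = "drop")
  list(pools = pools, summary = summary)
}
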