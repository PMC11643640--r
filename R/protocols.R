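# Declarative stimulation/recording programs: voltage-step families, the
# M-current deactivation protocol, current ramps, receptor-drive epochs, and
# pharmacological block.

new_step_protocol <- function(mode, holding, step_levels, step_duration,
                              prepulse = NULL, inter_sweep = 0, id = "step") {
  stopifnot(step_duration > 0, length(step_levels) > 0)
  structure(list(
    id = id, mode = mode, holding = holding,
    prepulse = prepulse, # list(level, duration) or NULL
    step_levels = step_levels, step_duration = step_duration,
    inter_sweep = inter_sweep
  ), class = c("kndy_step_protocol", "kndy_protocol_spec"))
}

#' Whole-cell calcium I-V protocol
#'
#' 150 ms voltage steps from a holding potential of -80 mV, in 10 mV
#' increments up to +30 mV. The peak inward current on the -10 mV step is the
#' standard density readout.
#'
#' @return A `kndy_step_protocol`.
#' @export
ca_iv_protocol <- function() {
  new_step_protocol(
    mode = "voltage", holding = -80,
    step_levels = seq(-80, 30, by = 10), step_duration = 150,
    inter_sweep = 2000, id = "ca_iv"
  )
}

#' Potassium-current step protocol
#'
#' 500 ms voltage steps from -60 to +40 mV in 10 mV increments, holding
#' -70 mV, delivered at 0.2 Hz (5 s between sweeps). End-of-step current is
#' the standard readout.
#'
#' @return A `kndy_step_protocol`.
#' @export
k_step_protocol <- function() {
  new_step_protocol(
    mode = "voltage", holding = -70,
    step_levels = seq(-60, 40, by = 10), step_duration = 500,
    inter_sweep = 5000, id = "k_step"
  )
}

#' M-current deactivation protocol
#'
#' 300 ms prepulse to -20 mV followed by 500 ms steps from -75 to -30 mV in
#' 5 mV increments. The deactivation relaxation amplitude is read per sweep
#' with [m_current_amplitude()].
#'
#' @return A `kndy_step_protocol`.
#' @export
m_deactivation_protocol <- function() {
  new_step_protocol(
    mode = "voltage", holding = -70,
    prepulse = list(level = -20, duration = 300),
    step_levels = seq(-75, -30, by = 5), step_duration = 500,
    inter_sweep = 3000, id = "m_deactivation"
  )
}

#' Current-ramp protocol
#'
#' Linearly increasing injected current, `I(t) = start + rate * t`, used to
#' read the rheobase from the first spike latency.
#'
#' @param rate Ramp rate in pA/s (> 0).
#' @param start Starting current (pA).
#' @param duration Ramp duration (ms).
#' @return A `kndy_ramp_protocol`.
#' @examples
#' ramp_protocol() # 50 pA/s over 2 s
#' @export
ramp_protocol <- function(rate = 50, start = 0, duration = 2000) {
  stopifnot(rate > 0, duration > 0)
  structure(list(id = "ramp", mode = "current", holding = 0,
                 rate = rate, start = start, duration = duration),
            class = c("kndy_ramp_protocol", "kndy_protocol_spec"))
}

#' Receptor-drive protocol
#'
#' Current-clamp epoch in which the NKB and/or dynorphin receptor drives
#' relax toward the given targets (1 = saturating) for `duration` ms
#' starting at `onset`, followed by `post` ms of recovery.
#'
#' @param nkb_target,dyn_target Drive targets in `[0, 1]`.
#' @param onset Pre-drive baseline (ms).
#' @param duration Drive duration (ms).
#' @param post Post-drive recording (ms).
#' @return A `kndy_drive_protocol`.
#' @export
drive_protocol <- function(nkb_target = 1, dyn_target = 0, onset = 1000,
                           duration = 10000, post = 3000) {
  stopifnot(nkb_target >= 0, nkb_target <= 1, dyn_target >= 0, dyn_target <= 1,
            duration > 0)
  structure(list(id = "drive", mode = "current", holding = 0,
                 nkb_target = nkb_target, dyn_target = dyn_target,
                 onset = onset, duration = duration, post = post),
            class = c("kndy_drive_protocol", "kndy_protocol_spec"))
}

#' Saturating-NKB synchronization protocol
#'
#' The model stand-in for 10 s of high-frequency (20 Hz) optogenetic NKB
#' release: a saturating NKB drive (`nkb_target = 1`) for 10 s.
#'
#' @param dyn_target Dynorphin drive target (default 0).
#' @return A `kndy_drive_protocol` with a 10 000 ms drive epoch.
#' @export
nkb_synch_protocol <- function(dyn_target = 0) {
  drive_protocol(nkb_target = 1, dyn_target = dyn_target,
                 onset = 1000, duration = 10000, post = 3000)
}

#' Pharmacological block
#'
#' Scales the named channel conductances by `(1 - fraction)`. Channel names:
#' NaT, NaP, A, BK, h, SK, M, T, Ca, TRPC5, GIRK, leak.
#'
#' @param params A [kndy_params] object.
#' @param block Named numeric vector of block fractions in `[0, 1]`,
#'   e.g. `c(SK = 1)` for complete SK block or `c(TRPC5 = 0.5)` for the
#'   CRISPR-like half-conductance state.
#' @return A modified copy of `params`; the input is untouched.
#' @examples
#' p <- kndy_params("OVX")
#' apply_block(p, c(SK = 1))[["g_SK"]]
#' @export
apply_block <- function(params, block) {
  stopifnot(inherits(params, "kndy_params"))
  if (length(block) == 0) return(params)
  bad <- setdiff(names(block), names(.kndy_channels))
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(.kndy_channels), collapse = ", "),
         call. = FALSE)
  }
  if (any(block < 0 | block > 1)) {
    stop("block fractions must lie in [0, 1]", call. = FALSE)
  }
  v <- unclass(params)
  for (ch in names(block)) {
    gname <- .kndy_channels[[ch]]
    v[[gname]] <- v[[gname]] * (1 - block[[ch]])
  }
  new_kndy_params(v, attr(params, "state_label"))
}

#' Recording-cocktail block (TTX/CNQX/AP5/picrotoxin)
#'
#' The synaptic blockers have no model correlate (no synaptic currents are
#' modelled); TTX zeroes both sodium conductances.
#'
#' @param params A [kndy_params] object.
#' @return Parameters with `g_NaT = g_NaP = 0`.
#' @export
recording_cocktail <- function(params) {
  apply_block(params, c(NaT = 1, NaP = 1))
}

# ---- conversion to executable segment tables -------------------------------

# A runnable protocol is a tibble of segments with columns:
# duration (ms), mode, level (mV command or pA base), rate (pA/s),
# nkb_target, dyn_target.
protocol_segments <- function(protocol, sweep_level = NULL) {
  UseMethod("protocol_segments")
}

#' @export
protocol_segments.kndy_step_protocol <- function(protocol, sweep_level = NULL) {
  stopifnot(!is.null(sweep_level))
  segs <- tibble::tibble(
    duration = 20, mode = protocol$mode, level = protocol$holding,
    rate = 0, nkb_target = 0, dyn_target = 0, epoch = "baseline"
  )
  if (!is.null(protocol$prepulse)) {
    segs <- dplyr::bind_rows(segs, tibble::tibble(
      duration = protocol$prepulse$duration, mode = protocol$mode,
      level = protocol$prepulse$level, rate = 0,
      nkb_target = 0, dyn_target = 0, epoch = "prepulse"
    ))
  }
  dplyr::bind_rows(segs, tibble::tibble(
    duration = protocol$step_duration, mode = protocol$mode,
    level = sweep_level, rate = 0, nkb_target = 0, dyn_target = 0,
    epoch = "step"
  ))
}

#' @export
protocol_segments.kndy_ramp_protocol <- function(protocol, sweep_level = NULL) {
  tibble::tibble(
    duration = protocol$duration, mode = "current", level = protocol$start,
    rate = protocol$rate, nkb_target = 0, dyn_target = 0, epoch = "ramp"
  )
}

#' @export
protocol_segments.kndy_drive_protocol <- function(protocol, sweep_level = NULL) {
  tibble::tibble(
    duration = c(protocol$onset, protocol$duration, protocol$post),
    mode = "current", level = 0, rate = 0,
    nkb_target = c(0, protocol$nkb_target, 0),
    dyn_target = c(0, protocol$dyn_target, 0),
    epoch = c("baseline", "drive", "post")
  ) |> dplyr::filter(.data$duration > 0)
}

#' Serialize / deserialize protocols
#'
#' Protocols share the YAML dialect of the parameter files.
#'
#' @param protocol A protocol object.
#' @param path File path.
#' @return `read_protocol_yaml()` rebuilds the protocol object.
#' @export
write_protocol_yaml <- function(protocol, path) {
  doc <- unclass(protocol)
  doc$class <- class(protocol)[1]
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  cls <- doc$class
  doc$class <- NULL
  if (is.null(cls)) stop("protocol file lacks a 'class' entry", call. = FALSE)
  structure(doc, class = c(cls, "kndy_protocol_spec"))
}
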