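# Numerical integration of the full model through deSolve, using the
# compiled right-hand side in src/kndy_model.c. All simulations are
# deterministic for fixed inputs; the optional Ornstein-Uhlenbeck background
# current is seeded and pre-sampled as a forcing series.

.kndy_state_names <- function() c("V", .kndy_gates, "Ca", "a_NKB", "a_Dyn")

# Flatten params + one segment's stimulus controls into the C parameter vector.
.c_parms <- function(params, mode, base = 0, rate = 0, t0 = 0,
                     nkb = 0, dyn = 0, ca_clamp = FALSE, noise = FALSE) {
  c(unclass(params),
    seg_mode = if (mode == "voltage") 1 else 0,
    seg_base = base, seg_rate = rate, seg_t0 = t0,
    seg_nkb = nkb, seg_dyn = dyn,
    seg_cacl = as.numeric(ca_clamp), seg_noise = as.numeric(noise))
}

.zero_forcing <- function(t0, t1) {
  cbind(c(t0 - 1, t1 + 1), c(0, 0))
}

# Exact-discretization Ornstein-Uhlenbeck path on a regular grid.
ou_path <- function(t0, t1, dt, sigma, tau, seed) {
  tt <- seq(t0, t1 + dt, by = dt)
  n <- length(tt)
  rho <- exp(-dt / tau)
  x <- numeric(n)
  withr::with_seed(seed, {
    z <- stats::rnorm(n)
    x[1] <- sigma * z[1]
    for (i in 2:n) x[i] <- rho * x[i - 1] + sigma * sqrt(1 - rho^2) * z[i]
  })
  cbind(tt, x)
}

.ode_once <- function(y0, times, parms, forcing, method, rtol, atol, hmax,
                      rk4_dt = 0.01) {
  if (method == "rk4") {
    # brute-force fixed-step integration on its own fine grid, then sampled
    # onto the requested output times
    grid <- seq(times[1], times[length(times)], by = rk4_dt)
    if (grid[length(grid)] < times[length(times)]) {
      grid <- c(grid, times[length(times)])
    }
    out <- deSolve::ode(
      y = y0, times = grid, func = "kndy_derivs", parms = parms,
      dllname = "kndysim", initfunc = "kndy_initparms",
      initforc = "kndy_initforc", forcings = forcing,
      nout = 13, outnames = c(.kndy_current_names, "total"),
      method = "rk4"
    )
    idx <- pmin(round((times - grid[1]) / rk4_dt) + 1, nrow(out))
    out[idx, , drop = FALSE]
  } else {
    deSolve::ode(
      y = y0, times = times, func = "kndy_derivs", parms = parms,
      dllname = "kndysim", initfunc = "kndy_initparms",
      initforc = "kndy_initforc", forcings = forcing,
      nout = 13, outnames = c(.kndy_current_names, "total"),
      method = method, rtol = rtol, atol = atol, hmax = hmax,
      maxsteps = 100000
    )
  }
}

#' Steady state at a holding condition
#'
#' Relaxes the model at a fixed holding condition (command voltage in
#' voltage clamp, injected current in current clamp) and returns the final
#' state vector. Gates start at their voltage steady state, which makes the
#' relaxation a pure tie-break refinement.
#'
#' @param params A [kndy_params] object.
#' @param holding Holding level: mV (`mode = "voltage"`) or pA
#'   (`mode = "current"`).
#' @param mode `"voltage"` or `"current"`.
#' @param duration Relaxation time (ms), default 5000.
#' @param V0 Starting potential for current clamp (mV).
#' @return Named state vector (V, 12 gates, Ca, a_NKB, a_Dyn).
#' @export
steady_state <- function(params, holding = 0, mode = "current",
                         duration = 5000, V0 = -65) {
  validate_kndy_params(params)
  Vstart <- if (mode == "voltage") holding else V0
  gates <- vapply(.kndy_gates, function(g) {
    steady_state_gate(Vstart, gating_spec_from_params(params, g))
  }, numeric(1))
  y0 <- c(V = Vstart, gates, Ca = unname(params[["Ca_rest"]]),
          a_NKB = 0, a_Dyn = 0)
  names(y0) <- .kndy_state_names()
  parms <- .c_parms(params, mode,
                    base = if (mode == "current") holding else 0)
  if (mode == "voltage") y0[["V"]] <- holding
  times <- seq(0, duration, length.out = max(4, ceiling(duration / 50)))
  out <- .ode_once(y0, times, parms,
                   .zero_forcing(0, duration), "lsoda", 1e-8, 1e-10, hmax = 5)
  y <- out[nrow(out), 1 + seq_along(y0)]
  names(y) <- .kndy_state_names()
  y
}

#' Simulate a protocol
#'
#' Integrates the full model over a runnable protocol (a ramp or drive
#' protocol, or a raw segment table) and returns a tidy trace. Step-family
#' protocols run one sweep per level through [simulate_sweeps()].
#'
#' The initial condition is the steady state obtained by relaxing the model
#' at the protocol's holding condition for `init_ms` (default 5 s), unless an
#' explicit `init_state` is given.
#'
#' @param params A [kndy_params] object.
#' @param protocol A `kndy_ramp_protocol`, `kndy_drive_protocol`, or segment
#'   tibble as produced by `kndysim:::protocol_segments()`.
#' @param dt_out Output sampling interval (ms), default 0.1.
#' @param method `"ode45"` (adaptive Runge-Kutta, default), `"lsoda"`, or
#'   `"rk4"` (fixed-step brute-force oracle with step `rk4_dt`).
#' @param rtol,atol,hmax Adaptive solver tolerances (defaults 1e-6, 1e-8,
#'   max step 1 ms).
#' @param rk4_dt Fixed step for `method = "rk4"` (ms).
#' @param init_ms Holding relaxation time (ms).
#' @param init_state Optional explicit initial state vector (overrides the
#'   holding relaxation).
#' @param noise Optional list `list(sigma = pA, tau = ms)` switching on the
#'   Ornstein-Uhlenbeck background current (current clamp only).
#' @param seed Integer seed, mandatory when `noise` is on.
#' @param ca_clamp If `TRUE`, cytosolic calcium is clamped at its initial
#'   value (BAPTA emulation).
#' @return A `kndy_trace` tibble with columns `time_ms`, `vm_mV`, `ca_uM`,
#'   `stim`, `a_nkb`, `a_dyn`, one column per current (pA) and `total`.
#' @examples
#' \donttest{
#' p <- kndy_params("OVX")
#' tr <- simulate_neuron(p, ramp_protocol(duration = 500), init_ms = 1000)
#' }
#' @export
simulate_neuron <- function(params, protocol, dt_out = 0.1,
                            method = c("ode45", "lsoda", "rk4"),
                            rtol = 1e-6, atol = 1e-8, hmax = 1, rk4_dt = 0.01,
                            init_ms = 5000, init_state = NULL,
                            noise = NULL, seed = NULL, ca_clamp = FALSE) {
  method <- match.arg(method)
  validate_kndy_params(params)
  segs <- if (inherits(protocol, "kndy_protocol_spec")) {
    if (inherits(protocol, "kndy_step_protocol")) {
      stop("step-family protocols run sweep-wise: use simulate_sweeps()",
           call. = FALSE)
    }
    protocol_segments(protocol)
  } else if (is.data.frame(protocol)) {
    protocol
  } else {
    stop("unsupported protocol object", call. = FALSE)
  }
  stopifnot(nrow(segs) >= 1, all(segs$duration > 0))
  proto_id <- if (inherits(protocol, "kndy_protocol_spec")) protocol$id else "segments"
  mode <- segs$mode[1]
  if (!all(segs$mode == mode)) {
    stop("mixed clamp modes within one protocol are not supported", call. = FALSE)
  }

  total_dur <- sum(segs$duration)
  use_noise <- !is.null(noise)
  if (use_noise) {
    if (is.null(seed)) stop("a seed is mandatory when noise is on", call. = FALSE)
    forcing <- ou_path(0, total_dur, dt = 0.5,
                       sigma = noise$sigma, tau = noise$tau, seed = seed)
  } else {
    forcing <- .zero_forcing(0, total_dur)
  }

  if (is.null(init_state)) {
    hold_mode <- mode
    holding <- if (inherits(protocol, "kndy_protocol_spec")) {
      protocol$holding
    } else if (mode == "voltage") segs$level[1] else 0
    init_state <- steady_state(params, holding, hold_mode, duration = init_ms)
  }

  y <- init_state
  if (ca_clamp) {
    # chelator emulation: calcium pinned at the nominal resting level from
    # the start of the recording
    y[["Ca"]] <- unname(params[["Ca_rest"]])
  }
  t_cursor <- 0
  pieces <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    t_end <- t_cursor + seg$duration
    times <- seq(t_cursor, t_end, by = dt_out)
    if (times[length(times)] < t_end) times <- c(times, t_end)
    parms <- .c_parms(
      params, seg$mode,
      base = if (seg$mode == "current") seg$level else 0,
      rate = seg$rate %||% 0, t0 = t_cursor,
      nkb = seg$nkb_target %||% 0, dyn = seg$dyn_target %||% 0,
      ca_clamp = ca_clamp, noise = use_noise && seg$mode == "current"
    )
    if (seg$mode == "voltage") y[["V"]] <- seg$level
    out <- .ode_once(y, times, parms, forcing, method, rtol, atol, hmax, rk4_dt)
    last <- out[nrow(out), -1]
    if (any(!is.finite(last))) {
      bad <- colnames(out)[-1][which(!is.finite(last))[1]]
      stop("simulation diverged (non-finite ", bad, ") in segment ", i,
           call. = FALSE)
    }
    y <- out[nrow(out), 1 + seq_along(y)]
    names(y) <- .kndy_state_names()
    # stimulus series for this segment
    stim <- if (seg$mode == "voltage") {
      rep(seg$level, nrow(out))
    } else {
      seg$level + (seg$rate %||% 0) * (out[, "time"] - t_cursor) / 1000
    }
    piece <- tibble::tibble(
      time_ms = out[, "time"],
      vm_mV = out[, "V"],
      ca_uM = out[, "Ca"],
      stim = stim,
      a_nkb = out[, "a_NKB"],
      a_dyn = out[, "a_Dyn"],
      epoch = seg$epoch %||% as.character(i)
    )
    for (cn in c(.kndy_current_names, "total")) piece[[cn]] <- out[, cn]
    if (i > 1) piece <- piece[-1, ]
    pieces[[i]] <- piece
    t_cursor <- t_end
  }
  trace <- dplyr::bind_rows(pieces)
  structure(trace,
            class = c("kndy_trace", class(trace)),
            mode = mode, protocol_id = proto_id,
            state_label = attr(params, "state_label"),
            C_m = unname(params[["C_m"]]),
            solver = list(method = method, rtol = rtol, atol = atol,
                          hmax = hmax, dt_out = dt_out, seed = seed))
}

#' Simulate a voltage/current step family
#'
#' Runs one sweep per step level; every sweep restarts from the holding
#' steady state (computed once), matching slow inter-sweep recovery.
#'
#' @param params A [kndy_params] object.
#' @param protocol A `kndy_step_protocol`.
#' @param ... Passed to [simulate_neuron()].
#' @return A `kndy_sweeps` tibble: the concatenated sweep traces with a
#'   `level` column.
#' @export
simulate_sweeps <- function(params, protocol, ...) {
  stopifnot(inherits(protocol, "kndy_step_protocol"))
  dots <- list(...)
  init_ms <- dots$init_ms %||% 5000
  init <- steady_state(params, protocol$holding, protocol$mode,
                       duration = init_ms)
  sweeps <- purrr::map(protocol$step_levels, function(lv) {
    segs <- protocol_segments(protocol, sweep_level = lv)
    tr <- simulate_neuron(params, segs, init_state = init, ...)
    tr$level <- lv
    tr
  })
  out <- dplyr::bind_rows(sweeps)
  structure(out,
            class = c("kndy_sweeps", "kndy_trace", class(tibble::tibble())),
            mode = protocol$mode, protocol_id = protocol$id,
            state_label = attr(params, "state_label"),
            C_m = unname(params[["C_m"]]),
            step_duration = protocol$step_duration)
}

#' Export a trace as tidy CSV with a JSON metadata sidecar
#'
#' @param trace A `kndy_trace`.
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(
    mode = attr(trace, "mode"),
    protocol_id = attr(trace, "protocol_id"),
    state_label = attr(trace, "state_label"),
    C_m = attr(trace, "C_m"),
    solver = attr(trace, "solver")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
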