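# Configuration-driven pipeline runner and run manifest, tying the stages
# (simulate, analyze, calibrate, scan, generate) together reproducibly.

.pipeline_stage_keys <- list(
  simulate = c("state", "protocol", "overrides", "block", "output", "dt_out",
               "init_ms", "method", "seed"),
  scan = c("state", "x_param", "y_param", "x_values", "y_values", "n",
           "protocol", "output", "boundary_output", "seed", "dt_out",
           "init_ms", "classes_a", "classes_b"),
  generate = c("kind", "spec", "output", "seed"),
  analyze = c("input", "operation", "output")
)

.known_protocols <- function(name) {
  switch(name,
    ca_iv = ca_iv_protocol(),
    k_step = k_step_protocol(),
    m_deactivation = m_deactivation_protocol(),
    ramp = ramp_protocol(),
    nkb_synch = nkb_synch_protocol(),
    nkb_dyn_synch = nkb_synch_protocol(dyn_target = 1),
    stop("unknown protocol name: ", name, call. = FALSE)
  )
}

.validate_stage <- function(stage) {
  kind <- stage$stage
  if (is.null(kind) || !kind %in% names(.pipeline_stage_keys)) {
    stop("config error: unknown or missing stage kind '", kind %||% "<none>",
         "'", call. = FALSE)
  }
  extra <- setdiff(setdiff(names(stage), "stage"),
                   .pipeline_stage_keys[[kind]])
  if (length(extra)) {
    stop("config error in '", kind, "' stage: unknown key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!is.null(stage$block)) {
    bad <- setdiff(names(stage$block), names(.kndy_channels))
    if (length(bad)) {
      stop("config error: invalid channel name(s) in pharmacology block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(stage)
}

.stage_params <- function(stage) {
  p <- kndy_params(stage$state %||% "OVX")
  if (!is.null(stage$overrides)) {
    p <- param_set(p, unlist(stage$overrides))
  }
  if (!is.null(stage$block)) {
    p <- apply_block(p, unlist(stage$block))
  }
  p
}

#' Run a configured pipeline
#'
#' Executes the stages listed in a YAML config (each a map with a `stage`
#' key: `simulate`, `scan` or `generate`), writes their outputs under
#' `out_dir`, and records a run manifest. Unknown config keys are errors,
#' not warnings, so protocol drift is loud. All stage seeds must be
#' explicit in the config; there is no silent default seed.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory (created if needed).
#' @return The manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config_path, out_dir = ".") {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    stop("config error: no stages", call. = FALSE)
  }
  lapply(cfg$stages, .validate_stage)
  for (st in cfg$stages) {
    if (st$stage %in% c("scan", "generate") && is.null(st$seed)) {
      stop("config error: stage '", st$stage, "' requires an explicit seed",
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)

  for (st in cfg$stages) {
    if (st$stage == "simulate") {
      p <- .stage_params(st)
      proto <- .known_protocols(st$protocol)
      out <- file.path(out_dir, st$output %||% "trace.csv")
      if (inherits(proto, "kndy_step_protocol")) {
        tr <- simulate_sweeps(p, proto, dt_out = st$dt_out %||% 0.1,
                              init_ms = st$init_ms %||% 5000)
      } else {
        tr <- simulate_neuron(p, proto, dt_out = st$dt_out %||% 0.1,
                              init_ms = st$init_ms %||% 5000)
      }
      write_trace_csv(tr, out)
      outputs <- c(outputs, out)
    } else if (st$stage == "scan") {
      p <- .stage_params(st)
      n <- st$n %||% 11
      xv <- if (!is.null(st$x_values)) unlist(st$x_values) else
        scan_axis(unclass(p)[[st$x_param]], n = n)
      yv <- if (!is.null(st$y_values)) unlist(st$y_values) else
        scan_axis(unclass(p)[[st$y_param]], n = n)
      grid <- scan_2d(p, st$x_param, xv, st$y_param, yv,
                      protocol = .known_protocols(st$protocol %||% "nkb_dyn_synch"),
                      seed = st$seed, dt_out = st$dt_out %||% 0.25,
                      init_ms = st$init_ms %||% 3000)
      out <- file.path(out_dir, st$output %||% "regime_grid.csv")
      bnd <- NULL
      bout <- NULL
      if (!is.null(st$classes_a) && !is.null(st$classes_b)) {
        bnd <- try(extract_boundary(grid, unlist(st$classes_a),
                                    unlist(st$classes_b)), silent = TRUE)
        if (inherits(bnd, "try-error")) bnd <- NULL
        bout <- file.path(out_dir, st$boundary_output %||% "boundary.json")
      }
      write_regime_grid(grid, out, boundary = bnd, json_path = bout)
      outputs <- c(outputs, out, if (!is.null(bnd)) bout)
    } else if (st$stage == "generate") {
      out <- file.path(out_dir, st$output %||% paste0(st$kind, ".csv"))
      dat <- switch(st$kind,
        activation = do.call(gen_activation_dataset,
                             c(st$spec, list(seed = st$seed))),
        qpcr = gen_qpcr_dataset(
          design = tibble::as_tibble(purrr::map_dfr(st$spec$design, tibble::as_tibble)),
          seed = st$seed),
        stop("unknown generate kind: ", st$kind, call. = FALSE)
      )
      write_dataset_csv(dat, out, spec = st$spec)
      outputs <- c(outputs, out)
    }
  }

  manifest <- list(
    command = "run_pipeline",
    config = normalizePath(config_path),
    config_hash = as.character(tools::md5sum(config_path)),
    package_version = as.character(utils::packageVersion("kndysim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
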