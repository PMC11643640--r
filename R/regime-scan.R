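# Two-dimensional conductance-space scans with firing-regime labels and
# boundary extraction between labelled regions.

#' Default log-spaced scan axis
#'
#' @param base Base conductance (nS).
#' @param n Number of points (>= 2).
#' @param lo,hi Multiplicative range (defaults 0.25x to 4x).
#' @return Numeric axis values.
#' @export
scan_axis <- function(base, n = 21, lo = 0.25, hi = 4) {
  exp(seq(log(base * lo), log(base * hi), length.out = n))
}

#' Two-dimensional conductance regime scan
#'
#' Simulates `protocol` at every grid point of two conductance axes and
#' classifies the firing mode during the drive/stimulus epoch. Cells are
#' independent; each gets a deterministic seed derived from
#' `(seed, i, j)`, so results do not depend on evaluation order. A diverging
#' simulation flags its cell (`label = "failed"`) and the scan continues.
#'
#' @param base Base [kndy_params].
#' @param x_param,y_param Conductance parameter names (e.g. `"g_TRPC5"`).
#' @param x_values,y_values Axis values (positive).
#' @param protocol Protocol simulated per cell (default: saturating NKB +
#'   dynorphin drive).
#' @param seed Integer seed.
#' @param classify_epoch Epoch used for classification (default `"drive"`;
#'   use `NULL` for the whole trace).
#' @param ... Passed to [simulate_neuron()].
#' @return A `kndy_regime_grid` tibble: `x`, `y`, `label`, `rate_Hz`,
#'   `n_bursts`, plus axis metadata attributes.
#' @export
scan_2d <- function(base, x_param, x_values, y_param, y_values,
                    protocol = nkb_synch_protocol(dyn_target = 1),
                    seed = 1, classify_epoch = "drive", ...) {
  stopifnot(inherits(base, "kndy_params"),
            x_param %in% names(unclass(base)),
            y_param %in% names(unclass(base)),
            all(x_values > 0), all(y_values > 0))
  grid <- tidyr::expand_grid(i = seq_along(x_values), j = seq_along(y_values))
  cells <- purrr::pmap_dfr(grid, function(i, j) {
    p <- param_set(base, stats::setNames(c(x_values[i], y_values[j]),
                                         c(x_param, y_param)))
    cell_seed <- (seed * 10007L + i * 101L + j) %% .Machine$integer.max
    tr <- try(simulate_neuron(p, protocol, seed = cell_seed, ...),
              silent = TRUE)
    if (inherits(tr, "try-error")) {
      return(tibble::tibble(x = x_values[i], y = y_values[j],
                            label = "failed", rate_Hz = NA_real_,
                            n_bursts = NA_integer_))
    }
    sub <- if (!is.null(classify_epoch)) {
      dplyr::filter(tr, .data$epoch == classify_epoch)
    } else tr
    cls <- classify_firing(detect_spikes(sub), sub)
    tibble::tibble(x = x_values[i], y = y_values[j],
                   label = cls$label, rate_Hz = cls$rate_Hz,
                   n_bursts = cls$n_bursts)
  })
  structure(cells, class = c("kndy_regime_grid", class(tibble::tibble())),
            x_param = x_param, y_param = y_param,
            x_values = x_values, y_values = y_values, seed = seed)
}

#' Extract the boundary between two labelled regions
#'
#' Marching-edge midpoints between adjacent grid cells carrying the two
#' labels, ordered along the dominant axis. A grid whose boundary is not a
#' simple curve (e.g. checkerboard labelling) is flagged.
#'
#' @param grid A `kndy_regime_grid`.
#' @param class_a,class_b The two labels (or two character vectors of labels
#'   to pool, e.g. `c("tonic", "irregular")` vs `"silent"`).
#' @return A `kndy_boundary` tibble of ordered midpoints (`x`, `y`) with a
#'   `simple` attribute (TRUE when each x column crosses at most once).
#' @export
extract_boundary <- function(grid, class_a, class_b) {
  lab <- ifelse(grid$label %in% class_a, "a",
                ifelse(grid$label %in% class_b, "b", NA))
  if (!any(lab == "a", na.rm = TRUE) || !any(lab == "b", na.rm = TRUE)) {
    stop("both classes must be present in the grid", call. = FALSE)
  }
  d <- grid
  d$lab <- lab
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y))
  pts <- list()
  # vertical edges (neighbours along x)
  for (k in seq_len(length(xs) - 1)) {
    a <- d[d$x == xs[k], ]; b <- d[d$x == xs[k + 1], ]
    m <- dplyr::inner_join(a, b, by = "y", suffix = c("_1", "_2"))
    hit <- !is.na(m$lab_1) & !is.na(m$lab_2) & m$lab_1 != m$lab_2
    if (any(hit)) {
      pts[[length(pts) + 1]] <- tibble::tibble(
        x = sqrt(xs[k] * xs[k + 1]), y = m$y[hit])
    }
  }
  # horizontal edges (neighbours along y)
  for (k in seq_len(length(ys) - 1)) {
    a <- d[d$y == ys[k], ]; b <- d[d$y == ys[k + 1], ]
    m <- dplyr::inner_join(a, b, by = "x", suffix = c("_1", "_2"))
    hit <- !is.na(m$lab_1) & !is.na(m$lab_2) & m$lab_1 != m$lab_2
    if (any(hit)) {
      pts[[length(pts) + 1]] <- tibble::tibble(
        x = m$x[hit], y = sqrt(ys[k] * ys[k + 1]))
    }
  }
  if (!length(pts)) {
    stop("classes never adjacent: no boundary", call. = FALSE)
  }
  out <- dplyr::distinct(dplyr::arrange(dplyr::bind_rows(pts),
                                        .data$x, .data$y))
  # simple if, per x column of the grid, the a/b labelling crosses at most once
  simple <- all(vapply(split(lab, d$x), function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) return(TRUE)
    sum(col[-1] != col[-length(col)]) <= 1
  }, logical(1)))
  structure(out, class = c("kndy_boundary", class(tibble::tibble())),
            simple = simple)
}

#' Write a regime grid and its boundary to disk
#'
#' @param grid A `kndy_regime_grid`.
#' @param csv_path Grid CSV path.
#' @param boundary Optional `kndy_boundary`.
#' @param json_path Boundary JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_regime_grid <- function(grid, csv_path, boundary = NULL,
                              json_path = NULL) {
  utils::write.csv(as.data.frame(grid), csv_path, row.names = FALSE)
  if (!is.null(boundary) && !is.null(json_path)) {
    jsonlite::write_json(
      list(points = as.data.frame(boundary),
           simple = isTRUE(attr(boundary, "simple"))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
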