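#' Construct a conformational descriptor series
#'
#' A scalar per-frame descriptor of a residue's conformation — typically a
#' distance in angstroms (e.g. a sidechain hydroxyl to a phosphate oxygen)
#' or a sidechain dihedral in degrees. Dihedrals are periodic; distances
#' are not.
#'
#' @param values Ordered numeric vector, one value per trajectory frame.
#' @param periodic Whether the descriptor wraps (dihedral angles).
#' @param period Period in the descriptor's units (360 for dihedrals).
#' @return A tibble of class `descriptor_series` with columns `frame`,
#'   `value`.
#' @export
descriptor_series <- function(values, periodic = FALSE, period = 360) {
  if (length(values) < 1L) rlang::abort("Descriptor series is empty.")
  if (any(!is.finite(values))) {
    rlang::abort("Descriptor values must be finite.")
  }
  out <- tibble::tibble(frame = seq_along(values),
                        value = as.numeric(values))
  attr(out, "periodic") <- isTRUE(periodic)
  attr(out, "period") <- as.numeric(period)
  class(out) <- c("descriptor_series", class(out))
  out
}

wrap_periodic <- function(x, period) {
  ((x + period / 2) %% period) - period / 2
}

#' Identify conformational states from a 1-D descriptor histogram
#'
#' Histograms the descriptor (with periodic wrap-around when flagged) and
#' takes each maximal contiguous run of occupied bins as one state, so
#' states are separated by empty histogram regions around each local mode.
#' States whose occupancy falls below `min_occupancy` are merged into the
#' state with the nearest mode. Every frame belongs to exactly one state
#' and occupancies sum to 1.
#'
#' @param series A `descriptor_series` (or numeric vector, treated as
#'   non-periodic).
#' @param n_bins Number of histogram bins. Default: 72 for periodic
#'   descriptors (5-degree bins for dihedrals), otherwise the bin count
#'   implied by a 0.2-unit bin width over the data range (at least 2).
#' @param min_occupancy States below this occupancy fraction are merged
#'   into their nearest neighbor (default 0.01), suppressing noise states.
#' @return A `conf_states` object: `states` (tibble of `state`,
#'   `occupancy`, `mode`), `dominant` (label), `assignments` (per-frame
#'   state), plus binning metadata.
#' @export
histogram_states <- function(series, n_bins = NULL, min_occupancy = 0.01) {
  if (!is.data.frame(series)) series <- descriptor_series(series)
  periodic <- isTRUE(attr(series, "periodic"))
  period <- attr(series, "period") %||% 360
  x <- series$value
  if (periodic) x <- wrap_periodic(x, period)
  if (is.null(n_bins)) {
    n_bins <- if (periodic) 72L else max(2L, ceiling(diff(range(x)) / 0.2))
  }
  if (n_bins < 2L) rlang::abort("`n_bins` must be >= 2.")
  if (min_occupancy < 0 || min_occupancy >= 0.5) {
    rlang::abort("`min_occupancy` must be in [0, 0.5).")
  }

  if (periodic) {
    lo <- -period / 2
    hi <- period / 2
  } else {
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) { # constant series: single degenerate state
      states <- tibble::tibble(state = "S1", occupancy = 1, mode = lo)
      return(new_conf_states(states, rep("S1", length(x)), series))
    }
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  occupied <- counts > 0
  run_id <- integer(n_bins)
  cur <- 0L
  for (b in seq_len(n_bins)) {
    if (occupied[b]) {
      if (b == 1L || !occupied[b - 1L]) cur <- cur + 1L
      run_id[b] <- cur
    }
  }
  # periodic wrap: a run touching the last bin continues into the first
  if (periodic && cur > 1L && occupied[1L] && occupied[n_bins]) {
    run_id[run_id == cur] <- run_id[1L]
    ids <- sort(unique(run_id[run_id > 0]))
    run_id[run_id > 0] <- match(run_id[run_id > 0], ids)
  }

  frame_run <- run_id[bin]
  runs <- sort(unique(frame_run))
  mode_of <- function(r) {
    bins_r <- which(run_id == r)
    centers[bins_r[which.max(counts[bins_r])]]
  }
  occ <- vapply(runs, function(r) mean(frame_run == r), numeric(1))
  modes <- vapply(runs, mode_of, numeric(1))

  # merge sub-threshold states into the nearest mode (periodic-aware)
  state_of_run <- stats::setNames(seq_along(runs), runs)
  repeat {
    groups <- split(seq_along(runs), state_of_run)
    g_occ <- vapply(groups, function(ix) sum(occ[ix]), numeric(1))
    weak <- names(groups)[g_occ < min_occupancy & length(groups) > 1]
    if (length(weak) == 0L || length(groups) <= 1L) break
    w <- weak[which.min(g_occ[weak])]
    w_mode <- modes[groups[[w]][which.max(occ[groups[[w]]])]]
    others <- setdiff(names(groups), w)
    d <- vapply(others, function(o) {
      om <- modes[groups[[o]][which.max(occ[groups[[o]]])]]
      dd <- abs(om - w_mode)
      if (periodic) dd <- min(dd, period - dd)
      dd
    }, numeric(1))
    state_of_run[state_of_run == as.integer(w)] <- as.integer(others[which.min(d)])
  }

  final_ids <- sort(unique(state_of_run))
  labels <- paste0("S", seq_along(final_ids))
  lab_of_run <- labels[match(state_of_run, final_ids)]
  assignments <- lab_of_run[match(frame_run, runs)]

  states <- purrr::map_dfr(seq_along(final_ids), function(k) {
    ix <- which(state_of_run == final_ids[k])
    tibble::tibble(
      state = labels[k],
      occupancy = sum(occ[ix]),
      mode = modes[ix[which.max(occ[ix])]]
    )
  })
  states <- dplyr::arrange(states, dplyr::desc(.data$occupancy),
                           .data$mode)
  new_conf_states(states, assignments, series)
}

new_conf_states <- function(states, assignments, series) {
  dom <- dominant_label(states)
  structure(
    list(
      states = states,
      dominant = dom,
      assignments = assignments,
      series = series,
      representative_index = NA_integer_
    ),
    class = "conf_states"
  )
}

dominant_label <- function(states) {
  best <- max(states$occupancy)
  cand <- states[states$occupancy == best, ]
  cand$state[which.min(cand$mode)]
}

#' Label of the most populated conformational state
#'
#' Ties are broken toward the state with the lower mode value.
#'
#' @param summary A `conf_states` object.
#' @return The dominant state's label.
#' @export
dominant_state <- function(summary) {
  if (nrow(summary$states) < 1L) rlang::abort("No states in summary.")
  dominant_label(summary$states)
}

#' Representative frame of a conformational state
#'
#' Returns the index of the frame (restricted to the state's members)
#' whose descriptor value is nearest the state's mode; the earliest frame
#' wins ties. Starting an alchemical transformation from a structure
#' representative of the most populated state avoids biasing the estimate
#' with a rarely-visited conformation.
#'
#' @param series The `descriptor_series` the summary was built from.
#' @param summary A `conf_states` object.
#' @param state State label; defaults to the dominant state.
#' @return A frame index into `series`.
#' @export
representative_frame <- function(series, summary, state = NULL) {
  state <- state %||% summary$dominant
  if (!state %in% summary$states$state) {
    rlang::abort(sprintf("State '%s' not present in summary.", state))
  }
  members <- which(summary$assignments == state)
  if (length(members) == 0L) {
    rlang::abort(sprintf("State '%s' has no member frames.", state))
  }
  mode <- summary$states$mode[summary$states$state == state]
  vals <- series$value[members]
  if (isTRUE(attr(series, "periodic"))) {
    period <- attr(series, "period") %||% 360
    d <- abs(wrap_periodic(vals, period) - mode)
    d <- pmin(d, period - d)
  } else {
    d <- abs(vals - mode)
  }
  members[which.min(d)]
}

#' @export
print.conf_states <- function(x, ...) {
  cat(sprintf("<conf_states> %d state(s), dominant %s\n",
              nrow(x$states), x$dominant))
  for (i in seq_len(nrow(x$states))) {
    cat(sprintf("  %s: occupancy %.3f, mode %.3f\n",
                x$states$state[i], x$states$occupancy[i], x$states$mode[i]))
  }
  invisible(x)
}

#' Tidy a conformational-state summary
#'
#' @param x A `conf_states` object.
#' @param ... Unused.
#' @return The per-state tibble (`state`, `occupancy`, `mode`) with a
#'   `dominant` flag column.
#' @method tidy conf_states
#' @export
tidy.conf_states <- function(x, ...) {
  dplyr::mutate(x$states, dominant = .data$state == x$dominant)
}
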