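#' Construct a dV/dlambda time series
#'
#' A `dvdl_series` is an ordered tibble of dV/dlambda samples from one
#' alchemical window, carrying the window's lambda value and the time per
#' sample as attributes.
#'
#' @param samples Numeric vector of dV/dlambda values (kcal/mol), in
#'   simulation order.
#' @param lambda The window's coupling value, in (0, 1).
#' @param dt Time per sample (metadata only; arbitrary units).
#' @return A tibble of class `dvdl_series` with columns `step` and `dvdl`.
#' @export
dvdl_series <- function(samples, lambda, dt = 1) {
  if (length(samples) < 1L) rlang::abort("A dvdl series needs >= 1 sample.")
  if (any(!is.finite(samples))) rlang::abort("dvdl samples must be finite.")
  out <- tibble::tibble(step = seq_along(samples), dvdl = as.numeric(samples))
  attr(out, "lambda") <- as.numeric(lambda)
  attr(out, "dt") <- as.numeric(dt)
  class(out) <- c("dvdl_series", class(out))
  out
}

series_lambda <- function(series) attr(series, "lambda")

#' Discard the equilibration transient of a window
#'
#' Removes the first `floor(fraction * N)` samples of the series. The
#' conventional discard is the first 10\% of the simulation time of each
#' window, applied to every window independently.
#'
#' @param series A `dvdl_series` (or numeric vector).
#' @param fraction Fraction of samples to discard, in \[0, 1).
#' @return The truncated series (same class as the input).
#' @export
discard_equilibration <- function(series, fraction = 0.1) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1) {
    rlang::abort("`fraction` must be a single value in [0, 1).")
  }
  x <- if (is.data.frame(series)) series$dvdl else series
  n_drop <- floor(fraction * length(x))
  if (n_drop >= length(x)) rlang::abort("Discard would empty the series.")
  kept <- if (n_drop == 0L) x else x[-seq_len(n_drop)]
  if (is.data.frame(series)) {
    dvdl_series(kept,
                lambda = attr(series, "lambda"),
                dt = attr(series, "dt") %||% 1)
  } else {
    kept
  }
}

#' Statistical inefficiency of an autocorrelated series
#'
#' Estimates the statistical inefficiency \eqn{g = 1 + 2 \sum_t C(t)},
#' where \eqn{C(t)} is the normalized autocovariance function, summed over
#' increasing lags until its first crossing below zero (a simple, robust
#' truncation for series of the lengths produced by lambda-window
#' simulations). `g` is the factor by which autocorrelation reduces the
#' effective number of independent samples; it is clamped to >= 1. For an
#' AR(1) process with coefficient \eqn{\phi} the true value is
#' \eqn{(1+\phi)/(1-\phi)}.
#'
#' @param x Numeric vector (or `dvdl_series`) of length >= 2 with nonzero
#'   variance.
#' @return The statistical inefficiency (dimensionless, >= 1).
#' @export
statistical_inefficiency <- function(x) {
  if (is.data.frame(x)) x <- x$dvdl
  n <- length(x)
  if (n < 2L) rlang::abort("Need >= 2 samples to estimate inefficiency.")
  x <- x - mean(x)
  c0 <- sum(x * x) / n
  if (c0 == 0) {
    rlang::abort("Series is constant; statistical inefficiency undefined.")
  }
  g <- 1
  for (t in seq_len(n - 1L)) {
    ct <- sum(x[seq_len(n - t)] * x[(t + 1L):n]) / ((n - t) * c0)
    if (ct <= 0) break
    g <- g + 2 * ct
  }
  max(g, 1)
}

#' Indices of an approximately uncorrelated subsample
#'
#' Picks every `ceiling(g)`-th frame starting from the first retained
#' frame, yielding samples separated by at least one statistical
#' inefficiency.
#'
#' @param series A `dvdl_series` or numeric vector.
#' @param g Statistical inefficiency (>= 1).
#' @return Integer vector of 1-based indices (always contains index 1).
#' @export
subsample_uncorrelated <- function(series, g) {
  x <- if (is.data.frame(series)) series$dvdl else series
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 1) {
    rlang::abort("`g` must be a single finite value >= 1.")
  }
  seq.int(1L, length(x), by = as.integer(ceiling(g)))
}

#' Per-window summary statistics of a dV/dlambda series
#'
#' Discards the equilibration transient, computes the mean over all
#' retained samples, estimates the statistical inefficiency `g`, subsamples
#' the series at stride `ceiling(g)`, and reports the standard error of the
#' mean from the variance (n - 1 denominator) of the uncorrelated
#' subsample divided by its size.
#'
#' @param series A `dvdl_series` (or numeric vector).
#' @param equilibration_fraction Fraction of each window discarded as
#'   equilibration (default 0.1).
#' @return A one-row tibble with columns `lambda`, `n`, `mean`, `sem`, `g`
#'   and `n_eff` (effective sample count N / g).
#' @export
window_stats <- function(series, equilibration_fraction = 0.1) {
  lam <- if (is.data.frame(series)) series_lambda(series) else NA_real_
  x <- if (is.data.frame(series)) series$dvdl else series
  x <- discard_equilibration(x, equilibration_fraction)
  if (length(x) < 2L) {
    rlang::abort("Fewer than 2 samples remain after equilibration discard.")
  }
  if (stats::var(x) == 0) {
    # zero-variance window (e.g. a null transformation with dV/dl == 0):
    # the mean is exact
    return(tibble::tibble(lambda = lam %||% NA_real_, n = length(x),
                          mean = x[1], sem = 0, g = 1,
                          n_eff = length(x)))
  }
  g <- statistical_inefficiency(x)
  idx <- subsample_uncorrelated(x, g)
  sub <- x[idx]
  sem <- if (length(sub) >= 2L) stats::sd(sub) / sqrt(length(sub)) else NA_real_
  tibble::tibble(
    lambda = lam %||% NA_real_,
    n = length(x),
    mean = mean(x),
    sem = sem,
    g = g,
    n_eff = length(x) / g
  )
}

#' Forward/reverse convergence profile of a cycle estimate
#'
#' Recomputes the thermodynamic-cycle ddG on growing prefixes (forward) or
#' suffixes (reverse) of every window's post-equilibration data. Agreement
#' of the forward and reverse profiles as the fraction approaches 1 is the
#' standard visual check that the per-window sampling is stationary.
#'
#' @param complex_windows,apo_windows Lists of `dvdl_series`, one per
#'   schedule node, in node order, for the complex and apo legs.
#' @param schedule The `lambda_schedule` shared by both legs.
#' @param n_chunks Number of cumulative time fractions to evaluate.
#' @param direction `"forward"`, `"reverse"`, or `"both"`.
#' @param equilibration_fraction Per-window discard fraction.
#' @return A tibble with columns `direction`, `fraction`, `ddg` and
#'   `sigma` (kcal/mol).
#' @export
convergence_profile <- function(complex_windows, apo_windows, schedule,
                                n_chunks = 10,
                                direction = c("both", "forward", "reverse"),
                                equilibration_fraction = 0.1) {
  direction <- rlang::arg_match(direction)
  if (!is.numeric(n_chunks) || n_chunks < 1) {
    rlang::abort("`n_chunks` must be >= 1.")
  }
  validate_schedule(schedule)
  dirs <- if (direction == "both") c("forward", "reverse") else direction

  trimmed <- function(windows) {
    purrr::map(windows, function(w) {
      x <- if (is.data.frame(w)) w$dvdl else w
      discard_equilibration(x, equilibration_fraction)
    })
  }
  cw <- trimmed(complex_windows)
  aw <- trimmed(apo_windows)

  leg_dg <- function(wins, frac, dir) {
    ms <- purrr::map_dbl(wins, function(x) {
      k <- max(2L, floor(frac * length(x)))
      if (k > length(x)) k <- length(x)
      if (k < 2L) rlang::abort("Convergence chunk shorter than 2 samples.")
      part <- if (dir == "forward") x[seq_len(k)] else x[(length(x) - k + 1L):length(x)]
      mean(part)
    })
    ss <- purrr::map_dbl(wins, function(x) {
      k <- max(2L, floor(frac * length(x)))
      part <- if (dir == "forward") x[seq_len(k)] else x[(length(x) - k + 1L):length(x)]
      st <- window_stats(part, equilibration_fraction = 0)
      st$sem
    })
    c(ti_integrate(schedule, ms), ti_error(schedule, ss))
  }

  purrr::map_dfr(dirs, function(dir) {
    purrr::map_dfr(seq_len(n_chunks), function(k) {
      frac <- k / n_chunks
      cx <- leg_dg(cw, frac, dir)
      ap <- leg_dg(aw, frac, dir)
      tibble::tibble(
        direction = dir,
        fraction = frac,
        ddg = cx[1] - ap[1],
        sigma = sqrt(cx[2]^2 + ap[2]^2)
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
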