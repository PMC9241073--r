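#' Gauss-Legendre lambda schedule
#'
#' Build an `n`-point Gauss-Legendre quadrature schedule on the alchemical
#' coupling interval (0, 1): the standard nodes and weights on \[-1, 1\] are
#' affinely mapped to \[0, 1\] (weights halved), so the weights sum to 1 and
#' the rule integrates polynomials up to degree 2n - 1 exactly. The
#' twelve-point rule is the schedule commonly used for side-chain
#' alchemical transformations (first nodes 0.00922, 0.04794, 0.11505;
#' first weights 0.02359, 0.05347, 0.08004).
#'
#' @param n Number of lambda windows (positive integer).
#' @return A tibble of class `lambda_schedule` with columns `lambda` and
#'   `weight`, ordered by increasing `lambda`.
#' @examples
#' gauss_legendre_schedule(12)
#' gauss_legendre_schedule(1) # midpoint rule: lambda 0.5, weight 1
#' @export
gauss_legendre_schedule <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    rlang::abort("`n` must be a single positive integer.")
  }
  n <- as.integer(n)
  if (n == 1L) {
    # pracma's recurrence needs n >= 2; the one-point rule is the midpoint
    sched <- tibble::tibble(lambda = 0.5, weight = 1)
  } else {
    gl <- pracma::gaussLegendre(n, 0, 1)
    sched <- tibble::tibble(lambda = gl$x, weight = gl$w)
  }
  new_lambda_schedule(sched)
}

new_lambda_schedule <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("lambda_schedule", class(x))
  x
}

#' Validate a lambda schedule
#'
#' Checks that nodes lie strictly inside (0, 1) and strictly increase, that
#' every weight is positive, and that the weights sum to 1 within `tol`.
#'
#' @param schedule A data frame with columns `lambda` and `weight`.
#' @param tol Tolerance on the weight sum (default 1e-4).
#' @return The schedule, invisibly, as a `lambda_schedule`; aborts on any
#'   violation.
#' @export
validate_schedule <- function(schedule, tol = 1e-4) {
  if (!all(c("lambda", "weight") %in% names(schedule))) {
    rlang::abort("A schedule needs `lambda` and `weight` columns.")
  }
  lam <- schedule$lambda
  w <- schedule$weight
  if (length(lam) < 1L) rlang::abort("Schedule is empty.")
  if (any(!is.finite(lam)) || any(!is.finite(w))) {
    rlang::abort("Schedule contains non-finite values.")
  }
  if (any(lam <= 0) || any(lam >= 1)) {
    rlang::abort("Lambda nodes must lie strictly inside (0, 1).")
  }
  if (is.unsorted(lam, strictly = TRUE)) {
    rlang::abort("Lambda nodes must be strictly increasing.")
  }
  if (any(w <= 0)) rlang::abort("Quadrature weights must be positive.")
  if (abs(sum(w) - 1) > tol) {
    rlang::abort(sprintf(
      "Quadrature weights sum to %.6f; expected 1 within %g.", sum(w), tol
    ))
  }
  invisible(new_lambda_schedule(schedule))
}

#' Thermodynamic-integration estimate of a free-energy change
#'
#' Approximates \eqn{\Delta G = \int_0^1 \langle \partial V / \partial
#' \lambda \rangle \, d\lambda} by the quadrature sum \eqn{\sum_i w_i
#' \langle \partial V/\partial\lambda \rangle_i} over the schedule's
#' windows. The estimator consumes per-window means only; per-window
#' statistics (equilibration discard, subsampling) are handled upstream by
#' [window_stats()].
#'
#' @param schedule A `lambda_schedule` (or data frame with `lambda`,
#'   `weight`), one row per window.
#' @param window_means Numeric vector of per-window mean dV/dlambda values
#'   (kcal/mol), one per schedule node, in node order.
#' @return The free-energy change in kcal/mol (length-1 numeric).
#' @seealso [ti_error()] for the matching uncertainty propagation.
#' @export
ti_integrate <- function(schedule, window_means) {
  validate_schedule(schedule)
  if (length(window_means) != nrow(schedule)) {
    rlang::abort(sprintf(
      "Got %d window means for a %d-node schedule.",
      length(window_means), nrow(schedule)
    ))
  }
  if (any(!is.finite(window_means))) {
    rlang::abort("Window means must be finite.")
  }
  sum(schedule$weight * window_means)
}

#' Propagated quadrature error of a TI estimate
#'
#' Treats the per-window means as independent and propagates their standard
#' errors through the quadrature sum:
#' \eqn{\sigma_{\Delta G} = \sqrt{\sum_i w_i^2 \sigma_i^2}}.
#'
#' @inheritParams ti_integrate
#' @param window_sems Numeric vector of per-window standard errors
#'   (kcal/mol), one per node, all non-negative.
#' @return One standard error on the TI estimate, kcal/mol.
#' @export
ti_error <- function(schedule, window_sems) {
  validate_schedule(schedule)
  if (length(window_sems) != nrow(schedule)) {
    rlang::abort(sprintf(
      "Got %d window SEMs for a %d-node schedule.",
      length(window_sems), nrow(schedule)
    ))
  }
  if (any(!is.finite(window_sems)) || any(window_sems < 0)) {
    rlang::abort("Window SEMs must be finite and non-negative.")
  }
  sqrt(sum(schedule$weight^2 * window_sems^2))
}
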