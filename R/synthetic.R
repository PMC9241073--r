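#' Synthetic dV/dlambda windows with analytic ground truth
#'
#' Emulates the per-window output of an alchemical MD run: at each
#' schedule node the samples follow a smooth polynomial mean profile
#' m(lambda), plus stationary AR(1) noise (modelling the autocorrelation
#' of real dV/dlambda series), plus an exponentially decaying
#' equilibration transient confined to the first fraction of each window.
#' The exact free-energy change is the analytic integral of m over
#' \[0, 1\], returned alongside the data so pipeline recovery can be
#' asserted against ground truth.
#'
#' @param schedule A `lambda_schedule`.
#' @param coefs Polynomial coefficients of m(lambda) in increasing order
#'   (kcal/mol): `m(l) = coefs[1] + coefs[2] l + ...`.
#' @param noise_sigma Stationary standard deviation of the AR(1) noise
#'   (kcal/mol).
#' @param ar1_phi AR(1) coefficient in \[0, 1); the default 0.9 gives a
#'   statistical inefficiency near 19, a realistic stress level.
#' @param equilibration_offset Initial bias (kcal/mol) decaying over the
#'   first `equilibration_fraction` of each window.
#' @param equilibration_fraction Fraction of the window affected by the
#'   transient (default 0.1, matching the conventional discard).
#' @param samples_per_window Samples per window.
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @return A list: `windows` (list of `dvdl_series`, one per node),
#'   `truth` (exact Delta G, kcal/mol), `schedule`.
#' @export
gen_dvdl_profile <- function(schedule, coefs = c(0, 2),
                             noise_sigma = 1, ar1_phi = 0.9,
                             equilibration_offset = 0,
                             equilibration_fraction = 0.1,
                             samples_per_window = 1000, seed = 1) {
  validate_schedule(schedule)
  if (abs(ar1_phi) >= 1) rlang::abort("`ar1_phi` must satisfy |phi| < 1.")
  if (noise_sigma < 0) rlang::abort("`noise_sigma` must be >= 0.")
  withr::local_seed(seed)
  n <- samples_per_window
  tau <- max(1, equilibration_fraction * n / 5)
  windows <- purrr::map(schedule$lambda, function(lam) {
    m <- sum(coefs * lam^(seq_along(coefs) - 1))
    noise <- if (noise_sigma > 0) {
      innov <- stats::rnorm(n, sd = sqrt(1 - ar1_phi^2) * noise_sigma)
      as.numeric(stats::filter(innov, ar1_phi, method = "recursive",
                               init = stats::rnorm(1, sd = noise_sigma)))
    } else {
      numeric(n)
    }
    transient <- equilibration_offset * exp(-(seq_len(n) - 1) / tau)
    dvdl_series(m + noise + transient, lambda = lam)
  })
  truth <- sum(coefs / seq_along(coefs))
  list(windows = windows, truth = truth, schedule = schedule)
}

# Scalar Metropolis random walk; proposals and acceptance draws are
# pre-generated so only the density evaluation sits in the loop.
metropolis_chain <- function(n_steps, x0, step, logf) {
  x <- numeric(n_steps)
  cur <- x0
  lcur <- logf(cur)
  prop <- stats::runif(n_steps, -step, step)
  lu <- log(stats::runif(n_steps))
  n_acc <- 0L
  for (i in seq_len(n_steps)) {
    cand <- cur + prop[i]
    lcand <- logf(cand)
    if (lcand - lcur > lu[i]) {
      cur <- cand
      lcur <- lcand
      n_acc <- n_acc + 1L
    }
    x[i] <- cur
  }
  list(x = x, acceptance = n_acc / n_steps)
}

# Tune the proposal half-width toward ~40% acceptance over short batches
# of a discarded burn-in, then return the tuned step and final state.
tune_step <- function(x0, step, logf, n_batches = 10, batch = 200) {
  cur <- x0
  for (b in seq_len(n_batches)) {
    run <- metropolis_chain(batch, cur, step, logf)
    cur <- run$x[batch]
    step <- step * exp(run$acceptance - 0.40)
  }
  list(step = step, x = cur)
}

#' Toy harmonic-oscillator alchemical simulation
#'
#' Metropolis sampling of a single coordinate under the lambda-mixed
#' harmonic potential \eqn{V(x; \lambda) = \tfrac12 [(1-\lambda) k_0 +
#' \lambda k_1] x^2}, recording \eqn{\partial V/\partial\lambda =
#' \tfrac12 (k_1 - k_0) x^2} at every step. The exact free-energy change
#' is \eqn{(k_B T / 2) \ln(k_1 / k_0)}, making this the canonical
#' validation harness for the TI estimator: the sampled dV/dlambda series
#' are genuinely autocorrelated, the estimate is stochastic, and the
#' truth is closed-form.
#'
#' @param schedule A `lambda_schedule`.
#' @param k0,k1 Spring constants of the two end states (kcal/mol/A^2).
#' @param kT Thermal energy in kcal/mol.
#' @param mc_steps Recorded Metropolis steps per window.
#' @param seed Integer seed.
#' @return A list: `windows` (list of `dvdl_series`), `truth` (exact
#'   Delta G), `acceptance` (per-window rates), `schedule`.
#' @export
toy_harmonic_sim <- function(schedule, k0 = 1, k1 = 4, kT = 1,
                             mc_steps = 20000, seed = 1) {
  validate_schedule(schedule)
  if (k0 <= 0 || k1 <= 0 || kT <= 0) {
    rlang::abort("`k0`, `k1` and `kT` must be positive.")
  }
  withr::local_seed(seed)
  half_dk <- 0.5 * (k1 - k0)
  out <- purrr::map(schedule$lambda, function(lam) {
    k <- (1 - lam) * k0 + lam * k1
    logf <- function(x) -0.5 * k * x^2 / kT
    tuned <- tune_step(0, 2.4 * sqrt(kT / k), logf)
    run <- metropolis_chain(mc_steps, tuned$x, tuned$step, logf)
    list(series = dvdl_series(half_dk * run$x^2, lambda = lam),
         acceptance = run$acceptance)
  })
  list(
    windows = purrr::map(out, "series"),
    truth = (kT / 2) * log(k1 / k0),
    acceptance = purrr::map_dbl(out, "acceptance"),
    schedule = schedule
  )
}

#' Softcore Lennard-Jones pair potential
#'
#' The separation-shifted one-parameter softcore form
#' \deqn{V(r;\lambda) = 4 \epsilon \lambda \left[
#'   (\alpha (1-\lambda) + (r/\sigma)^6)^{-2} -
#'   (\alpha (1-\lambda) + (r/\sigma)^6)^{-1} \right].}
#' At lambda = 1 it reduces to the plain LJ pair potential; at lambda = 0
#' the interaction vanishes, and for intermediate lambda the alpha term
#' removes the r = 0 singularity so appearing/disappearing particles
#' never see infinite energies.
#'
#' @param r Separation (angstrom).
#' @param lam Coupling value in \[0, 1\].
#' @param epsilon Well depth (kcal/mol).
#' @param sigma LJ diameter (angstrom).
#' @param alpha Softcore parameter (dimensionless, default 0.5).
#' @return Potential energy in kcal/mol.
#' @export
softcore_lj_potential <- function(r, lam, epsilon, sigma, alpha = 0.5) {
  a <- alpha * (1 - lam) + (r / sigma)^6
  4 * epsilon * lam * (a^-2 - a^-1)
}

#' @rdname softcore_lj_potential
#' @return `softcore_lj_dvdl()`: the analytic lambda-derivative of the
#'   potential, kcal/mol.
#' @export
softcore_lj_dvdl <- function(r, lam, epsilon, sigma, alpha = 0.5) {
  a <- alpha * (1 - lam) + (r / sigma)^6
  4 * epsilon * ((a^-2 - a^-1) + lam * alpha * (2 * a^-3 - a^-2))
}

#' Toy softcore Lennard-Jones decoupling simulation
#'
#' One particle pair in a spherical volume of radius `box_length / 2`:
#' the radial separation is Metropolis-sampled under
#' [softcore_lj_potential()] (with the r^2 volume Jacobian), and
#' dV/dlambda is recorded analytically at each step. The reference
#' free-energy change is computed independently from the radial
#' configurational integrals \eqn{Z(\lambda) = \int_0^R r^2
#' e^{-V(r;\lambda)/k_BT} dr} by adaptive quadrature:
#' \eqn{\Delta G = -k_B T \ln(Z_1/Z_0)}.
#'
#' @param schedule A `lambda_schedule`.
#' @param epsilon,sigma,alpha Softcore LJ parameters.
#' @param box_length Diameter of the sampled volume (angstrom).
#' @param kT Thermal energy (kcal/mol).
#' @param mc_steps Recorded Metropolis steps per window.
#' @param seed Integer seed.
#' @return A list: `windows`, `truth` (quadrature oracle Delta G),
#'   `acceptance`, `schedule`.
#' @export
toy_softcore_lj <- function(schedule, epsilon = 0.5, sigma = 3,
                            box_length = 12, alpha = 0.5, kT = 0.59248,
                            mc_steps = 20000, seed = 1) {
  validate_schedule(schedule)
  if (epsilon <= 0 || sigma <= 0 || kT <= 0 || box_length <= 0) {
    rlang::abort("`epsilon`, `sigma`, `kT` and `box_length` must be positive.")
  }
  withr::local_seed(seed)
  rmax <- box_length / 2
  out <- purrr::map(schedule$lambda, function(lam) {
    logf <- function(r) {
      if (r <= 0 || r > rmax) return(-Inf)
      2 * log(r) - softcore_lj_potential(r, lam, epsilon, sigma, alpha) / kT
    }
    tuned <- tune_step(sigma, sigma / 2, logf)
    run <- metropolis_chain(mc_steps, tuned$x, tuned$step, logf)
    list(
      series = dvdl_series(
        softcore_lj_dvdl(run$x, lam, epsilon, sigma, alpha), lambda = lam),
      acceptance = run$acceptance
    )
  })
  z <- function(lam) {
    stats::integrate(function(r) {
      r^2 * exp(-softcore_lj_potential(r, lam, epsilon, sigma, alpha) / kT)
    }, 0, rmax, rel.tol = 1e-10)$value
  }
  list(
    windows = purrr::map(out, "series"),
    truth = -kT * log(z(1) / z(0)),
    acceptance = purrr::map_dbl(out, "acceptance"),
    schedule = schedule
  )
}

#' Synthetic two-state conformational descriptor series
#'
#' A hidden two-state Markov chain with stationary occupancies equal to
#' `weights` (transition matrix \eqn{P = \phi I + (1-\phi)\mathbf{1}
#' w^T}, so \eqn{\phi} sets the frame-to-frame persistence) and Gaussian
#' emission around each state's mean. Models a residue hopping between
#' two sidechain conformations in an equilibrium trajectory.
#'
#' @param n Number of frames.
#' @param weights Stationary occupancies (length 2, sum 1).
#' @param means Emission means per state (angstrom or degrees).
#' @param widths Emission standard deviations per state.
#' @param ar1_phi Persistence of the hidden chain in \[0, 1).
#' @param seed Integer seed.
#' @param periodic Whether the descriptor is periodic (dihedral).
#' @param period Period when periodic (default 360).
#' @return A list: `series` (a `descriptor_series`), `states` (hidden
#'   state index per frame), `truth_weights`.
#' @export
gen_twostate_series <- function(n, weights = c(0.9, 0.1),
                                means = c(4, 7), widths = c(0.3, 0.3),
                                ar1_phi = 0.5, seed = 1,
                                periodic = FALSE, period = 360) {
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    rlang::abort("`weights` must be two non-negative values summing to 1.")
  }
  if (ar1_phi < 0 || ar1_phi >= 1) {
    rlang::abort("`ar1_phi` must be in [0, 1).")
  }
  withr::local_seed(seed)
  if (any(weights == 0)) {
    states <- rep(which(weights > 0), n)
  } else {
    states <- integer(n)
    states[1] <- sample(1:2, 1, prob = weights)
    stay <- stats::runif(n) < ar1_phi
    redraw <- sample(1:2, n, replace = TRUE, prob = weights)
    for (i in 2:n) {
      states[i] <- if (stay[i]) states[i - 1] else redraw[i]
    }
  }
  vals <- stats::rnorm(n, mean = means[states], sd = widths[states])
  if (periodic) vals <- wrap_periodic(vals, period)
  list(
    series = descriptor_series(vals, periodic = periodic, period = period),
    states = states,
    truth_weights = weights
  )
}

#' Write a leg's window files and schedule to a directory
#'
#' Materializes in-memory windows in the on-disk window-file dialect, one
#' file per lambda node, for use from a cycle manifest.
#'
#' @param windows List of `dvdl_series`.
#' @param schedule The matching `lambda_schedule`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "window").
#' @return A list with `schedule` (path) and `windows` (paths), invisibly.
#' @export
write_synthetic_leg <- function(windows, schedule, dir,
                                prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sched_path <- file.path(dir, "schedule.tsv")
  write_schedule(schedule, sched_path)
  paths <- purrr::imap_chr(windows, function(w, i) {
    p <- file.path(dir, sprintf("%s_%02d.dat", prefix, i))
    write_dvdl_window(w, p)
    p
  })
  invisible(list(schedule = sched_path, windows = paths))
}
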