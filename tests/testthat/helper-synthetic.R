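# Shared fixtures, built in code at test time.

sched12 <- gauss_legendre_schedule(12)

# The published 12-window lambda/weight scheme (5-decimal printing).
printed_lambdas <- c(0.00922, 0.04794, 0.11505, 0.20634, 0.31608, 0.43738,
                     0.56262, 0.68392, 0.79366, 0.88495, 0.95206, 0.99078)
printed_half_weights <- c(0.02359, 0.05347, 0.08004, 0.10158, 0.11675,
                          0.12457)

# Mean dV/dlambda profile of the analytic harmonic transformation
# k0 -> k1: <dV/dl> = (k1 - k0) kT / (2 k(lambda)), integral
# (kT/2) ln(k1/k0).
harmonic_mean_profile <- function(lam, k0, k1, kT) {
  0.5 * (k1 - k0) * kT / ((1 - lam) * k0 + lam * k1)
}

# Seeded AR(1) series with stationary sd `sigma`.
ar1_series <- function(n, phi, sigma = 1, seed = 1) {
  withr::with_seed(seed, {
    innov <- stats::rnorm(n, sd = sqrt(1 - phi^2) * sigma)
    as.numeric(stats::filter(innov, phi, method = "recursive",
                             init = stats::rnorm(1, sd = sigma)))
  })
}

# Quadrature over raw per-window means (no discard); exact for
# noise-free generated profiles.
estimate_leg_means_only <- function(gen) {
  ti_integrate(gen$schedule,
               purrr::map_dbl(gen$windows, ~ mean(.x$dvdl)))
}

# In-memory cycle manifest around two lists of dvdl_series.
mem_manifest <- function(complex_windows, apo_windows, schedule,
                         label = "T35S", src = "THR", tgt = "SER",
                         frac = 0.1) {
  list(
    mutation_label = label, position = 35L,
    source_residue = src, target_residue = tgt,
    temperature = 298.15, equilibration_fraction = frac,
    coion_policy = "auto",
    legs = list(
      complex = list(schedule = schedule, windows = complex_windows),
      apo = list(schedule = schedule, windows = apo_windows)
    )
  )
}
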