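test_that("equilibration discard follows the floor convention", {
  x <- dvdl_series(seq_len(100), lambda = 0.5)
  expect_equal(nrow(discard_equilibration(x, 0.1)), 90L)
  expect_equal(discard_equilibration(x, 0)$dvdl, x$dvdl)
  x5 <- dvdl_series(1:5, lambda = 0.5)
  expect_equal(discard_equilibration(x5, 0.9)$dvdl, 5) # floor(4.5) = 4 removed
  expect_error(discard_equilibration(x, 1), "\\[0, 1\\)")
})

test_that("statistical inefficiency is ~1 for white noise and errors on constants", {
  withr::with_seed(11, x <- rnorm(1e5))
  expect_equal(statistical_inefficiency(x), 1, tolerance = 0.1)
  expect_error(statistical_inefficiency(rep(2, 100)), "constant")
})

test_that("statistical inefficiency matches the analytic AR(1) value", {
  # short-series check; the long-series (N = 1e6) benchmark lives in the
  # acceptance suite
  g_true <- (1 + 0.8) / (1 - 0.8)
  g_hat <- statistical_inefficiency(ar1_series(4e5, 0.8, seed = 21))
  expect_equal(g_hat, g_true, tolerance = 0.1)
})

test_that("uncorrelated subsampling uses a ceiling stride from the first frame", {
  x <- 1:10
  expect_equal(subsample_uncorrelated(x, 1), 1:10)
  expect_equal(subsample_uncorrelated(x, 3), c(1L, 4L, 7L, 10L))
  expect_equal(subsample_uncorrelated(x, 2.2), c(1L, 4L, 7L, 10L))
  expect_equal(subsample_uncorrelated(x, 10), 1L)
})

test_that("window_stats recovers iid moments and a two-state mean", {
  withr::with_seed(5, x <- rnorm(1e4, mean = 2, sd = 1))
  st <- window_stats(dvdl_series(x, 0.5), equilibration_fraction = 0)
  expect_equal(st$sem, 0.01, tolerance = 0.2)
  expect_lt(abs(st$mean - 2), 3 * st$sem)
  expect_equal(st$g, 1, tolerance = 0.15)

  st2 <- window_stats(c(1, 1, 1, 3, 3, 3), equilibration_fraction = 0)
  expect_equal(st2$mean, 2)
})

test_that("autocorrelation inflates the SEM by about sqrt(g)", {
  phi <- 0.9
  x <- ar1_series(2e5, phi, sigma = 1, seed = 31)
  st <- window_stats(x, equilibration_fraction = 0)
  naive <- stats::sd(x) / sqrt(length(x))
  expect_gt(st$g, 5)
  expect_equal(st$sem / naive, sqrt(st$g), tolerance = 0.35)
  expect_lte(st$n_eff, length(x))
})

test_that("SEM shrinks as 1/sqrt(N) on stationary data", {
  sems <- vapply(c(1e4, 4e4, 16e4), function(n) {
    window_stats(ar1_series(n, 0.5, seed = 101), 0)$sem
  }, numeric(1))
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.3)
  expect_equal(sems[2] / sems[3], 2, tolerance = 0.3)
})

test_that("window_stats mean is stable across subsampling choices in expectation", {
  # the reported mean uses all retained frames; across seeded replicates it
  # stays within 3 SEM of the true mean
  hits <- vapply(1:10, function(s) {
    x <- ar1_series(2e4, 0.8, seed = 200 + s) + 1.5
    st <- window_stats(x, equilibration_fraction = 0.1)
    abs(st$mean - 1.5) < 3 * st$sem
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("a single-chunk convergence profile equals the full-data estimate", {
  s <- gauss_legendre_schedule(4)
  cx <- gen_dvdl_profile(s, coefs = c(3), noise_sigma = 0.5,
                         samples_per_window = 400, seed = 41)
  ap <- gen_dvdl_profile(s, coefs = c(1), noise_sigma = 0.5,
                         samples_per_window = 400, seed = 42)
  man <- mem_manifest(cx$windows, ap$windows, s)
  full <- compute_cycle(man, n_chunks = 0)
  prof <- convergence_profile(cx$windows, ap$windows, s, n_chunks = 1,
                              direction = "forward")
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$ddg, full$ddg, tolerance = 1e-12)
})

test_that("time-reversing every window swaps the forward and reverse profiles", {
  s <- gauss_legendre_schedule(3)
  cx <- gen_dvdl_profile(s, coefs = c(2, 1), noise_sigma = 0.4,
                         samples_per_window = 300, seed = 51)
  ap <- gen_dvdl_profile(s, coefs = c(0.5), noise_sigma = 0.4,
                         samples_per_window = 300, seed = 52)
  rev_wins <- function(wins) {
    lapply(wins, function(w) dvdl_series(rev(w$dvdl), attr(w, "lambda")))
  }
  fwd <- convergence_profile(cx$windows, ap$windows, s, n_chunks = 4,
                             direction = "forward",
                             equilibration_fraction = 0)
  rev_rev <- convergence_profile(rev_wins(cx$windows), rev_wins(ap$windows),
                                 s, n_chunks = 4, direction = "reverse",
                                 equilibration_fraction = 0)
  expect_equal(fwd$ddg, rev_rev$ddg, tolerance = 1e-12)
})

test_that("forward and reverse estimates agree on stationary data", {
  s <- gauss_legendre_schedule(6)
  cx <- gen_dvdl_profile(s, coefs = c(3, -1), noise_sigma = 1,
                         samples_per_window = 2000, seed = 61)
  ap <- gen_dvdl_profile(s, coefs = c(1), noise_sigma = 1,
                         samples_per_window = 2000, seed = 62)
  prof <- convergence_profile(cx$windows, ap$windows, s, n_chunks = 5,
                              direction = "both")
  fin <- prof[prof$fraction == 1, ]
  gap <- abs(diff(fin$ddg))
  expect_lt(gap, 3 * sqrt(sum(fin$sigma^2)))
})
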