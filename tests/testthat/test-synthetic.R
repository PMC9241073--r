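test_that("generators are bit-identical under equal seeds", {
  s <- gauss_legendre_schedule(4)
  a <- gen_dvdl_profile(s, samples_per_window = 200, seed = 5)
  b <- gen_dvdl_profile(s, samples_per_window = 200, seed = 5)
  expect_identical(purrr::map(a$windows, "dvdl"),
                   purrr::map(b$windows, "dvdl"))
  c <- gen_dvdl_profile(s, samples_per_window = 200, seed = 6)
  expect_false(identical(a$windows[[1]]$dvdl, c$windows[[1]]$dvdl))

  t1 <- gen_twostate_series(500, seed = 4)
  t2 <- gen_twostate_series(500, seed = 4)
  expect_identical(t1$series$value, t2$series$value)

  h1 <- toy_harmonic_sim(s, mc_steps = 500, seed = 9)
  h2 <- toy_harmonic_sim(s, mc_steps = 500, seed = 9)
  expect_identical(purrr::map(h1$windows, "dvdl"),
                   purrr::map(h2$windows, "dvdl"))
})

test_that("noise-free polynomial profiles integrate exactly through the pipeline", {
  s <- gauss_legendre_schedule(12)
  gen <- gen_dvdl_profile(s, coefs = c(0, 2), noise_sigma = 0,
                          samples_per_window = 10, seed = 1)
  leg <- estimate_leg_means_only(gen)
  expect_equal(leg, 1, tolerance = 1e-12)
  expect_equal(gen$truth, 1)

  gen2 <- gen_dvdl_profile(s, coefs = c(1, -2, 6), noise_sigma = 0,
                           samples_per_window = 10, seed = 1)
  expect_equal(gen2$truth, 1 - 1 + 2)
  expect_equal(estimate_leg_means_only(gen2), gen2$truth,
               tolerance = 1e-12)
})

test_that("constant-mean noisy profiles recover the constant within 3 SEM", {
  s <- gauss_legendre_schedule(6)
  gen <- gen_dvdl_profile(s, coefs = c(2.5), noise_sigma = 1,
                          ar1_phi = 0.5, samples_per_window = 5000,
                          seed = 17)
  leg <- estimate_leg(gen$windows, s)
  expect_lt(abs(leg$delta_g - 2.5), 3 * leg$sigma)
})

test_that("the equilibration transient is confined to the discarded fraction", {
  s <- gauss_legendre_schedule(2)
  gen <- gen_dvdl_profile(s, coefs = c(0), noise_sigma = 0,
                          equilibration_offset = 10,
                          samples_per_window = 1000, seed = 1)
  w <- gen$windows[[1]]$dvdl
  expect_gt(w[1], 9) # transient present at the start
  expect_lt(max(abs(w[101:1000])), 0.1) # negligible after the first 10%
})

test_that("the harmonic sampler obeys equipartition and the null transformation", {
  s <- gauss_legendre_schedule(2)
  sim0 <- toy_harmonic_sim(s, k0 = 2, k1 = 2, kT = 1, mc_steps = 2000,
                           seed = 23)
  expect_true(all(purrr::map_dbl(sim0$windows, ~ max(abs(.x$dvdl))) == 0))
  expect_equal(sim0$truth, 0)

  # equipartition: <x^2> = kT / k(lambda), read off through the recorded
  # dV/dl = (k1-k0)/2 x^2 with (k1-k0)/2 = 1
  kT <- 1.3
  sim2 <- toy_harmonic_sim(s, k0 = 1, k1 = 3, kT = kT, mc_steps = 30000,
                           seed = 25)
  for (i in seq_along(s$lambda)) {
    k <- (1 - s$lambda[i]) * 1 + s$lambda[i] * 3
    x2 <- sim2$windows[[i]]$dvdl / 1 # dV/dl = x^2 since (k1-k0)/2 = 1
    st <- window_stats(x2, 0.1)
    expect_lt(abs(st$mean - kT / k), 4 * st$sem)
  }
})

test_that("harmonic ground truth scales linearly with kT at fixed k-ratio", {
  s <- gauss_legendre_schedule(2)
  t1 <- toy_harmonic_sim(s, k0 = 1, k1 = 4, kT = 1, mc_steps = 10,
                         seed = 1)$truth
  t2 <- toy_harmonic_sim(s, k0 = 1, k1 = 4, kT = 2.5, mc_steps = 10,
                         seed = 1)$truth
  expect_equal(t2, 2.5 * t1, tolerance = 1e-12)
  expect_equal(t1, 0.5 * log(4), tolerance = 1e-12)
})

test_that("the softcore potential has the correct endpoint behavior", {
  r <- seq(2.5, 6, by = 0.25)
  eps <- 0.5
  sig <- 3
  plain_lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  expect_equal(softcore_lj_potential(r, 1, eps, sig), plain_lj,
               tolerance = 1e-12)
  expect_equal(softcore_lj_potential(r, 0, eps, sig), rep(0, length(r)))
  # softcore removes the r = 0 singularity away from lambda = 1
  expect_true(is.finite(softcore_lj_potential(0, 0.5, eps, sig)))

  # analytic dV/dl matches a central finite difference
  for (lam in c(0.2, 0.5, 0.8)) {
    h <- 1e-6
    fd <- (softcore_lj_potential(r, lam + h, eps, sig) -
             softcore_lj_potential(r, lam - h, eps, sig)) / (2 * h)
    expect_equal(softcore_lj_dvdl(r, lam, eps, sig), fd, tolerance = 1e-6)
  }
})

test_that("softcore-LJ decoupling agrees with the configurational-integral oracle", {
  s <- gauss_legendre_schedule(12)
  lj <- toy_softcore_lj(s, mc_steps = 15000, seed = 27)
  leg <- estimate_leg(lj$windows, s)
  expect_lt(abs(leg$delta_g - lj$truth), 3 * leg$sigma)
  expect_true(all(lj$acceptance > 0.2 & lj$acceptance < 0.7))
})

test_that("two-state series honour degenerate and stated weights", {
  one <- gen_twostate_series(2000, weights = c(1, 0), seed = 31)
  expect_true(all(one$states == 1L))
  hs <- histogram_states(one$series)
  expect_equal(nrow(hs$states), 1L)

  gen <- gen_twostate_series(10000, weights = c(0.9, 0.1), seed = 32)
  expect_equal(mean(gen$states == 1), 0.9, tolerance = 0.02)
  expect_error(gen_twostate_series(100, weights = c(0.6, 0.6)), "summing")
})

test_that("synthetic legs round-trip bit-identically through window files", {
  s <- gauss_legendre_schedule(3)
  gen <- gen_dvdl_profile(s, samples_per_window = 100, seed = 33)
  td <- withr::local_tempdir()
  paths <- write_synthetic_leg(gen$windows, s, td)
  back <- purrr::map(paths$windows, read_dvdl_window)
  expect_identical(purrr::map(back, "dvdl"),
                   purrr::map(gen$windows, "dvdl"))
  expect_identical(purrr::map_dbl(back, ~ attr(.x, "lambda")),
                   s$lambda)
})
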