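test_that("formal charge deltas follow the pH-7 convention", {
  expect_equal(residue_charge_delta("ASP", "ALA"), 1L)  # D38A anneals -1
  expect_equal(residue_charge_delta("LYS", "GLN"), -1L) # K135Q anneals +1
  expect_equal(residue_charge_delta("TYR", "LYS"), 1L)  # Y32K creates +1
  expect_equal(residue_charge_delta("VAL", "ALA"), 0L)
  expect_equal(residue_charge_delta("HIS", "ALA"), 0L)
  expect_error(residue_charge_delta("XXX", "ALA"), "Unknown residue")
})

test_that("co-ion planning keeps the box neutral and rejects large deltas", {
  expect_equal(plan_coion(1)$action, "na_to_water")
  expect_equal(plan_coion(-1)$action, "water_to_na")
  expect_equal(plan_coion(0)$action, "none")
  expect_error(plan_coion(2), "Unsupported")
  expect_error(plan_coion(-2), "Unsupported")
})

test_that("identical legs cancel to ddG = 0 with sqrt(2) error combination", {
  s <- gauss_legendre_schedule(4)
  gen <- gen_dvdl_profile(s, coefs = c(2, 1), noise_sigma = 0.5,
                          samples_per_window = 300, seed = 71)
  man <- mem_manifest(gen$windows, gen$windows, s)
  cyc <- compute_cycle(man, n_chunks = 0)
  expect_equal(cyc$ddg, 0, tolerance = 1e-12)
  expect_equal(cyc$sigma, sqrt(2) * cyc$legs$complex$sigma,
               tolerance = 1e-12)
  expect_equal(cyc$sigma^2,
               cyc$legs$complex$sigma^2 + cyc$legs$apo$sigma^2,
               tolerance = 1e-12)
})

test_that("swapping leg roles negates the cycle ddG", {
  s <- gauss_legendre_schedule(4)
  cx <- gen_dvdl_profile(s, coefs = c(3), noise_sigma = 0.3,
                         samples_per_window = 300, seed = 72)
  ap <- gen_dvdl_profile(s, coefs = c(1), noise_sigma = 0.3,
                         samples_per_window = 300, seed = 73)
  a <- compute_cycle(mem_manifest(cx$windows, ap$windows, s), n_chunks = 0)
  b <- compute_cycle(mem_manifest(ap$windows, cx$windows, s), n_chunks = 0)
  expect_equal(a$ddg, -b$ddg, tolerance = 1e-12)
  expect_equal(a$sigma, b$sigma, tolerance = 1e-12)
})

test_that("synthetic legs with known ground truth are recovered within 3 sigma", {
  s <- gauss_legendre_schedule(12)
  cx <- gen_dvdl_profile(s, coefs = c(3), noise_sigma = 1,
                         samples_per_window = 1000, seed = 74)
  ap <- gen_dvdl_profile(s, coefs = c(1), noise_sigma = 1,
                         samples_per_window = 1000, seed = 75)
  cyc <- compute_cycle(mem_manifest(cx$windows, ap$windows, s),
                       n_chunks = 0)
  expect_lt(abs(cyc$ddg - 2), 3 * cyc$sigma)
  expect_equal(cyc$coion$action, "none")
})

test_that("a toy harmonic cycle reproduces the closed-form ddG", {
  # complex leg k 1 -> 4, apo leg k 1 -> 1 at kT = 0.59248:
  # ddG = (kT/2) ln 4 ~ 0.4107
  kT <- 0.59248
  s <- gauss_legendre_schedule(12)
  cx <- toy_harmonic_sim(s, k0 = 1, k1 = 4, kT = kT, mc_steps = 8000,
                         seed = 81)
  ap <- toy_harmonic_sim(s, k0 = 1, k1 = 1, kT = kT, mc_steps = 8000,
                         seed = 82)
  cyc <- compute_cycle(mem_manifest(cx$windows, ap$windows, s),
                       n_chunks = 0)
  expect_lt(abs(cyc$ddg - (kT / 2) * log(4)), 3 * cyc$sigma)
  expect_equal(cyc$legs$apo$delta_g, 0, tolerance = 1e-12) # dV/dl == 0
})

test_that("cycle parameter recovery holds in >= 18 of 20 seeded replicates", {
  s <- gauss_legendre_schedule(6)
  hits <- vapply(1:20, function(rep) {
    cx <- gen_dvdl_profile(s, coefs = c(1, 4, -3), noise_sigma = 1.5,
                           samples_per_window = 600,
                           equilibration_offset = 4, seed = 1000 + rep)
    ap <- gen_dvdl_profile(s, coefs = c(0.5, 1), noise_sigma = 1.5,
                           samples_per_window = 600,
                           equilibration_offset = -2, seed = 2000 + rep)
    truth <- cx$truth - ap$truth
    cyc <- compute_cycle(mem_manifest(cx$windows, ap$windows, s),
                         n_chunks = 0)
    abs(cyc$ddg - truth) < 3 * cyc$sigma
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("cycle results expose tidy/glance views consistent with the object", {
  s <- gauss_legendre_schedule(3)
  gen <- gen_dvdl_profile(s, samples_per_window = 100, seed = 91)
  cyc <- compute_cycle(mem_manifest(gen$windows, gen$windows, s,
                                    label = "D38A", src = "ASP",
                                    tgt = "ALA"), n_chunks = 0)
  expect_equal(cyc$coion$action, "na_to_water")
  td <- tidy(cyc)
  expect_equal(nrow(td), 6L)
  expect_setequal(unique(td$environment), c("complex", "apo"))
  gl <- glance(cyc)
  expect_equal(gl$ddg, cyc$ddg)
  expect_equal(gl$coion_action, "na_to_water")
})
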