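test_that("generators are reproducible under a fixed seed", {
  cal <- exact_calibration()
  m <- recovery_masses()
  a <- simulate_isec(7.5, 1.1, 2.3, m, cal, noise_sd = 0.02, seed = 5)
  b <- simulate_isec(7.5, 1.1, 2.3, m, cal, noise_sd = 0.02, seed = 5)
  c <- simulate_isec(7.5, 1.1, 2.3, m, cal, noise_sd = 0.02, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$retention_volume, c$retention_volume))

  d1 <- simulate_depletion(1000, extraction_efficiency = 0.6,
                           noise_cv = 0.05, seed = 5)
  d2 <- simulate_depletion(1000, extraction_efficiency = 0.6,
                           noise_cv = 0.05, seed = 5)
  d3 <- simulate_depletion(1000, extraction_efficiency = 0.6,
                           noise_cv = 0.05, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1$concentration, d3$concentration))

  r1 <- simulate_dose_response(300, 5000, 22, 4, noise_sd = 100, seed = 5)
  r2 <- simulate_dose_response(300, 5000, 22, 4, noise_sd = 100, seed = 5)
  r3 <- simulate_dose_response(300, 5000, 22, 4, noise_sd = 100, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$response_mean, r3$response_mean))
})

test_that("seeded generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_isec(7.5, 1.1, 2.3, recovery_masses(),
                          exact_calibration(), noise_sd = 0.02, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noise-free chromatograms round-trip through the Kd formula", {
  cal <- exact_calibration()
  sim <- simulate_isec(7.5, v0 = 1.1, vt = 2.3,
                       molecular_mass = recovery_masses(),
                       calibration = cal, noise_sd = 0)
  kd_back <- compute_kd(sim$retention_volume, column_volumes(1.1, 2.3))
  expect_equal(kd_back, sim$kd_true, tolerance = 1e-12)
  # limits: a probe as large as the pore is excluded, a tiny probe permeates
  lim <- simulate_isec(2, 1.1, 2.3, molecular_mass = c(1e-6, 400),
                       calibration = cal, noise_sd = 0)
  expect_equal(lim$kd_true[2], 0)        # stokes radius 2 = pore radius
  expect_equal(lim$retention_volume[2], 1.1)
  expect_gt(lim$kd_true[1], 0.999)       # stokes radius 1e-4 nm
  expect_lt(abs(lim$retention_volume[1] - 2.3), 1e-3)
})

test_that("pore mixtures weight the partition coefficients", {
  cal <- exact_calibration()
  mono_small <- simulate_isec(2, 1, 2, 400, cal)
  mono_big <- simulate_isec(10, 1, 2, 400, cal)
  mix <- simulate_isec(c(2, 10), 1, 2, 400, cal, pore_weight = c(0.3, 0.7))
  expect_equal(mix$kd_true, 0.3 * mono_small$kd_true + 0.7 * mono_big$kd_true)
  expect_error(simulate_isec(c(2, 10), 1, 2, 400, cal,
                             pore_weight = c(0.5, 0.2)), "sum to 1")
})

test_that("reservoir depletion matches the closed form and conserves mass", {
  # E = 1 and one reservoir volume per hour: C(1)/C0 = exp(-1)
  s <- simulate_depletion(1000, reservoir_volume = 60, flow = 1,
                          extraction_efficiency = 1, timepoints = c(0, 1))
  expect_equal(s$concentration[2] / s$concentration[1], exp(-1))
  # control circuit is constant
  ctrl <- simulate_depletion(1000, extraction_efficiency = 0, timepoints = 0:6)
  expect_equal(ctrl$concentration, rep(1000, 7))
  # mass balance, closed form
  mb <- attr(s, "mass_balance")
  expect_equal(mb$reservoir_mass + mb$captured_mass,
               rep(1000 * 60, 2), tolerance = 1e-12)
})

test_that("the saturable depletion variant plateaus at capacity and conserves mass", {
  cap <- 1000 * 60 / 2 # half the initial reservoir mass
  s <- simulate_depletion(1000, extraction_efficiency = 0.8, capacity = cap,
                          timepoints = 0:24)
  mb <- attr(s, "mass_balance")
  rel_err <- abs(mb$reservoir_mass + mb$captured_mass - 1000 * 60) / (1000 * 60)
  expect_lt(max(rel_err), 1e-6)
  # concentration settles near c0/2 once the capacity is exhausted
  expect_equal(s$concentration[25], 500, tolerance = 1e-3)
  expect_equal(mb$captured_mass[25], cap, tolerance = 1e-6)
  # saturable path never dips below the capacity floor
  expect_true(all(s$concentration >= 500 - 1e-9))
})

test_that("dose-response generator obeys the Hill identities", {
  dr <- simulate_dose_response(300, 5000, ec50 = 50, hill = 2,
                               doses = c(0, 50), noise_sd = 0)
  expect_equal(dr$response_mean[1], 300)           # baseline at dose 0
  expect_equal(dr$response_mean[2], 300 + 5000 / 2) # half-maximum at EC50
  # reported SD is the generator noise scale
  noisy <- simulate_dose_response(300, 5000, 22, 4, noise_sd = 120, seed = 3)
  expect_true(all(noisy$response_sd == 120))
  expect_equal(noisy$response_mean, noisy$response_true,
               tolerance = 0.5) # loose: replicate-mean jitter only
})

test_that("a known change point is recovered end-to-end by the threshold module", {
  dr <- simulate_dose_response(300, 5000, ec50 = 22, hill = 4, noise_sd = 0)
  br <- activation_threshold(dr)
  expect_equal(br$last_inactive_dose, 10)
  expect_equal(br$first_active_dose, 50)
})
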