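test_that("profiles sort by mass and police Kd range", {
  vols <- column_volumes(1, 2)
  prof <- isec_profile("x", vols, c(500, 100, 1000), kd = c(0.5, 0.9, 0.1))
  expect_equal(prof$points$molecular_mass, c(100, 500, 1000))
  expect_equal(prof$points$kd, c(0.9, 0.5, 0.1))
  # small excursions clamp with a warning, raw values preserved
  expect_warning(
    p2 <- isec_profile("x", vols, c(100, 1000), kd = c(1.03, -0.02)),
    "clamped"
  )
  expect_equal(p2$points$kd, c(1, 0))
  expect_equal(p2$points$kd_raw, c(1.03, -0.02))
  # larger excursions are errors, with a configurable tolerance
  expect_error(isec_profile("x", vols, 100, kd = 1.2), "outside")
  expect_warning(
    isec_profile("x", vols, 100, kd = 1.2, kd_tolerance = 0.25),
    "clamped"
  )
  expect_error(isec_profile("x", vols, numeric(0), kd = numeric(0)),
               "at least one")
})

test_that("fixture adsorbents bracket at the printed pore sizes", {
  cal <- table2_calibration()
  br161 <- accessible_pore_bracket(table2_profile("CG161c"), cal)
  expect_equal(round(c(br161$d_lower, br161$d_upper), 1), c(10.0, 16.2))
  expect_equal(round(c(br161$r_lower, br161$r_upper), 2), c(5.01, 8.11),
               tolerance = 0.01)
  # Kd exactly at the threshold counts as accessible (tie row at 17300)
  brh <- accessible_pore_bracket(table2_profile("HAC"), cal)
  expect_equal(round(c(brh$d_lower, brh$d_upper), 1), c(7.6, 10.0))
  br300 <- accessible_pore_bracket(table2_profile("CG300m"), cal)
  expect_equal(round(c(br300$d_lower, br300$d_upper), 1), c(20.9, 26.0))
  expect_false(any(br161$open_lower, br161$open_upper,
                   brh$open_lower, brh$open_upper))
})

test_that("never-crossed thresholds yield flagged open brackets, not errors", {
  vols <- column_volumes(1, 2)
  cal <- exact_calibration()
  all_in <- isec_profile("open", vols, c(100, 1000, 10000), kd = c(1, 1, 1))
  br <- accessible_pore_bracket(all_in, cal)
  expect_true(br$open_upper)
  expect_true(is.na(br$r_upper))
  expect_false(br$open_lower)
  all_out <- isec_profile("shut", vols, c(100, 1000), kd = c(0.05, 0.01))
  br2 <- accessible_pore_bracket(all_out, cal)
  expect_true(br2$open_lower)
  expect_true(is.na(br2$r_lower))
  expect_error(accessible_pore_bracket(
    isec_profile("one", vols, 100, kd = 0.5), cal
  ), "at least 2")
})

test_that("noisy non-monotone profiles are smoothed antitonically before bracketing", {
  vols <- column_volumes(1, 2)
  cal <- exact_calibration()
  # a local bump above threshold must not split the accessible region
  prof <- isec_profile("bumpy", vols, c(1e2, 1e3, 1e4, 1e5, 1e6),
                       kd = c(0.9, 0.4, 0.08, 0.12, 0.01))
  br <- accessible_pore_bracket(prof, cal)
  expect_equal(br$calls$kd_smooth, sort(br$calls$kd_smooth, decreasing = TRUE))
  # raw values survive in the calls table
  expect_equal(br$calls$kd_raw, c(0.9, 0.4, 0.08, 0.12, 0.01))
  expect_true(br$r_lower < br$r_upper)
})

test_that("characterization composes bracket, porosity and pore volume", {
  cal <- table2_calibration()
  geom <- column_geometry(0.46, 15)
  ch <- characterize_adsorbent(table2_profile("CG300m"), cal, geometry = geom)
  expect_equal(round(c(ch$bracket$d_lower, ch$bracket$d_upper), 1), c(20.9, 26.0))
  expect_equal(round(ch$porosity_percent, 1), 82.0)
  expect_equal(ch$pore_volume_ml, 1.11)
  expect_equal(ch$route, "stokes")
  # profile volumes carried a vb already (from the fixture accessor)
  ch2 <- characterize_adsorbent(table2_profile("CG300m"), cal)
  expect_equal(ch2$porosity_percent, ch$porosity_percent)
  # no bed volume from anywhere is an error
  bare <- isec_profile("bare", column_volumes(1.14, 2.25),
                       c(1e3, 1e5), kd = c(0.8, 0.05))
  expect_error(characterize_adsorbent(bare, cal), "bed volume")
})

test_that("the exclusion-correlation route is available and labelled", {
  cal <- table2_calibration()
  ch <- characterize_adsorbent(table2_profile("CG161c"), cal,
                               route = "exclusion")
  expect_equal(ch$route, "exclusion")
  # bounds from the bracketing masses 27500 / 62300 via the correlation
  expect_equal(ch$bracket$d_lower,
               exclusion_diameter_from_mass(27500) / 10)
  expect_equal(ch$bracket$d_upper,
               exclusion_diameter_from_mass(62300) / 10)
  # the two routes genuinely differ; reports must carry the label
  ch_s <- characterize_adsorbent(table2_profile("CG161c"), cal)
  expect_false(isTRUE(all.equal(ch$bracket$d_lower, ch_s$bracket$d_lower)))
})

test_that("a noise-free synthetic single-pore adsorbent is recovered", {
  cal <- exact_calibration()
  sim <- simulate_isec(7.5, v0 = 1.1, vt = 2.3,
                       molecular_mass = recovery_masses(),
                       calibration = cal, noise_sd = 0)
  prof <- isec_profile("virtual", column_volumes(1.1, 2.3),
                       sim$molecular_mass,
                       retention_volume = sim$retention_volume)
  br <- accessible_pore_bracket(prof, cal)
  expect_lt(br$r_lower, 7.5)
  expect_gt(br$r_upper, 7.5)
})
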