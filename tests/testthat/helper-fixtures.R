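# shared fixture constructors

# power-law calibration over the bundled polystyrene standards (tracer excluded)
table2_calibration <- function() {
  std <- load_fixture("polystyrene_standards")
  ps <- std[std$role == "standard", ]
  fit_stokes_calibration(ps$molecular_mass, ps$stokes_radius)
}

table2_profile <- function(adsorbent, ...) {
  kd <- load_fixture("isec_kd")
  sub <- kd[kd$adsorbent == adsorbent, ]
  isec_profile(adsorbent, fixture_column_volumes(adsorbent),
               sub$molecular_mass, sub$kd, ...)
}

# exact calibration R_S = 0.1 * sqrt(M): masses map to clean radii
exact_calibration <- function() {
  fit_stokes_calibration(c(100, 10000), c(1, 10))
}

# masses whose Stokes radii are 0.25 * 2^(0:7) nm under exact_calibration()
recovery_masses <- function() (0.25 * 2^(0:7) / 0.1)^2
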