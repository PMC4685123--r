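# All generators take an integer `seed`; when non-NULL the RNG is seeded
# locally so equal seeds give identical output without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# equilibrium partition coefficient of a spherical probe of radius r in a
# cylindrical pore of radius rp (classical SEC partitioning)
partition_kd <- function(probe_radius, pore_radius, pore_weight) {
  vapply(probe_radius, function(r) {
    sum(pore_weight * ifelse(r < pore_radius, (1 - r / pore_radius)^2, 0))
  }, numeric(1))
}

#' Simulate an inverse size-exclusion chromatography experiment
#'
#' Generates per-standard retention volumes for a virtual adsorbent
#' whose pores are cylinders of one or several radii. A probe of
#' Stokes radius r partitions into a pore of radius \eqn{r_p} with
#' \eqn{K_d = (1 - r/r_p)^2} when \eqn{r < r_p} and 0 otherwise
#' (mixture-weighted over the pore set); the retention volume follows
#' as \eqn{V_R = V_0 + K_d (V_T - V_0)} plus additive Gaussian noise.
#' The partition law is a modelling choice of the generator only; the
#' analysis functions never assume it.
#'
#' @param pore_radius Pore radius (nm), or a vector of radii for a
#'   pore-size mixture.
#' @param v0,vt Column void and total mobile-phase volumes, mL.
#' @param molecular_mass Molecular masses of the probe standards, Da.
#' @param calibration A [fit_stokes_calibration()] object converting
#'   mass to Stokes radius.
#' @param pore_weight Mixture weights, summing to 1; default uniform.
#' @param noise_sd SD of additive Gaussian noise on the retention
#'   volume, mL.
#' @param seed Optional integer seed; fixed seed gives identical
#'   output.
#'
#' @return A tibble with columns `molecular_mass`, `stokes_radius`,
#'   `kd_true`, `retention_volume`.
#' @examples
#' cal <- fit_stokes_calibration(c(100, 10000), c(1, 10))
#' simulate_isec(7.5, v0 = 1.1, vt = 2.3,
#'   molecular_mass = 10^seq(2, 6, length.out = 9),
#'   calibration = cal, noise_sd = 0
#' )
#' @export
simulate_isec <- function(pore_radius, v0, vt, molecular_mass, calibration,
                          pore_weight = NULL, noise_sd = 0, seed = NULL) {
  check_numeric_pos(pore_radius, "pore_radius")
  vols <- column_volumes(v0, vt)
  check_numeric_pos(molecular_mass, "molecular_mass")
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  if (is.null(pore_weight)) {
    pore_weight <- rep(1 / length(pore_radius), length(pore_radius))
  }
  if (length(pore_weight) != length(pore_radius)) {
    stop_bad("`pore_weight` must match `pore_radius` in length")
  }
  if (abs(sum(pore_weight) - 1) > 1e-8) {
    stop_bad("`pore_weight` must sum to 1")
  }
  r <- stokes_radius(molecular_mass, calibration)
  kd_true <- partition_kd(r, pore_radius, pore_weight)
  vr <- v0 + kd_true * (vt - v0)
  vr <- with_seed(seed, vr + stats::rnorm(length(vr), sd = noise_sd))
  tibble::tibble(
    molecular_mass = molecular_mass,
    stokes_radius = r,
    kd_true = kd_true,
    retention_volume = vr
  )
}

#' Simulate analyte depletion in a recirculating reservoir
#'
#' A well-mixed reservoir of volume V is recirculated at flow Q through
#' an adsorbent cartridge that captures a fraction E (the single-pass
#' extraction efficiency) of the analyte passing it, so
#' \eqn{C(t) = C_0 e^{-(QE/V)t}} with Q in mL/h. With a finite
#' `capacity`, captured mass accumulates until the capacity is reached,
#' after which extraction stops; this saturable variant is integrated
#' by fixed-step Euler (step <= 0.01 h) with exact mass bookkeeping.
#' Noise is multiplicative log-normal, matching the roughly constant
#' coefficient of variation of immunoassays. A no-adsorbent control
#' circuit is the special case `extraction_efficiency = 0`.
#'
#' @param c0 Initial concentration, pg/mL.
#' @param reservoir_volume Reservoir volume, mL (default 60, the bench
#'   scale-down of an adult blood volume).
#' @param flow Circuit flow, mL/min (default 1).
#' @param extraction_efficiency Single-pass extraction fraction in
#'   [0, 1].
#' @param capacity Optional adsorbent capacity, pg; `NULL` for the
#'   unsaturable closed form.
#' @param timepoints Sampling times, hours.
#' @param noise_cv Log-normal noise scale (SD of log concentration).
#' @param seed Optional integer seed.
#' @param analyte,condition Labels carried into the output.
#'
#' @return A tibble in the long concentration-series format (`analyte`,
#'   `condition`, `time_h`, `concentration`, `censored`, `lod`) with a
#'   `mass_balance` attribute recording, per timepoint, the noise-free
#'   reservoir and captured masses (pg).
#' @examples
#' simulate_depletion(1000, extraction_efficiency = 0.6, timepoints = 0:6)
#' @export
simulate_depletion <- function(c0, reservoir_volume = 60, flow = 1,
                               extraction_efficiency = 0, capacity = NULL,
                               timepoints = 0:6, noise_cv = 0, seed = NULL,
                               analyte = "analyte", condition = "treated") {
  check_scalar_pos(c0, "c0")
  check_scalar_pos(reservoir_volume, "reservoir_volume")
  check_scalar_pos(flow, "flow")
  if (!is.numeric(extraction_efficiency) || extraction_efficiency < 0 ||
      extraction_efficiency > 1) {
    stop_bad("`extraction_efficiency` must lie in [0, 1]")
  }
  check_numeric_pos(timepoints, "timepoints", strict = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop_bad("`timepoints` must be strictly increasing")
  }
  check_scalar_pos(noise_cv, "noise_cv", strict = FALSE)
  q_h <- 60 * flow # mL/h
  if (is.null(capacity)) {
    conc <- c0 * exp(-(q_h * extraction_efficiency / reservoir_volume) * timepoints)
    captured <- (c0 - conc) * reservoir_volume
  } else {
    check_scalar_pos(capacity, "capacity")
    dt <- 0.01
    t_end <- max(timepoints)
    n_step <- ceiling(t_end / dt + 1e-9)
    t_grid <- seq(0, by = dt, length.out = n_step + 1L)
    m <- c0 * reservoir_volume # reservoir mass, pg
    cap_used <- 0
    m_path <- numeric(n_step + 1L)
    cap_path <- numeric(n_step + 1L)
    m_path[1L] <- m
    for (i in seq_len(n_step)) {
      take <- q_h * extraction_efficiency * (m / reservoir_volume) * dt
      take <- min(take, capacity - cap_used) # saturation: stop at capacity
      m <- m - take
      cap_used <- cap_used + take
      m_path[i + 1L] <- m
      cap_path[i + 1L] <- cap_used
    }
    conc <- stats::approx(t_grid, m_path, xout = timepoints)$y / reservoir_volume
    captured <- stats::approx(t_grid, cap_path, xout = timepoints)$y
  }
  obs <- with_seed(seed, {
    if (noise_cv > 0) {
      conc * exp(stats::rnorm(length(conc), sd = noise_cv))
    } else {
      conc
    }
  })
  out <- tibble::tibble(
    analyte = analyte, condition = condition,
    time_h = timepoints, concentration = obs,
    censored = FALSE, lod = NA_real_
  )
  attr(out, "mass_balance") <- tibble::tibble(
    time_h = timepoints,
    reservoir_mass = conc * reservoir_volume,
    captured_mass = captured
  )
  out
}

#' Simulate a sigmoid dose-response series
#'
#' Mean response follows a Hill curve,
#' \eqn{baseline + E_{max} d^h / (EC_{50}^h + d^h)}. Observed replicate
#' means are drawn with standard error `noise_sd / sqrt(n)`; the
#' reported per-dose SD is the generator's `noise_sd` itself. The
#' default dose grid is the standard plasma-spiking series 0 to
#' 10000 pg/mL after tenfold dilution into culture medium.
#'
#' @param baseline Baseline (zero-dose) response, assay units.
#' @param emax Maximal response increment above baseline.
#' @param ec50 Dose of half-maximal response, pg/mL.
#' @param hill Hill coefficient.
#' @param doses Dose grid, pg/mL.
#' @param noise_sd Replicate SD of the response, assay units.
#' @param n Replicates per dose.
#' @param seed Optional integer seed.
#' @param marker Label carried into the output.
#'
#' @return A tibble with columns `marker`, `dose`, `response_mean`,
#'   `response_sd`, `n`, `response_true`.
#' @examples
#' simulate_dose_response(300, 5000, ec50 = 22, hill = 4, seed = 1)
#' @export
simulate_dose_response <- function(baseline, emax, ec50, hill,
                                   doses = effective_dose(
                                     c(0, 50, 100, 500, 1000, 5000, 10000)
                                   ),
                                   noise_sd = 0, n = 3, seed = NULL,
                                   marker = "marker") {
  check_scalar_pos(baseline, "baseline")
  check_scalar_pos(emax, "emax")
  check_scalar_pos(ec50, "ec50")
  check_scalar_pos(hill, "hill")
  check_numeric_pos(doses, "doses", strict = FALSE)
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  if (!is.numeric(n) || n < 1) stop_bad("`n` must be >= 1")
  mu <- baseline + emax * doses^hill / (ec50^hill + doses^hill)
  obs <- with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd / sqrt(n)))
  tibble::tibble(
    marker = marker, dose = doses,
    response_mean = obs, response_sd = noise_sd, n = as.integer(n),
    response_true = mu
  )
}
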