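#' Fit a power-law Stokes-radius calibration
#'
#' Polystyrene coils in a good solvent follow a power law
#' \eqn{R_S = a \, M^b} between molecular mass and Stokes (viscosity)
#' radius. The calibration is fitted by ordinary least squares in
#' log-log space, `log(R_S) = log(a) + b log(M)`, and carries the
#' log-log coefficient of determination as a quality measure.
#'
#' Only genuine size standards belong in the fit: a small-molecule
#' tracer such as toluene is not a polymer coil and does not follow the
#' polystyrene power law.
#'
#' @param molecular_mass Molecular masses of the standards, Da.
#' @param stokes_radius Their Stokes radii, nm.
#'
#' @return An object of class `stokes_calibration` with elements
#'   `prefactor` (nm per Da^exponent), `exponent`, `r_squared`
#'   (log-log), and `n`.
#' @examples
#' fit_stokes_calibration(c(100, 10000), c(1, 10)) # exact: a = 0.1, b = 0.5
#' @seealso [stokes_radius()] to evaluate the fitted law.
#' @export
fit_stokes_calibration <- function(molecular_mass, stokes_radius) {
  check_numeric_pos(molecular_mass, "molecular_mass")
  check_numeric_pos(stokes_radius, "stokes_radius")
  if (length(molecular_mass) != length(stokes_radius)) {
    stop_bad("`molecular_mass` and `stokes_radius` must have equal length")
  }
  if (length(unique(molecular_mass)) < 2L) {
    stop_bad("at least 2 standards with distinct molecular masses are required")
  }
  fit <- stats::lm(log(stokes_radius) ~ log(molecular_mass))
  r2 <- if (length(molecular_mass) > 2L) summary(fit)$r.squared else 1
  structure(
    list(
      prefactor = unname(exp(stats::coef(fit)[1L])),
      exponent = unname(stats::coef(fit)[2L]),
      r_squared = r2,
      n = length(molecular_mass)
    ),
    class = "stokes_calibration"
  )
}

#' @export
print.stokes_calibration <- function(x, ...) {
  cat(sprintf(
    "Stokes calibration: R_S = %.4g * M^%.4g nm (n = %d, log-log R^2 = %.6f)\n",
    x$prefactor, x$exponent, x$n, x$r_squared
  ))
  invisible(x)
}

#' Stokes radius predicted by a calibration
#'
#' @param molecular_mass Molecular mass(es), Da.
#' @param calibration A [fit_stokes_calibration()] object, or any list
#'   with `prefactor` and `exponent`.
#' @return Stokes radius in nm.
#' @examples
#' cal <- fit_stokes_calibration(c(100, 10000), c(1, 10))
#' stokes_radius(570, cal)
#' @export
stokes_radius <- function(molecular_mass, calibration) {
  check_numeric_pos(molecular_mass, "molecular_mass")
  check_scalar_pos(calibration$prefactor, "calibration$prefactor")
  calibration$prefactor * molecular_mass^calibration$exponent
}

#' Pore diameter excluding a polystyrene coil of given mass
#'
#' The empirical exclusion correlation \eqn{M_W = 2.25 \times \Phi^{1.7}}
#' links the molecular mass of a polystyrene sample to the diameter
#' \eqn{\Phi} (in Angstrom) of the smallest cylindrical pore it can
#' still enter. This function inverts it,
#' \eqn{\Phi = (M_W / 2.25)^{1/1.7}}; [exclusion_mass_from_diameter()]
#' is the forward direction.
#'
#' @param molecular_mass Molecular mass(es), Da.
#' @param coefficient,exponent Correlation constants; defaults 2.25 and
#'   1.7 as established for polystyrene.
#' @return Pore diameter(s) in Angstrom.
#' @examples
#' exclusion_diameter_from_mass(2.25) # 1 Angstrom
#' @export
exclusion_diameter_from_mass <- function(molecular_mass, coefficient = 2.25,
                                         exponent = 1.7) {
  check_numeric_pos(molecular_mass, "molecular_mass")
  check_scalar_pos(coefficient, "coefficient")
  check_scalar_pos(exponent, "exponent")
  (molecular_mass / coefficient)^(1 / exponent)
}

#' @rdname exclusion_diameter_from_mass
#' @param diameter Pore diameter(s) in Angstrom.
#' @export
exclusion_mass_from_diameter <- function(diameter, coefficient = 2.25,
                                         exponent = 1.7) {
  check_numeric_pos(diameter, "diameter")
  check_scalar_pos(coefficient, "coefficient")
  check_scalar_pos(exponent, "exponent")
  coefficient * diameter^exponent
}
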