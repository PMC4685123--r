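#' Column geometry for a packed chromatography column
#'
#' @param inner_diameter Inner diameter of the column in cm.
#' @param length Packed bed length in cm.
#'
#' @return An object of class `column_geometry`.
#' @examples
#' column_geometry(0.46, 15)
#' @export
column_geometry <- function(inner_diameter, length) {
  check_scalar_pos(inner_diameter, "inner_diameter")
  check_scalar_pos(length, "length")
  structure(
    list(inner_diameter = inner_diameter, length = length),
    class = "column_geometry"
  )
}

#' Geometric bed volume of a cylindrical column
#'
#' The bed volume \eqn{V_B} of a packed column is the cylinder volume
#' \eqn{\pi (d/2)^2 L}. It is the denominator anchor of the intraparticle
#' porosity calculation; see [porosity()].
#'
#' @param geometry A [column_geometry()] object.
#' @return Bed volume in mL.
#' @examples
#' column_bed_volume(column_geometry(0.46, 15)) # ~2.49 mL
#' @export
column_bed_volume <- function(geometry) {
  stopifnot(inherits(geometry, "column_geometry"))
  pi * (geometry$inner_diameter / 2)^2 * geometry$length
}

#' Characteristic mobile-phase volumes of a packed column
#'
#' `v0` is the interparticle void volume measured with a fully excluded
#' probe, `vt` the total mobile-phase volume measured with a small
#' fully permeating tracer, and `vb` the column bed volume. The
#' physically required ordering `0 < v0 < vt <= vb` is enforced: a
#' supplied `vb` smaller than `vt` is impossible (the mobile phase
#' cannot exceed the bed that holds it) and raises an error naming the
#' offending values rather than silently producing porosities above
#' 100 percent.
#'
#' @param v0 Interparticle void volume, mL.
#' @param vt Total mobile-phase volume, mL.
#' @param vb Optional column bed volume, mL. Usually derived from
#'   [column_bed_volume()] and supplied by [characterize_adsorbent()].
#'
#' @return An object of class `column_volumes`.
#' @examples
#' column_volumes(v0 = 1.13, vt = 2.31, vb = 2.493)
#' @export
column_volumes <- function(v0, vt, vb = NULL) {
  check_scalar_pos(v0, "v0")
  check_scalar_pos(vt, "vt")
  if (vt <= v0) {
    stop_bad(sprintf(
      "total mobile-phase volume vt (%g mL) must exceed void volume v0 (%g mL)",
      vt, v0
    ))
  }
  if (!is.null(vb)) {
    check_scalar_pos(vb, "vb")
    if (vt > vb) {
      stop_bad(sprintf(
        "inconsistent column volumes: vt = %g mL exceeds bed volume vb = %g mL",
        vt, vb
      ))
    }
  }
  structure(list(v0 = v0, vt = vt, vb = vb), class = "column_volumes")
}

#' @export
print.column_volumes <- function(x, ...) {
  cat(sprintf(
    "Column volumes: V0 = %.2f mL, VT = %.2f mL, VB = %s mL\n",
    x$v0, x$vt, if (is.null(x$vb)) "<unset>" else sprintf("%.3f", x$vb)
  ))
  invisible(x)
}

#' SEC distribution coefficient from a retention volume
#'
#' Computes \eqn{K_d = (V_R - V_0) / (V_T - V_0)}, the fraction of the
#' intraparticle mobile-phase volume accessible to a probe: 0 for a
#' fully excluded solute (elutes at the void volume) and 1 for a small
#' tracer that permeates the entire pore volume. The raw value is
#' returned unclamped; measurement noise can push it slightly outside
#' [0, 1] and clamping is the caller's decision (see [isec_profile()]).
#'
#' @param vr Retention volume(s), mL. May be a vector.
#' @param volumes A [column_volumes()] object.
#'
#' @return Raw distribution coefficient(s), dimensionless.
#' @examples
#' vols <- column_volumes(v0 = 1.06, vt = 2.30)
#' compute_kd(2.30, vols) # tracer, 1
#' compute_kd(1.06, vols) # excluded probe, 0
#' @export
compute_kd <- function(vr, volumes) {
  stopifnot(inherits(volumes, "column_volumes"))
  check_numeric_pos(vr, "vr", strict = FALSE)
  (vr - volumes$v0) / (volumes$vt - volumes$v0)
}

#' Intraparticle porosity of a packed adsorbent
#'
#' \eqn{\varepsilon_P = (V_T - V_0) / (V_B - V_0)}, expressed in
#' percent: the fraction of the interstitial-free bed occupied by
#' intraparticle pore space. Requires a bed volume; the
#' `column_volumes` invariant `vt <= vb` guarantees the result lies in
#' (0, 100].
#'
#' @param volumes A [column_volumes()] object with `vb` set.
#' @return Porosity in percent.
#' @examples
#' porosity(column_volumes(v0 = 1.13, vt = 2.31, vb = 2.4929)) # ~86.6
#' @export
porosity <- function(volumes) {
  stopifnot(inherits(volumes, "column_volumes"))
  if (is.null(volumes$vb)) {
    stop_bad("porosity requires a bed volume: supply `vb` or a column geometry")
  }
  100 * (volumes$vt - volumes$v0) / (volumes$vb - volumes$v0)
}

#' Intraparticle pore volume of a packed adsorbent
#'
#' \eqn{V_P = V_T - V_0}: the mobile-phase volume held inside the
#' particles.
#'
#' @param volumes A [column_volumes()] object.
#' @return Pore volume in mL.
#' @examples
#' pore_volume(column_volumes(v0 = 1.14, vt = 2.25)) # 1.11
#' @export
pore_volume <- function(volumes) {
  stopifnot(inherits(volumes, "column_volumes"))
  volumes$vt - volumes$v0
}
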