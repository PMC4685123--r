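#' Convert a result object into a plain report list
#'
#' Methods flatten the package's result classes into named lists ready
#' for JSON serialization, applying the reporting precision (radii and
#' diameters to 1 decimal in nm, porosity to 1 decimal in percent,
#' volumes to 2 decimals in mL) — rounding happens here only, never
#' inside the computations.
#'
#' @param x A result object.
#' @param ... Passed on to methods.
#' @return A named list of atomic values and tibbles.
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.default <- function(x, ...) x

#' @export
as_report.pore_bracket <- function(x, ...) {
  list(
    adsorbent = x$adsorbent_id,
    threshold = x$threshold,
    pore_radius_nm = list(lower = round1(x$r_lower), upper = round1(x$r_upper)),
    pore_diameter_nm = list(lower = round1(x$d_lower), upper = round1(x$d_upper)),
    open_lower = x$open_lower,
    open_upper = x$open_upper,
    calls = x$calls
  )
}

#' @export
as_report.pore_characterization <- function(x, ...) {
  rep <- as_report(x$bracket)
  rep$route <- x$route
  rep$porosity_percent <- round1(x$porosity_percent)
  rep$pore_volume_ml <- round2(x$pore_volume_ml)
  rep$volumes_ml <- list(
    v0 = round2(x$volumes$v0), vt = round2(x$volumes$vt),
    vb = round2(x$volumes$vb)
  )
  rep
}

#' @export
as_report.depletion_fit <- function(x, ...) {
  list(
    c0_pg_ml = x$c0,
    rate_per_h = x$rate,
    extraction_efficiency = x$extraction_efficiency,
    n_points = x$n_points
  )
}

#' @export
as_report.threshold_bracket <- function(x, ...) {
  list(
    last_inactive_dose = x$last_inactive_dose,
    first_active_dose = x$first_active_dose,
    open_low = x$open_low,
    open_high = x$open_high,
    sd_multiplier = x$sd_multiplier,
    min_fold_change = x$min_fold_change,
    interpolated_dose = x$interpolated_dose,
    calls = x$calls
  )
}

#' @export
as_report.stokes_calibration <- function(x, ...) {
  list(
    prefactor_nm = x$prefactor,
    exponent = x$exponent,
    r_squared_loglog = x$r_squared,
    n_standards = x$n
  )
}

#' Write an analysis report as JSON
#'
#' Serializes a result object (or a named list of them) through
#' [as_report()], stamped with the package version. Stable key order;
#' round-trips through [jsonlite::read_json()].
#'
#' @param results A result object or named list of result objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' \dontrun{
#' write_report(list(scale_down = scale_down_factor(300, 5)), "report.json")
#' }
#' @export
write_report <- function(results, path) {
  body <- if (is.list(results) && is.null(attr(results, "class"))) {
    lapply(results, as_report)
  } else {
    as_report(results)
  }
  doc <- list(
    package = "adsorbkit",
    version = as.character(utils::packageVersion("adsorbkit")),
    results = body
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
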