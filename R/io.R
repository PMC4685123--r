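# delimiter sniffing: comma default, tab when the header contains one
read_delimited <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE, colClasses = "character")
}

parse_numeric_col <- function(x, column, allow_na = FALSE) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop_bad(sprintf(
      "malformed numeric value '%s' in column '%s', row %d",
      x[which(bad)[1L]], column, which(bad)[1L]
    ))
  }
  if (!allow_na && anyNA(out)) {
    stop_bad(sprintf("missing value in column '%s', row %d",
                     column, which(is.na(out))[1L]))
  }
  out
}

# "<2"-style entries become (NA, censored = TRUE, lod = 2)
parse_censored_col <- function(x, column) {
  cens <- grepl("^\\s*<", x)
  lod <- rep(NA_real_, length(x))
  value <- x
  value[cens] <- NA_character_
  lod[cens] <- parse_numeric_col(sub("^\\s*<\\s*", "", x[cens]), column)
  list(
    value = parse_numeric_col(value, column, allow_na = TRUE),
    censored = cens,
    lod = lod
  )
}

require_columns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop_bad(sprintf(
      "'%s' lacks required column(s): %s (found: %s)",
      path, paste(missing_cols, collapse = ", "),
      paste(names(df), collapse = ", ")
    ))
  }
}

#' Read a long-format concentration series file
#'
#' Expects columns `analyte`, `condition`, `time_h`,
#' `concentration_pg_ml` and optionally `sd_pg_ml` and `n`. Comma or
#' tab delimited (auto-detected). Left-censored entries written as
#' `<x` (e.g. `<2`) are parsed into a `censored` flag with `lod = x`
#' and a missing concentration, ready for [removal_table()]'s
#' substitution rules.
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `analyte`, `condition`, `time_h`,
#'   `concentration`, `censored`, `lod`, and when present `sd`, `n`.
#' @examples
#' read_concentration_series(fixture_path("cytokine_endpoints"))
#' @export
read_concentration_series <- function(path) {
  df <- read_delimited(path)
  require_columns(df, c("analyte", "condition", "time_h", "concentration_pg_ml"),
                  path)
  conc <- parse_censored_col(df$concentration_pg_ml, "concentration_pg_ml")
  out <- tibble::tibble(
    analyte = df$analyte,
    condition = df$condition,
    time_h = parse_numeric_col(df$time_h, "time_h"),
    concentration = conc$value,
    censored = conc$censored,
    lod = conc$lod
  )
  if (!is.null(df$sd_pg_ml)) {
    out$sd <- parse_numeric_col(df$sd_pg_ml, "sd_pg_ml", allow_na = TRUE)
  }
  if (!is.null(df$n)) out$n <- parse_numeric_col(df$n, "n", allow_na = TRUE)
  out
}

#' Read a size-standards calibration file
#'
#' Expects columns `molecular_mass` and optionally `stokes_radius` and
#' `role` (`"standard"` or `"tracer"`; a small-molecule tracer anchors
#' the total mobile-phase volume but does not belong in a polymer
#' Stokes calibration).
#'
#' @param path Path to the delimited file.
#' @param standards_only Drop tracer rows (default `TRUE`).
#' @return A tibble with `molecular_mass` and, when present,
#'   `stokes_radius` and `role`.
#' @examples
#' read_standards(fixture_path("polystyrene_standards"))
#' @export
read_standards <- function(path, standards_only = TRUE) {
  df <- read_delimited(path)
  require_columns(df, "molecular_mass", path)
  out <- tibble::tibble(
    molecular_mass = parse_numeric_col(df$molecular_mass, "molecular_mass")
  )
  if (!is.null(df$stokes_radius)) {
    out$stokes_radius <- parse_numeric_col(df$stokes_radius, "stokes_radius")
  }
  if (!is.null(df$role)) out$role <- df$role
  if (standards_only && !is.null(out[["role"]])) {
    out <- out[out[["role"]] == "standard", , drop = FALSE]
  }
  out
}

#' Read per-adsorbent iSEC measurements
#'
#' Expects `molecular_mass` plus either `kd` or `retention_volume`
#' columns, and optionally `adsorbent`.
#'
#' @param path Path to the delimited file.
#' @return A tibble.
#' @examples
#' read_isec_measurements(fixture_path("isec_kd"))
#' @export
read_isec_measurements <- function(path) {
  df <- read_delimited(path)
  require_columns(df, "molecular_mass", path)
  if (is.null(df$kd) && is.null(df$retention_volume)) {
    stop_bad(sprintf("'%s' needs a `kd` or `retention_volume` column", path))
  }
  out <- tibble::tibble(
    molecular_mass = parse_numeric_col(df$molecular_mass, "molecular_mass")
  )
  if (!is.null(df$adsorbent)) out$adsorbent <- df$adsorbent
  if (!is.null(df$kd)) out$kd <- parse_numeric_col(df$kd, "kd")
  if (!is.null(df$retention_volume)) {
    out$retention_volume <- parse_numeric_col(df$retention_volume,
                                              "retention_volume")
  }
  out
}

fixture_files <- c(
  polystyrene_standards = "polystyrene_standards.csv",
  isec_kd = "isec_kd.csv",
  isec_columns = "isec_columns.csv",
  cytokine_endpoints = "cytokine_endpoints.csv",
  particle_size = "particle_size.csv",
  huvec_secretion = "huvec_secretion.csv"
)

#' Path to a bundled fixture file
#'
#' The package ships the published characterization tables of three
#' polystyrene-divinylbenzene hemoadsorbents (Amberchrom CG161c and
#' CG300m, and a clinically approved hemoperfusion adsorbent, HAC) as
#' plain CSV: the polystyrene standards with Stokes radii, the
#' per-adsorbent Kd profiles and column volumes, the 6-hour endpoint
#' cytokine concentrations of the recirculating scale-down experiment
#' (with below-LOD entries), and, informationally, particle sizes and
#' HUVEC secretion readouts.
#'
#' @param id One of `"polystyrene_standards"`, `"isec_kd"`,
#'   `"isec_columns"`, `"cytokine_endpoints"`, `"particle_size"`,
#'   `"huvec_secretion"`.
#' @return File path.
#' @export
fixture_path <- function(id) {
  id <- match.arg(id, names(fixture_files))
  system.file("extdata", fixture_files[[id]], package = "adsorbkit",
              mustWork = TRUE)
}

#' Load a bundled fixture as a tibble
#'
#' @inheritParams fixture_path
#' @return A parsed tibble; `cytokine_endpoints` comes through
#'   [read_concentration_series()] with censoring resolved into flags,
#'   the others through the matching readers or a plain delimited read.
#' @examples
#' load_fixture("polystyrene_standards")
#' @export
load_fixture <- function(id) {
  id <- match.arg(id, names(fixture_files))
  path <- fixture_path(id)
  switch(id,
    polystyrene_standards = read_standards(path, standards_only = FALSE),
    isec_kd = read_isec_measurements(path),
    cytokine_endpoints = read_concentration_series(path),
    {
      df <- read_delimited(path)
      for (col in names(df)) {
        num <- suppressWarnings(as.numeric(df[[col]]))
        if (!anyNA(num)) df[[col]] <- num
      }
      tibble::as_tibble(df)
    }
  )
}

#' Column volume anchors of a bundled adsorbent
#'
#' Convenience accessor over the `isec_columns` fixture: returns the
#' [column_volumes()] of one adsorbent, with the bed volume computed
#' geometrically from the recorded column dimensions.
#'
#' @param adsorbent `"CG161c"`, `"CG300m"` or `"HAC"`.
#' @return A [column_volumes()] object.
#' @examples
#' fixture_column_volumes("HAC")
#' @export
fixture_column_volumes <- function(adsorbent) {
  cols <- load_fixture("isec_columns")
  row <- cols[cols$adsorbent == adsorbent, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop_bad("unknown adsorbent '", adsorbent, "' in the isec_columns fixture")
  }
  geom <- column_geometry(row$inner_diameter_cm, row$length_cm)
  column_volumes(row$v0_ml, row$vt_ml, vb = column_bed_volume(geom))
}
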