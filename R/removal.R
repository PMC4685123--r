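#' Removal percentage relative to a reference concentration
#'
#' `100 * (1 - treated / reference)`. In the recirculating scale-down
#' model the reference is the no-adsorbent control circuit at the same
#' endpoint, which nets out any loss or generation unrelated to the
#' adsorbent. Values may be negative (treated above reference); they
#' are returned as-is and flagged downstream by [removal_table()].
#'
#' @param treated_final Endpoint concentration in the treated circuit,
#'   pg/mL.
#' @param control_final Endpoint concentration in the reference
#'   circuit, pg/mL. Must be positive.
#' @return Removal in percent. Vectorized.
#' @examples
#' removal_percent(177, 3102) # ~94.3
#' @export
removal_percent <- function(treated_final, control_final) {
  check_numeric_pos(treated_final, "treated_final", strict = FALSE)
  check_numeric_pos(control_final, "control_final", strict = TRUE)
  100 * (1 - treated_final / control_final)
}

resolve_censored <- function(concentration, censored, lod,
                             rule = c("lod2", "lod", "zero")) {
  rule <- match.arg(rule)
  sub <- switch(rule, lod2 = lod / 2, lod = lod, zero = 0)
  ifelse(censored, sub, concentration)
}

#' Removal summaries for a set of concentration series
#'
#' Builds one removal summary per (analyte, adsorbent) pair from
#' long-format concentration series. The endpoint for each analyte is
#' the latest timepoint shared by the treated and reference series.
#' Left-censored measurements ("below LOD") are substituted by the
#' configured rule and flagged in the output. When per-condition SDs
#' are present, an approximate removal SD is propagated to first order.
#'
#' @param series Data frame in long format with columns `analyte`,
#'   `condition`, `time_h`, `concentration`, `censored` (logical),
#'   `lod`, and optionally `sd` and `n`. See
#'   [read_concentration_series()].
#' @param censor Substitution rule for censored values: half the limit
#'   of detection (`"lod2"`, default), the limit itself (`"lod"`), or
#'   zero (`"zero"`).
#' @param reference `"control"` (default): reference is the control
#'   condition at the same endpoint. `"t0"`: reference is the treated
#'   series' own first timepoint.
#' @param control_label Condition label of the no-adsorbent control.
#'
#' @return A tibble with one row per (analyte, adsorbent):
#'   `analyte`, `adsorbent`, `removal_percent`, `removal_sd`
#'   (approximate, `NA` without input SDs), `reference`,
#'   `reference_time`, `censored` (treated or reference value
#'   substituted) and `negative` (treated above reference).
#' @examples
#' tab <- load_fixture("cytokine_endpoints")
#' removal_table(tab)
#' @export
removal_table <- function(series, censor = c("lod2", "lod", "zero"),
                          reference = c("control", "t0"),
                          control_label = "control") {
  censor <- match.arg(censor)
  reference <- match.arg(reference)
  needed <- c("analyte", "condition", "time_h", "concentration")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols)) {
    stop_bad("`series` lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(series[["censored"]])) series$censored <- FALSE
  if (is.null(series[["lod"]])) series$lod <- NA_real_
  has_sd <- !is.null(series[["sd"]])
  if (!has_sd) series$sd <- NA_real_
  if (nrow(series) == 0L) {
    return(tibble::tibble(
      analyte = character(), adsorbent = character(),
      removal_percent = double(), removal_sd = double(),
      reference = character(), reference_time = double(),
      censored = logical(), negative = logical()
    ))
  }
  series$concentration <- resolve_censored(
    series$concentration, series$censored, series$lod, censor
  )

  rows <- list()
  for (an in unique(series$analyte)) {
    sub <- series[series$analyte == an, , drop = FALSE]
    treatments <- setdiff(unique(sub$condition), control_label)
    ctrl <- sub[sub$condition == control_label, , drop = FALSE]
    if (reference == "control" && nrow(ctrl) == 0L) {
      stop_bad(sprintf("no '%s' series found for analyte '%s'", control_label, an))
    }
    for (tr in treatments) {
      trt <- sub[sub$condition == tr, , drop = FALSE]
      if (reference == "control") {
        t_end <- max(intersect(trt$time_h, ctrl$time_h))
        ref_row <- ctrl[ctrl$time_h == t_end, , drop = FALSE][1L, ]
        ref_label <- control_label
      } else {
        t_end <- max(trt$time_h)
        ref_row <- trt[trt$time_h == min(trt$time_h), , drop = FALSE][1L, ]
        ref_label <- "t0"
      }
      trt_row <- trt[trt$time_h == t_end, , drop = FALSE][1L, ]
      r <- removal_percent(trt_row$concentration, ref_row$concentration)
      r_sd <- NA_real_
      if (has_sd && !is.na(trt_row$sd) && !is.na(ref_row$sd)) {
        # first-order propagation of the ratio T/C; approximate only
        r_sd <- 100 * sqrt(
          (trt_row$sd / ref_row$concentration)^2 +
            (trt_row$concentration * ref_row$sd / ref_row$concentration^2)^2
        )
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analyte = an, adsorbent = tr,
        removal_percent = r, removal_sd = r_sd,
        reference = ref_label, reference_time = t_end,
        censored = isTRUE(trt_row$censored) || isTRUE(ref_row$censored),
        negative = r < 0
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$analyte, out$adsorbent), ]
}

#' Scale-down factor between a clinical device and its bench model
#'
#' @param clinical_volume Clinical-scale volume (e.g. a 300 mL
#'   adsorbent cartridge), mL.
#' @param model_volume Bench-scale counterpart (e.g. a 5 mL cartridge),
#'   mL.
#' @return Dimensionless ratio `clinical_volume / model_volume`.
#' @examples
#' scale_down_factor(300, 5) # 60
#' @export
scale_down_factor <- function(clinical_volume, model_volume) {
  check_numeric_pos(clinical_volume, "clinical_volume")
  check_numeric_pos(model_volume, "model_volume")
  clinical_volume / model_volume
}

#' Superficial linear velocity in a packed column
#'
#' Converts a volumetric flow into the superficial (empty-column)
#' linear velocity, the quantity matched when scaling a clinical
#' cartridge down to a bench column.
#'
#' @param flow Volumetric flow, mL/min.
#' @param inner_diameter Column inner diameter, cm.
#' @return Linear velocity in cm/h.
#' @examples
#' linear_velocity(1, 1.18) # ~55 cm/h
#' @export
linear_velocity <- function(flow, inner_diameter) {
  check_numeric_pos(flow, "flow")
  check_numeric_pos(inner_diameter, "inner_diameter")
  60 * flow / (pi * (inner_diameter / 2)^2)
}

#' Fit a single-compartment depletion model to a concentration series
#'
#' Models a well-mixed recirculation reservoir feeding an adsorbent
#' cartridge with constant single-pass extraction efficiency E:
#' \eqn{C(t) = C_0 e^{-kt}} with \eqn{k = Q E / V} (Q the flow in
#' mL/h, V the reservoir volume). `c0` and `rate` come from log-linear
#' least squares on the uncensored points; the extraction efficiency is
#' derived as \eqn{E = k V / Q} and clipped to [0, 1] with a warning
#' when sampling noise pushes it outside.
#'
#' @param time_h Sampling times, hours.
#' @param concentration Concentrations, pg/mL.
#' @param reservoir_volume Reservoir volume, mL.
#' @param flow Circuit flow, mL/min.
#' @param censored Optional logical flags; censored points are dropped
#'   from the fit.
#'
#' @return An object of class `depletion_fit` with `c0` (pg/mL), `rate`
#'   (per hour), `extraction_efficiency`, and `n_points`.
#' @examples
#' t <- 0:6
#' fit_depletion(t, 1000 * exp(-0.5 * t), reservoir_volume = 60, flow = 1)
#' @export
fit_depletion <- function(time_h, concentration, reservoir_volume, flow,
                          censored = NULL) {
  check_scalar_pos(reservoir_volume, "reservoir_volume")
  check_scalar_pos(flow, "flow")
  if (is.null(censored)) censored <- rep(FALSE, length(time_h))
  keep <- !censored
  time_h <- time_h[keep]
  concentration <- concentration[keep]
  if (length(time_h) < 3L) {
    stop_bad("depletion fit needs at least 3 uncensored points")
  }
  check_numeric_pos(concentration, "concentration")
  fit <- stats::lm(log(concentration) ~ time_h)
  rate <- -unname(stats::coef(fit)[2L])
  if (rate < 0) {
    # numerically-zero slopes (exactly flat series) clip silently
    if (rate < -1e-10) {
      warning("estimated depletion rate was negative; clipped to 0",
              call. = FALSE)
    }
    rate <- 0
  }
  eff <- rate * reservoir_volume / (60 * flow)
  if (eff > 1) {
    warning(sprintf(
      "derived extraction efficiency %.3g exceeds 1; clipped", eff
    ), call. = FALSE)
    eff <- 1
  }
  structure(
    list(
      c0 = unname(exp(stats::coef(fit)[1L])),
      rate = rate,
      extraction_efficiency = eff,
      n_points = length(time_h)
    ),
    class = "depletion_fit"
  )
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf(
    "Depletion fit: C0 = %.4g pg/mL, rate = %.4g /h, E = %.3f (n = %d)\n",
    x$c0, x$rate, x$extraction_efficiency, x$n_points
  ))
  invisible(x)
}
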