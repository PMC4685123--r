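#' Effective dose after dilution into culture medium
#'
#' Spiked plasma added at one part in `dilution_factor` of the culture
#' volume exposes the cells to `spiked / dilution_factor`. The default
#' 10 corresponds to culturing with 10 percent plasma.
#'
#' @param spiked Spiked concentration(s), pg/mL.
#' @param dilution_factor Dilution factor, >= 1.
#' @return Effective dose(s), pg/mL.
#' @examples
#' effective_dose(c(0, 50, 100, 500, 1000, 5000, 10000))
#' @export
effective_dose <- function(spiked, dilution_factor = 10) {
  check_numeric_pos(spiked, "spiked", strict = FALSE)
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1L ||
      is.na(dilution_factor) || dilution_factor < 1) {
    stop_bad("`dilution_factor` must be a single number >= 1")
  }
  spiked / dilution_factor
}

#' Bracket the activation threshold of a dose-response series
#'
#' Calls each dose "active" when its mean response satisfies both of
#' two criteria relative to the zero-dose baseline: it exceeds
#' `baseline_mean + sd_multiplier * baseline_sd` (separation from
#' baseline noise) and it is at least `min_fold_change` times the
#' baseline mean (biological relevance). The activation threshold is
#' then bracketed by the largest inactive dose below the first active
#' dose and the first active dose itself; design doses, not
#' interpolated values, are reported, matching how thresholds are read
#' off a dose series. Both sub-rule verdicts are reported per dose.
#'
#' A series with no active dose yields an open-above bracket
#' (`open_high`); a series active already at its first nonzero dose
#' brackets against the baseline dose and is flagged `open_low` (the
#' true threshold may lie below the tested range). Both are flagged
#' results, not errors.
#'
#' @param series Data frame with columns `dose`, `response_mean`, and
#'   optionally `response_sd` (default 0) and `n`. Must contain a
#'   zero-dose baseline row.
#' @param sd_multiplier Baseline-SD multiple a response must exceed.
#' @param min_fold_change Minimum fold change over baseline.
#' @param interpolate If `TRUE`, also report a log-linear interpolated
#'   crossing dose inside the bracket (never the default report).
#'
#' @return An object of class `threshold_bracket`: `last_inactive_dose`,
#'   `first_active_dose`, flags `open_low`/`open_high`, per-dose
#'   `calls` tibble (columns `dose`, `response_mean`, `above_noise`,
#'   `above_fold`, `active`), and optionally `interpolated_dose`.
#' @examples
#' dr <- data.frame(
#'   dose = c(0, 5, 10, 50, 100),
#'   response_mean = c(300, 310, 320, 4800, 5100),
#'   response_sd = c(30, 30, 35, 200, 250)
#' )
#' activation_threshold(dr)
#' @export
activation_threshold <- function(series, sd_multiplier = 3,
                                 min_fold_change = 2, interpolate = FALSE) {
  check_scalar_pos(sd_multiplier, "sd_multiplier")
  check_scalar_pos(min_fold_change, "min_fold_change")
  if (!all(c("dose", "response_mean") %in% names(series))) {
    stop_bad("`series` needs columns `dose` and `response_mean`")
  }
  if (is.null(series[["response_sd"]])) series$response_sd <- 0
  series <- series[order(series$dose), , drop = FALSE]
  if (!any(series$dose == 0)) {
    stop_bad("`series` must contain a zero-dose baseline point")
  }
  base <- series[series$dose == 0, , drop = FALSE][1L, ]
  noise_cut <- base$response_mean + sd_multiplier * base$response_sd
  fold_cut <- min_fold_change * base$response_mean
  nonzero <- series[series$dose > 0, , drop = FALSE]
  above_noise <- nonzero$response_mean > noise_cut
  above_fold <- nonzero$response_mean >= fold_cut
  active <- above_noise & above_fold
  calls <- tibble::tibble(
    dose = nonzero$dose,
    response_mean = nonzero$response_mean,
    above_noise = above_noise,
    above_fold = above_fold,
    active = active
  )
  if (!any(active)) {
    first_active <- NA_real_
    last_inactive <- max(nonzero$dose)
    open_low <- FALSE
    open_high <- TRUE
  } else {
    i <- min(which(active))
    first_active <- nonzero$dose[i]
    last_inactive <- if (i == 1L) 0 else nonzero$dose[i - 1L]
    open_low <- i == 1L
    open_high <- FALSE
  }
  out <- list(
    last_inactive_dose = last_inactive,
    first_active_dose = first_active,
    open_low = open_low,
    open_high = open_high,
    sd_multiplier = sd_multiplier,
    min_fold_change = min_fold_change,
    calls = calls
  )
  if (interpolate && !open_high && !is.na(first_active)) {
    # log-linear crossing of the stricter of the two criterion cuts
    cut <- max(noise_cut, fold_cut)
    y1 <- if (out$last_inactive_dose == 0) base$response_mean else
      calls$response_mean[calls$dose == out$last_inactive_dose]
    y2 <- calls$response_mean[calls$dose == first_active]
    x1 <- max(out$last_inactive_dose, min(nonzero$dose) / 10)
    x2 <- first_active
    f <- (cut - y1) / (y2 - y1)
    out$interpolated_dose <- exp(log(x1) + f * (log(x2) - log(x1)))
  }
  structure(out, class = "threshold_bracket")
}

#' @export
print.threshold_bracket <- function(x, ...) {
  lo <- x$last_inactive_dose
  hi <- if (is.na(x$first_active_dose)) "above tested range" else
    sprintf("%g", x$first_active_dose)
  cat(sprintf(
    "Activation threshold bracket: (%g, %s) pg/mL%s%s\n",
    lo, hi,
    if (x$open_low) " [open below]" else "",
    if (x$open_high) " [open above]" else ""
  ))
  invisible(x)
}

#' Expression or secretion relative to a positive control
#'
#' Plain ratio normalization: `100 * sample / positive_control`,
#' in percent. No background or isotype subtraction is applied; feed
#' background-corrected values if that is the convention of the assay.
#'
#' @param sample_value Sample readout, assay units.
#' @param positive_control_value Positive-control readout, same units,
#'   must be positive.
#' @return Relative expression in percent. Vectorized.
#' @examples
#' relative_expression(22, 100) # 22
#' @export
relative_expression <- function(sample_value, positive_control_value) {
  check_numeric_pos(sample_value, "sample_value", strict = FALSE)
  check_numeric_pos(positive_control_value, "positive_control_value")
  100 * sample_value / positive_control_value
}
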