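# internal input checks shared across the package

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name, strict = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_bad(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) stop_bad(sprintf("`%s` must be finite", name))
  if (strict && x <= 0) stop_bad(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (!strict && x < 0) stop_bad(sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}

check_numeric_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_bad(sprintf("`%s` must be numeric without missing values", name))
  }
  bad <- if (strict) x <= 0 else x < 0
  if (any(bad)) {
    stop_bad(sprintf(
      "`%s` must be %s (offending value: %g)",
      name, if (strict) "> 0" else ">= 0", x[which(bad)[1L]]
    ))
  }
  invisible(x)
}

# round only at the reporting surface, never inside computations
round1 <- function(x) round(x, 1L)
round2 <- function(x) round(x, 2L)
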