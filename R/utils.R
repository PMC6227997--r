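# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves going up (93.617 -> 94,
#' 55.5 -> 56), the convention used for all reported whole-number percentages.
#' Base `round()` rounds halves to even, which is unsuitable for reporting.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Classed conditions so callers (and the pipeline driver) can distinguish
# configuration, validation and coverage failures.
abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("spinnerbudget_config_error", "spinnerbudget_error")))
}
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("spinnerbudget_validation_error", "spinnerbudget_error")))
}
abort_coverage <- function(msg) {
  stop(errorCondition(msg, class = c("spinnerbudget_coverage_error", "spinnerbudget_error")))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
}

parse_iso_date <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", x))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: unparseable ISO-8601 date '%s' (row %d)", what, x[bad[1]], bad[1]
    ))
  }
  d
}

parse_iso_datetime <- function(x, what) {
  x2 <- sub("T", " ", x, fixed = TRUE)
  t <- as.POSIXct(x2, format = "%Y-%m-%d %H:%M", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: unparseable ISO-8601 timestamp '%s' (row %d)", what, x[bad[1]], bad[1]
    ))
  }
  t
}

format_iso_datetime <- function(t) format(t, "%Y-%m-%d %H:%M", tz = "UTC")
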