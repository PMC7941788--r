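# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("firexcess_invalid_argument", "error")))
}

stop_missing_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("firexcess_missing_data", "error")))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

# round half away from zero (matches reported integer percentages; base
# round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# locale-independent weekday index, Monday = 1 .. Sunday = 7
weekday_index <- function(dates) {
  wday <- as.POSIXlt(dates)$wday  # 0 = Sunday
  ((wday + 6L) %% 7L) + 1L
}

as_date_strict <- function(x, name = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(d))) stop_invalid(name, " contains values not parseable as ISO-8601 dates")
  d
}

# pairwise Euclidean distance matrix for planar (x, y) in km
distance_matrix <- function(x, y) {
  as.matrix(stats::dist(cbind(x, y)))
}
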