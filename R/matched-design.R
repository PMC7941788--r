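#' Study design for the within-community matched analysis
#'
#' An exposed period plus the bidirectional weekday-matched control rule:
#' each exposed day is contrasted with the same weekday on the
#' `window_weeks` previous and next weeks (4 control days for the default
#' 2-week half-width).
#'
#' @param exposed_dates strictly increasing calendar dates (default the five
#'   consecutive days 2007-10-22..26).
#' @param window_weeks integer half-width of the control window in weeks.
#' @param label free-text label (e.g. "2007 main", "falsification 2000").
#' @param exclude_dates optional dates never used as controls (sensitivity
#'   analyses); selecting a control that falls on one raises an error.
#' @return object of class `study_design`.
#' @export
study_design <- function(exposed_dates = seq(as.Date("2007-10-22"),
                                             as.Date("2007-10-26"), by = "day"),
                         window_weeks = 2, label = "", exclude_dates = NULL) {
  exposed_dates <- as_date_strict(exposed_dates, "exposed_dates")
  if (length(exposed_dates) < 1L || is.unsorted(exposed_dates, strictly = TRUE))
    stop_invalid("exposed_dates must be non-empty and strictly increasing")
  if (!is.numeric(window_weeks) || window_weeks < 1)
    stop_invalid("window_weeks must be >= 1")
  if (!is.null(exclude_dates)) exclude_dates <- as_date_strict(exclude_dates)
  structure(list(exposed_dates = exposed_dates,
                 window_weeks = as.integer(window_weeks),
                 label = label, exclude_dates = exclude_dates),
            class = "study_design")
}

#' Weekday-matched bidirectional control days
#'
#' Returns `exposed_date + 7k` for `k = -window_weeks..window_weeks`,
#' `k != 0`, sorted ascending. All controls share the exposed date's weekday
#' by construction (pure +/- 7k-day arithmetic; no locale or
#' first-day-of-week convention is involved).
#'
#' @param exposed_date a calendar date.
#' @param window_weeks integer half-width in weeks (>= 1).
#' @return Date vector of length `2 * window_weeks`.
#' @examples
#' select_control_days(as.Date("2007-10-22"), 2)
#' @export
select_control_days <- function(exposed_date, window_weeks = 2) {
  exposed_date <- as_date_strict(exposed_date, "exposed_date")
  if (length(exposed_date) != 1L) stop_invalid("exposed_date must be a single date")
  if (!is.numeric(window_weeks) || window_weeks < 1)
    stop_invalid("window_weeks must be >= 1")
  k <- seq_len(as.integer(window_weeks))
  sort(exposed_date + 7L * c(-rev(k), k))
}

# count lookup for one unit; absent cells are 0 (long count data usually
# omit zero rows) unless absent_as_zero = FALSE, which raises instead
panel_lookup <- function(panel, absent_as_zero = TRUE) {
  key <- paste(panel$unit_id, panel$date)
  if (anyDuplicated(key))
    stop_invalid("panel has duplicate (unit_id, date) records: ",
                 paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  counts <- panel$count
  names(counts) <- key
  function(unit, dates) {
    v <- counts[paste(unit, dates)]
    if (anyNA(v)) {
      if (!absent_as_zero) {
        miss <- dates[is.na(v)]
        stop_missing_data("missing count cell(s): ",
                          paste(paste0("(", unit, ", ", miss, ")"), collapse = ", "))
      }
      v[is.na(v)] <- 0
    }
    as.numeric(v)
  }
}

#' Excess count for one unit and exposed day
#'
#' Exposed-day count minus the median of its weekday-matched control-day
#' counts. With the default 2-week window the median of the 4 controls is
#' the mean of the two middle values, so the excess can be negative or
#' half-integer.
#'
#' @param unit_id unit label present in the panel.
#' @param exposed_date exposed calendar date.
#' @param panel count panel data.frame (unit_id, date, count).
#' @param design a [study_design()] (only `window_weeks`/`exclude_dates` used).
#' @param absent_as_zero treat absent (unit, date) records as zero counts
#'   (default); `FALSE` raises a missing-data error naming the cell.
#' @return numeric excess.
#' @export
excess_count <- function(unit_id, exposed_date, panel, design = study_design(),
                         absent_as_zero = TRUE) {
  lk <- panel_lookup(panel, absent_as_zero)
  exposed_date <- as_date_strict(exposed_date, "exposed_date")
  ctrl <- select_control_days(exposed_date, design$window_weeks)
  if (!is.null(design$exclude_dates) && any(ctrl %in% design$exclude_dates))
    stop_invalid("control day(s) ",
                 paste(ctrl[ctrl %in% design$exclude_dates], collapse = ", "),
                 " fall on excluded dates")
  lk(unit_id, exposed_date) - stats::median(lk(unit_id, ctrl))
}

#' Per-unit, per-exposed-day excess panel
#'
#' Applies the median-contrast excess to every (unit, exposed day) pair and
#' attaches the period aggregates: county per-day totals, total excess,
#' total exposed-day admissions, and the percent of total.
#'
#' @inheritParams excess_count
#' @return object of class `excess_panel`: a list with `excess` (data.frame
#'   unit_id, date, excess), `per_day` (county totals per exposed day),
#'   `total_excess`, `total_count`, `percent_excess` (unrounded), `design`.
#' @export
excess_panel <- function(panel, design = study_design(), absent_as_zero = TRUE) {
  units <- sort(unique(panel$unit_id))
  panel$date <- as_date_strict(panel$date, "panel$date")
  lk <- panel_lookup(panel, absent_as_zero)
  ed <- design$exposed_dates
  ctrl <- lapply(ed, select_control_days, window_weeks = design$window_weeks)
  if (!is.null(design$exclude_dates)) {
    bad <- unlist(lapply(ctrl, function(d) d[d %in% design$exclude_dates]))
    if (length(bad))
      stop_invalid("control day(s) fall on excluded dates: ",
                   paste(unique(as.Date(bad, origin = "1970-01-01")), collapse = ", "))
  }
  rows <- vector("list", length(units))
  total_count <- 0
  for (i in seq_along(units)) {
    u <- units[i]
    exp_counts <- lk(u, ed)
    med <- vapply(ctrl, function(d) stats::median(lk(u, d)), numeric(1))
    rows[[i]] <- data.frame(unit_id = u, date = ed,
                            excess = exp_counts - med,
                            stringsAsFactors = FALSE)
    total_count <- total_count + sum(exp_counts)
  }
  exc <- do.call(rbind, rows)
  per_day <- vapply(ed, function(d) sum(exc$excess[exc$date == d]), numeric(1))
  names(per_day) <- as.character(ed)
  total_excess <- sum(per_day)
  structure(list(
    excess = exc, per_day = per_day,
    total_excess = total_excess, total_count = total_count,
    percent_excess = if (total_count > 0) 100 * total_excess / total_count else NA_real_,
    design = design
  ), class = "excess_panel")
}

#' Per-unit mean excess over exposed days (for mapping)
#'
#' @param ep an [excess_panel()].
#' @return named numeric vector, one mean per unit (names = unit ids).
#' @export
mean_excess_for_mapping <- function(ep) {
  stopifnot(inherits(ep, "excess_panel"))
  out <- tapply(ep$excess$excess, ep$excess$unit_id, mean)
  out[sort(names(out))]
}

#' Percent of total admissions attributable to excess
#'
#' `100 * total_excess / total_count`, with the reported value rounded half
#' away from zero to the nearest integer (the convention behind headline
#' figures like "30%").
#'
#' @param total_excess,total_count period totals; `total_count > 0`.
#' @return list with `percent` (unrounded) and `reported` (integer).
#' @export
percent_excess <- function(total_excess, total_count) {
  assert_scalar_number(total_excess, "total_excess")
  assert_scalar_number(total_count, "total_count")
  if (total_count <= 0)
    stop(errorCondition("percent undefined: total_count must be > 0",
                        class = c("firexcess_undefined_percent", "error")))
  p <- 100 * total_excess / total_count
  list(percent = p, reported = as.integer(round_half_away(p)))
}

#' Period summary table row
#'
#' County per-exposed-day totals, their sum, total exposed-day admissions,
#' and the percent of total (both unrounded and reported nearest-integer).
#'
#' @param ep an [excess_panel()], or a numeric vector of per-day county
#'   excess totals together with `total_count`.
#' @param total_count required when `ep` is a plain numeric vector.
#' @return list: `per_day`, `total_excess`, `total_count`,
#'   `percent`, `percent_reported`.
#' @export
period_summary <- function(ep, total_count = NULL) {
  if (inherits(ep, "excess_panel")) {
    per_day <- ep$per_day
    total_count <- ep$total_count
  } else {
    per_day <- as.numeric(ep)
    if (is.null(total_count)) stop_invalid("total_count required for raw per-day input")
  }
  total_excess <- sum(per_day)
  pe <- percent_excess(total_excess, total_count)
  list(per_day = per_day, total_excess = total_excess,
       total_count = total_count,
       percent = pe$percent, percent_reported = pe$reported)
}

#' @export
print.excess_panel <- function(x, ...) {
  cat("Excess panel:", length(unique(x$excess$unit_id)), "units x",
      length(x$design$exposed_dates), "exposed days",
      if (nzchar(x$design$label)) paste0("(", x$design$label, ")") else "", "\n")
  cat("  per-day county excess:", paste(round(x$per_day, 1), collapse = ", "), "\n")
  cat(sprintf("  total excess %.1f of %d admissions (%.1f%%)\n",
              x$total_excess, x$total_count, x$percent_excess))
  invisible(x)
}
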