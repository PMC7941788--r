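# readers/writers for the text interchange formats (CSV, JSON, ESRI ASCII)

#' Read a daily count panel from CSV
#'
#' Expects a header `unit_id,date,count` with ISO-8601 dates and nonnegative
#' integer counts. Duplicate (unit, date) rows, malformed dates, negative or
#' non-integer counts raise errors naming the offending row numbers.
#'
#' @param path CSV path.
#' @return data.frame with `unit_id` (character), `date` (Date), `count`
#'   (integer).
#' @export
read_count_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  if (!identical(names(df)[1:3], c("unit_id", "date", "count")))
    stop_invalid("expected header unit_id,date,count in ", path)
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop_invalid("malformed date(s) at row(s): ",
                 paste(utils::head(which(is.na(d)), 5L), collapse = ", "))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad))
    stop_invalid("counts must be nonnegative integers; bad row(s): ",
                 paste(utils::head(which(bad), 5L), collapse = ", "))
  key <- paste(df$unit_id, df$date)
  if (anyDuplicated(key))
    stop_invalid("duplicate (unit_id, date) row(s): ",
                 paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  data.frame(unit_id = df$unit_id, date = d, count = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Read unit geometry from CSV
#'
#' Expects header `unit_id,x_km,y_km,population`.
#'
#' @param path CSV path.
#' @return geometry data.frame.
#' @export
read_geometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "x_km", "y_km", "population")
  if (!all(need %in% names(df)))
    stop_invalid("geometry CSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$unit_id)) stop_invalid("duplicate unit_ids in ", path)
  if (any(!is.finite(df$x_km)) || any(!is.finite(df$y_km)))
    stop_invalid("non-finite coordinates in ", path)
  if (any(df$population < 1)) stop_invalid("populations must be >= 1")
  df[need]
}

#' Write a count panel / geometry / excess table to CSV
#'
#' Thin wrappers fixing the canonical column layouts so write-then-read
#' round-trips exactly.
#'
#' @param x the object to write.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_count_panel <- function(x, path) {
  utils::write.csv(data.frame(unit_id = x$unit_id,
                              date = format(x$date, "%Y-%m-%d"),
                              count = x$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_panel
#' @export
write_geometry <- function(x, path) {
  utils::write.csv(x[c("unit_id", "x_km", "y_km", "population")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_panel
#' @export
write_excess <- function(x, path) {
  ex <- if (inherits(x, "excess_panel")) x$excess else x
  utils::write.csv(data.frame(unit_id = ex$unit_id,
                              date = format(ex$date, "%Y-%m-%d"),
                              excess = ex$excess),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published county-level excess tables bundled with the package
#'
#' Per-day county excess counts and period totals for the October exposed
#' 5-day windows of the 2000/2003/2004/2007 San Diego study periods, as
#' published (fire years 2003/2007; falsification years 2000/2004). The
#' printed period totals occasionally differ by 1 from the sum of their own
#' printed per-day values; both are provided, and headline percentages are
#' defined against the printed totals.
#'
#' @return list with `per_day` (period_id, day, excess) and `totals`
#'   (period_id, year, window, printed_total_excess, total_count, main).
#' @export
published_excess_tables <- function() {
  dir <- system.file("extdata", package = "firexcess")
  list(per_day = utils::read.csv(file.path(dir, "published_excess_per_day.csv"),
                                 stringsAsFactors = FALSE),
       totals = utils::read.csv(file.path(dir, "published_period_totals.csv"),
                                stringsAsFactors = FALSE))
}
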