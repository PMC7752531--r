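#' Build a study calendar
#'
#' A study calendar fixes the surveillance-week convention and the study
#' window, and derives the integer week grid used everywhere else in the
#' package: week 0 is the surveillance week containing `study_start_date`,
#' and indices increase by one per 7 days. The system-maintenance window is
#' mapped onto that grid, and the first week after maintenance is the
#' *disruption week* that splits the study into pre- and post-disruption
#' periods.
#'
#' @param study_start_date,study_close_date First and last calendar date of
#'   the study window (`Date` or parseable string). The close date is the end
#'   of data collection, which may extend past individual participants'
#'   study-end dates.
#' @param maintenance_start,maintenance_end First and last date of the system
#'   shutdown, inclusive. Must lie strictly inside the study window.
#' @param week_convention One of `"sunday_start"`, `"monday_start"`, `"iso"`.
#'   `"iso"` uses Monday-start weeks (ISO 8601 boundaries).
#' @return An object of class `study_calendar`: a list with the week anchor
#'   date, `study_start_week` (always 0), `study_close_week`,
#'   `maintenance_weeks` (integer vector), `disruption_week`, and the inputs.
#' @seealso [week_of()], [default_calendar()]
#' @export
study_calendar <- function(study_start_date,
                           study_close_date,
                           maintenance_start,
                           maintenance_end,
                           week_convention = c("sunday_start", "monday_start", "iso")) {
  week_convention <- match.arg(week_convention)
  study_start_date <- as.Date(study_start_date)
  study_close_date <- as.Date(study_close_date)
  maintenance_start <- as.Date(maintenance_start)
  maintenance_end <- as.Date(maintenance_end)
  stopifnot(
    !is.na(study_start_date), !is.na(study_close_date),
    !is.na(maintenance_start), !is.na(maintenance_end),
    study_close_date > study_start_date,
    maintenance_end >= maintenance_start
  )

  # Anchor: the week-start on or before study_start_date under the convention.
  start_dow <- if (week_convention == "sunday_start") 0L else 1L # POSIXlt wday: Sun = 0
  offset <- (as.POSIXlt(study_start_date)$wday - start_dow) %% 7L
  anchor <- study_start_date - offset

  cal <- structure(
    list(
      anchor = anchor,
      study_start_date = study_start_date,
      study_close_date = study_close_date,
      maintenance_start = maintenance_start,
      maintenance_end = maintenance_end,
      week_convention = week_convention,
      study_start_week = 0L
    ),
    class = "study_calendar"
  )
  cal$study_close_week <- week_of(study_close_date, cal)
  cal$maintenance_weeks <- seq.int(
    week_of(maintenance_start, cal),
    week_of(maintenance_end, cal)
  )
  cal$disruption_week <- week_of(maintenance_end, cal) + 1L

  if (min(cal$maintenance_weeks) <= cal$study_start_week ||
    max(cal$maintenance_weeks) >= cal$study_close_week) {
    stop("maintenance window must lie strictly inside the study window", call. = FALSE)
  }
  cal
}

#' Default study calendar
#'
#' Two-year study window (April 2016 through March 2018) with the 10-week
#' maintenance shutdown from 2017-05-07 through 2017-07-15, under
#' Sunday-start surveillance weeks. The maintenance dates are
#' Sunday-to-Saturday aligned, so the shutdown covers exactly 10 whole weeks
#' (weeks 57-66) and the disruption week is 67.
#'
#' @param week_convention Week convention, see [study_calendar()].
#' @return A `study_calendar`.
#' @export
default_calendar <- function(week_convention = "sunday_start") {
  study_calendar(
    study_start_date = "2016-04-03",
    study_close_date = "2018-03-31",
    maintenance_start = "2017-05-07",
    maintenance_end = "2017-07-15",
    week_convention = week_convention
  )
}

#' Map calendar dates to study week indices
#'
#' Deterministic translation-equivariant mapping: all dates inside one
#' surveillance week share an index, and `week_of(d + 7k) == week_of(d) + k`.
#' Week 0 is the week containing the calendar's study start date.
#'
#' @param date `Date` vector (or datetimes / parseable strings).
#' @param calendar A [study_calendar()].
#' @return Integer vector of week indices.
#' @export
week_of <- function(date, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  date <- as.Date(date)
  as.integer(floor(as.numeric(date - calendar$anchor) / 7))
}

#' First calendar date of a study week
#'
#' Inverse of [week_of()] at week granularity: returns the date on which the
#' given week index begins under the calendar's convention.
#'
#' @param week Integer week index vector.
#' @param calendar A [study_calendar()].
#' @return `Date` vector.
#' @export
week_start_date <- function(week, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  calendar$anchor + 7 * as.integer(week)
}

#' All week indices of the study window
#'
#' @param calendar A [study_calendar()].
#' @return Integer vector `study_start_week:study_close_week`.
#' @export
study_weeks <- function(calendar) {
  seq.int(calendar$study_start_week, calendar$study_close_week)
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("<study_calendar>\n")
  cat(
    "  window: ", format(x$study_start_date), " .. ", format(x$study_close_date),
    "  (weeks ", x$study_start_week, "-", x$study_close_week, ")\n",
    sep = ""
  )
  cat(
    "  maintenance: ", format(x$maintenance_start), " .. ", format(x$maintenance_end),
    "  (", length(x$maintenance_weeks), " weeks: ",
    min(x$maintenance_weeks), "-", max(x$maintenance_weeks), ")\n",
    sep = ""
  )
  cat("  disruption week:", x$disruption_week, "\n")
  cat("  week convention:", x$week_convention, "\n")
  invisible(x)
}
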