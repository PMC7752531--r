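#' @importFrom rlang .data
NULL

roster_columns <- function() {
  c(
    "participant_id", "gender", "age_group", "job_category", "ethnicity",
    "children_in_household", "vaccinated_past_year", "allergy", "hospital",
    "enrollment_date", "study_end_date", "registration_complete",
    "background_complete"
  )
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(df)
}

# Coerce a character column to a factor with fixed levels; unknown values
# produce an error naming the offending rows.
parse_level <- function(x, levels, column) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column '%s': unknown level%s %s at row%s %s (allowed: %s)",
        column,
        if (length(bad) > 1) "s" else "",
        paste(unique(x[bad]), collapse = ", "),
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", "),
        paste(levels, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  factor(x, levels = levels)
}

parse_bool <- function(x, column) {
  if (is.logical(x)) {
    return(x)
  }
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x0) & is.na(out))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column '%s': unparseable logical value at row%s %s",
        column, if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out
}

parse_date <- function(x, column) {
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column '%s': unparseable date (expected YYYY-MM-DD) at row%s %s",
        column, if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out
}

#' Read a participant roster
#'
#' Reads `roster.csv` (one row per recruited participant) into a typed
#' tibble, validating categorical levels, logical flags and dates with
#' row-numbered diagnostics, and derives integer enrollment / study-end week
#' indices from the calendar.
#'
#' @param path CSV file with columns `participant_id, gender, age_group,
#'   job_category, ethnicity, children_in_household, vaccinated_past_year,
#'   allergy, hospital, enrollment_date, study_end_date,
#'   registration_complete, background_complete`.
#' @param calendar A [study_calendar()] used to derive week indices.
#' @return Tibble with the typed columns plus `enrollment_week` and
#'   `study_end_week`.
#' @export
load_roster <- function(path, calendar = default_calendar()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, roster_columns(), "roster")
  lv <- participant_levels()
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    gender = parse_level(raw$gender, lv$gender, "gender"),
    age_group = parse_level(raw$age_group, lv$age_group, "age_group"),
    job_category = parse_level(raw$job_category, lv$job_category, "job_category"),
    ethnicity = parse_level(raw$ethnicity, lv$ethnicity, "ethnicity"),
    children_in_household = parse_bool(raw$children_in_household, "children_in_household"),
    vaccinated_past_year = parse_bool(raw$vaccinated_past_year, "vaccinated_past_year"),
    allergy = parse_bool(raw$allergy, "allergy"),
    hospital = parse_level(raw$hospital, lv$hospital, "hospital"),
    enrollment_date = parse_date(raw$enrollment_date, "enrollment_date"),
    study_end_date = parse_date(raw$study_end_date, "study_end_date"),
    registration_complete = parse_bool(raw$registration_complete, "registration_complete"),
    background_complete = parse_bool(raw$background_complete, "background_complete")
  )
  out$enrollment_week <- week_of(out$enrollment_date, calendar)
  out$study_end_week <- week_of(out$study_end_date, calendar)
  bad <- which(out$study_end_week <= out$enrollment_week)
  if (length(bad) > 0) {
    stop(
      sprintf(
        "roster row%s %s: study_end_date not after enrollment_date",
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out
}

#' Write a participant roster
#'
#' Inverse of [load_roster()]; `load_roster(write_roster(x, p), cal)`
#' reproduces `x` exactly.
#'
#' @param roster Roster tibble as produced by [load_roster()] or
#'   [simulate_roster()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  out <- roster[, roster_columns()]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read weekly symptom reports
#'
#' Reads `reports.csv` (one row per submitted weekly survey) into a typed
#' tibble with the 18 canonical symptom indicators, derives the surveillance
#' week of each submission, and flags submissions timestamped inside the
#' maintenance window. Flagged rows are retained on load; downstream
#' analyses decide inclusion.
#'
#' @param path CSV with columns `participant_id, submitted_at` and the 18
#'   symptom columns of [ili_symptoms()].
#' @param calendar A [study_calendar()].
#' @return Tibble with `participant_id`, `submitted_at` (UTC), `week`, the 18
#'   logical symptom columns, and `in_maintenance`.
#' @export
load_reports <- function(path, calendar = default_calendar()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("participant_id", "submitted_at", ili_symptoms()), "reports")
  submitted_at <- as.POSIXct(raw$submitted_at, tz = "UTC")
  bad <- which(!is.na(raw$submitted_at) & is.na(submitted_at))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column 'submitted_at': unparseable date-time at row%s %s",
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    submitted_at = submitted_at
  )
  for (s in ili_symptoms()) {
    out[[s]] <- parse_bool(raw[[s]], s)
  }
  out$week <- week_of(as.Date(out$submitted_at), calendar)
  out$in_maintenance <- out$week %in% calendar$maintenance_weeks
  out
}

#' Write weekly symptom reports
#'
#' @param reports Reports tibble ([load_reports()] / [simulate_reports()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- reports[, c("participant_id", "submitted_at", ili_symptoms())]
  out$submitted_at <- format(out$submitted_at, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a sentinel reference ILI series
#'
#' Reads `reference.csv` (columns `week_start_date, ili_pct`) and aligns each
#' row to the study-week grid. The sentinel provider's week-start convention
#' need not match the configured one: each row is aligned to the study week
#' containing its week-start date.
#'
#' @param path CSV path.
#' @param calendar A [study_calendar()].
#' @return Tibble `week, week_start_date, ili_pct` with strictly increasing
#'   weeks and `ili_pct` in `[0, 100]`.
#' @export
load_reference <- function(path, calendar = default_calendar()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("week_start_date", "ili_pct"), "reference series")
  wsd <- parse_date(raw$week_start_date, "week_start_date")
  ili <- suppressWarnings(as.numeric(raw$ili_pct))
  bad <- which(!is.na(raw$ili_pct) & is.na(ili))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column 'ili_pct': non-numeric value at row%s %s",
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  bad <- which(ili < 0 | ili > 100)
  if (length(bad) > 0) {
    stop(
      sprintf(
        "column 'ili_pct': value outside [0, 100] at row%s %s",
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    week = week_of(wsd, calendar),
    week_start_date = wsd,
    ili_pct = ili
  )
  if (anyDuplicated(out$week) || is.unsorted(out$week, strictly = TRUE)) {
    stop("reference series weeks must be strictly increasing with no duplicates",
      call. = FALSE
    )
  }
  out
}

#' Write a sentinel reference ILI series
#'
#' @param reference Reference tibble ([load_reference()] /
#'   [simulate_reference()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  readr::write_csv(reference[, c("week_start_date", "ili_pct")], path)
  invisible(path)
}
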