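#' ILI case classification
#'
#' A report meets the ILI case definition when it flags fever (self-reported
#' fever at or above 38.0 degrees C) together with cough or sore throat.
#'
#' @param reports Reports tibble (or any data frame with logical `fever`,
#'   `cough`, `sore_throat` columns).
#' @return Logical vector, one element per row.
#' @export
is_ili <- function(reports) {
  reports$fever & (reports$cough | reports$sore_throat)
}

#' Within-week report deduplication
#'
#' Collapses multiple submissions from one participant in one week to a
#' single retained report: the symptomatic one if any (the latest symptomatic
#' when several), otherwise the latest submission. All entries are used,
#' including those after individual study-end dates.
#'
#' @param reports Reports tibble.
#' @param symptom_set Columns counting as "symptomatic" for the retention
#'   rule; defaults to all 18 survey symptoms (the weekly questionnaire is an
#'   acute-respiratory-symptom survey, but it includes gastrointestinal
#'   items; pass a respiratory-only subset to narrow the rule).
#' @return A weekly panel tibble: at most one row per `(participant_id,
#'   week)`, ordered by participant then week, with `any_symptom` and
#'   `is_ili` columns appended. `is_ili` implies `any_symptom`.
#' @export
dedupe_within_week <- function(reports, symptom_set = ili_symptoms()) {
  stopifnot(all(symptom_set %in% names(reports)))
  any_symptom <- rowSums(as.matrix(reports[, symptom_set])) > 0
  # Retention key: lexicographic max of (any_symptom, submitted_at) within
  # each (participant, week) picks the latest symptomatic report if any
  # symptomatic exists, else the latest report.
  o <- order(reports$participant_id, reports$week, any_symptom, reports$submitted_at)
  sorted <- reports[o, , drop = FALSE]
  sorted$any_symptom <- any_symptom[o]
  keep <- !duplicated(sorted[, c("participant_id", "week")], fromLast = TRUE)
  panel <- sorted[keep, , drop = FALSE]
  panel$is_ili <- is_ili(panel)
  tibble::as_tibble(panel)
}

#' Consolidate consecutive ILI weeks into episodes
#'
#' ILI reports in consecutive weeks (week difference exactly 1, each week
#' meeting the case definition) belong to one illness episode; only the first
#' week of each maximal run counts as an onset. A gap week - missing or with
#' a non-ILI report - starts a new episode. Non-onset ILI rows keep their
#' report (they still count in incidence denominators) with `onset = FALSE`.
#' Idempotent, and invariant to the input row order.
#'
#' @param panel Deduplicated weekly panel ([dedupe_within_week()]).
#' @return The panel, ordered by participant then week, with a logical
#'   `onset` column.
#' @export
merge_episodes <- function(panel) {
  if (anyDuplicated(panel[, c("participant_id", "week")]) > 0) {
    stop("panel must be deduplicated (one row per participant-week)", call. = FALSE)
  }
  o <- order(panel$participant_id, panel$week)
  panel <- panel[o, , drop = FALSE]
  same_prev <- c(
    FALSE,
    panel$participant_id[-1] == panel$participant_id[-nrow(panel)] &
      panel$week[-1] == panel$week[-nrow(panel)] + 1L &
      panel$is_ili[-nrow(panel)]
  )
  panel$onset <- panel$is_ili & !same_prev
  tibble::as_tibble(panel)
}

#' Weekly ILI incidence series
#'
#' For each study week: the number of retained reports (denominator), the
#' number of episode onsets (numerator, after [merge_episodes()]), and the
#' incidence `100 * onsets / reports` in percent. Weeks with no reports -
#' including maintenance weeks - carry a flagged missing value, never 0/0.
#'
#' @param panel Weekly panel with an `onset` column.
#' @param calendar A [study_calendar()].
#' @return Incidence tibble `week, n_reports, n_ili_onsets, ili_pct_cohort,
#'   flag` with `flag` in `"ok"`, `"maintenance"`, `"no_reports"`.
#' @export
weekly_incidence <- function(panel, calendar) {
  if (!"onset" %in% names(panel)) {
    stop("panel has no 'onset' column; run merge_episodes() first", call. = FALSE)
  }
  wk <- study_weeks(calendar)
  pos <- match(panel$week, wk)
  in_window <- !is.na(pos)
  n_reports <- tabulate(pos[in_window], nbins = length(wk))
  n_onsets <- tabulate(pos[in_window & panel$onset], nbins = length(wk))
  flag <- rep("ok", length(wk))
  flag[n_reports == 0] <- "no_reports"
  flag[wk %in% calendar$maintenance_weeks & n_reports == 0] <- "maintenance"
  tibble::tibble(
    week = wk,
    n_reports = n_reports,
    n_ili_onsets = n_onsets,
    ili_pct_cohort = ifelse(n_reports > 0, 100 * n_onsets / n_reports, NA_real_),
    flag = flag
  )
}

#' Trailing moving proportion of an incidence series
#'
#' Smooths a weekly incidence series over trailing windows of `width` weeks.
#' The default `"pooled"` method divides summed onsets by summed reports over
#' the window (count-weighted); `"mean"` averages the weekly percentages
#' instead. The first `width - 1` weeks are missing, and any window touching
#' a missing week (e.g., maintenance) propagates missing.
#'
#' @param series [weekly_incidence()] output.
#' @param width Window width in weeks (default 4).
#' @param method `"pooled"` (default) or `"mean"`.
#' @return The series with a `moving_pct` column appended.
#' @export
moving_proportion <- function(series, width = 4, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  n <- nrow(series)
  ok <- series$n_reports > 0
  moving <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < width) next
    win <- (i - width + 1):i
    if (!all(ok[win])) next
    moving[i] <- if (method == "pooled") {
      100 * sum(series$n_ili_onsets[win]) / sum(series$n_reports[win])
    } else {
      mean(series$ili_pct_cohort[win])
    }
  }
  series$moving_pct <- moving
  series
}

#' Trailing moving mean of a reference series
#'
#' The sentinel reference is published as a percentage without counts, so its
#' moving proportion is the trailing mean of the weekly percentages over the
#' same window width used for the cohort series.
#'
#' @param reference Reference tibble ([load_reference()]).
#' @param width Window width in weeks (default 4).
#' @return The reference with a `moving_pct` column appended.
#' @export
reference_moving <- function(reference, width = 4) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  n <- nrow(reference)
  moving <- rep(NA_real_, n)
  contiguous <- c(TRUE, diff(reference$week) == 1L)
  for (i in seq_len(n)) {
    if (i < width) next
    win <- (i - width + 1):i
    if (!all(contiguous[win[-1]])) next
    moving[i] <- mean(reference$ili_pct[win])
  }
  reference$moving_pct <- moving
  reference
}

#' Episode summary statistics of a panel
#'
#' Data-dependent cohort summaries: the number and fraction of participants
#' with at least one ILI episode, and the total episode count.
#'
#' @param panel Weekly panel with `onset` flags.
#' @param cohort Analysis roster (denominator for the participant fraction).
#' @return List: `n_episodes`, `participants_with_episode`,
#'   `pct_participants_with_episode`.
#' @export
episode_summary <- function(panel, cohort) {
  onsets <- panel[panel$onset, , drop = FALSE]
  with_ep <- intersect(unique(onsets$participant_id), cohort$participant_id)
  list(
    n_episodes = nrow(onsets),
    participants_with_episode = length(with_ep),
    pct_participants_with_episode = 100 * length(with_ep) / nrow(cohort)
  )
}
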