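# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (set-membership scans, Sigma formulas,
# explicit window loops) and never reuse package internals.

cal0 <- default_calendar()

# One typed report row; `symptoms` are the column names set to TRUE.
fx_report <- function(pid, submitted_at, symptoms = character(),
                      cal = cal0) {
  r <- tibble::tibble(
    participant_id = pid,
    submitted_at = as.POSIXct(submitted_at, tz = "UTC")
  )
  for (s in ili_symptoms()) r[[s]] <- s %in% symptoms
  r$week <- week_of(as.Date(r$submitted_at), cal)
  r$in_maintenance <- r$week %in% cal$maintenance_weeks
  r
}

# Report placed in a given study week (day 1 of the week, plus `hour`).
fx_report_wk <- function(pid, week, symptoms = character(), hour = 9,
                         cal = cal0) {
  fx_report(pid,
    as.POSIXct(week_start_date(week, cal), tz = "UTC") + 86400 + hour * 3600,
    symptoms, cal
  )
}

fx_reports <- function(...) dplyr::bind_rows(...)

# One typed roster row with overridable covariates; weeks are relative to the
# calendar grid.
fx_participant <- function(pid, enrollment_week = 0L, study_end_week = 78L,
                           gender = "female", age_group = "21-30",
                           job_category = "nursing", ethnicity = "chinese",
                           children_in_household = FALSE,
                           vaccinated_past_year = TRUE, allergy = FALSE,
                           hospital = "TTSH", registration_complete = TRUE,
                           background_complete = TRUE, cal = cal0) {
  lv <- participant_levels()
  tibble::tibble(
    participant_id = pid,
    gender = factor(gender, lv$gender),
    age_group = factor(age_group, lv$age_group),
    job_category = factor(job_category, lv$job_category),
    ethnicity = factor(ethnicity, lv$ethnicity),
    children_in_household = children_in_household,
    vaccinated_past_year = vaccinated_past_year,
    allergy = allergy,
    hospital = factor(hospital, lv$hospital),
    enrollment_date = week_start_date(enrollment_week, cal),
    study_end_date = week_start_date(study_end_week, cal),
    registration_complete = registration_complete,
    background_complete = background_complete,
    enrollment_week = as.integer(enrollment_week),
    study_end_week = as.integer(study_end_week)
  )
}

# ---- independent oracles ---------------------------------------------------

# Episode onsets of one participant by set membership: week w is an onset iff
# w is an ILI week and w-1 is not.
oracle_onset_weeks <- function(ili_weeks) {
  ili_weeks[!(ili_weeks - 1L) %in% ili_weeks]
}

# Pearson r via the textbook Sigma formula, with the t-transform p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# One-sample t on differences via the closed form.
oracle_paired_t <- function(d) {
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(t = t, df = length(d) - 1, p = 2 * stats::pt(-abs(t), length(d) - 1))
}

# Pooled trailing windows by explicit loop.
oracle_pooled_moving <- function(onsets, reports, width) {
  n <- length(onsets)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < width) next
    w <- (i - width + 1):i
    if (any(reports[w] == 0)) next
    out[i] <- 100 * sum(onsets[w]) / sum(reports[w])
  }
  out
}

# Random small deduplicated panel for property tests: n participants, weeks
# 0..(n_weeks-1), each participant-week present with prob p_present and ILI
# with prob p_ili given present.
random_panel <- function(n = 5, n_weeks = 12, p_present = 0.6, p_ili = 0.3) {
  rows <- list()
  for (i in seq_len(n)) {
    wk <- which(stats::runif(n_weeks) < p_present) - 1L
    if (length(wk) == 0) next
    ili <- stats::runif(length(wk)) < p_ili
    r <- tibble::tibble(
      participant_id = sprintf("P%02d", i),
      week = wk,
      submitted_at = as.POSIXct("2016-04-04", tz = "UTC") + wk * 604800,
      fever = ili, cough = ili, sore_throat = FALSE
    )
    for (s in setdiff(ili_symptoms(), c("fever", "cough", "sore_throat"))) {
      r[[s]] <- FALSE
    }
    rows[[length(rows) + 1]] <- r
  }
  df <- dplyr::bind_rows(rows)
  df$any_symptom <- rowSums(as.matrix(df[, ili_symptoms()])) > 0
  df$is_ili <- is_ili(df)
  df
}
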