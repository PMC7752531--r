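#' Surveillance power: correlation against the sentinel series
#'
#' Pearson correlation between the trailing moving proportion of the cohort
#' ILI incidence and that of the sentinel reference series, with a two-sided
#' p-value from the t transform on `n_weeks - 2` degrees of freedom. Weeks
#' with a missing value on either side are dropped pairwise. With the
#' `"before_maintenance"` period, only weeks strictly before the first
#' maintenance week enter the correlation; trailing windows are computed
#' before filtering, so no window pools across the maintenance gap (windows
#' straddling the boundary are excluded on the cohort side by
#' missing-propagation).
#'
#' @param incidence [weekly_incidence()] output (raw weekly series; moving
#'   proportions are computed here).
#' @param reference Reference tibble ([load_reference()] /
#'   [simulate_reference()]).
#' @param calendar A [study_calendar()].
#' @param period `"all"` or `"before_maintenance"`.
#' @param width Moving-window width in weeks (default 4).
#' @param method Cohort moving-proportion method, see [moving_proportion()].
#' @return One-row tibble (class rows of a `SurveillanceResult` table):
#'   `stratum, level, period, r, p_value, n_weeks, degenerate`. Fewer than 3
#'   paired weeks or zero variance on either side yields a flagged degenerate
#'   row with missing `r`.
#' @export
surveillance_correlation <- function(incidence, reference,
                                     calendar = default_calendar(),
                                     period = c("all", "before_maintenance"),
                                     width = 4, method = "pooled") {
  period <- match.arg(period)
  flu <- moving_proportion(incidence, width = width, method = method)
  ref <- reference_moving(reference, width = width)
  df <- dplyr::inner_join(
    flu[, c("week", "moving_pct")],
    ref[, c("week", "moving_pct")],
    by = "week", suffix = c("_cohort", "_ref")
  )
  if (period == "before_maintenance") {
    df <- df[df$week < min(calendar$maintenance_weeks), , drop = FALSE]
  }
  df <- df[!is.na(df$moving_pct_cohort) & !is.na(df$moving_pct_ref), , drop = FALSE]
  result_row("overall", "overall", period, df$moving_pct_cohort, df$moving_pct_ref)
}

result_row <- function(stratum, level, period, x, y) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(
      stratum = stratum, level = level, period = period,
      r = NA_real_, p_value = NA_real_, n_weeks = n, degenerate = TRUE
    ))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    stratum = stratum, level = level, period = period,
    r = unname(ct$estimate), p_value = ct$p.value, n_weeks = n,
    degenerate = FALSE
  )
}

#' Stratified surveillance correlations
#'
#' Re-runs the incidence pipeline (weekly incidence then trailing moving
#' proportion) on the panel restricted to each level of each stratifying
#' covariate, and correlates each stratum series against the same reference,
#' for each requested period. Each participant's reports contribute to
#' exactly one stratum per covariate. Empty strata are flagged and skipped.
#'
#' @param panel Weekly panel with `onset` flags ([merge_episodes()]).
#' @param cohort Analysis roster supplying the stratifying covariates.
#' @param reference Reference tibble.
#' @param calendar A [study_calendar()].
#' @param strata Covariate names (default: the participation covariates).
#' @param periods Periods to evaluate (default both).
#' @param width,method Moving-proportion parameters.
#' @return Tibble with one row per (covariate level, period):
#'   `stratum, level, period, r, p_value, n_weeks, degenerate`.
#' @export
stratified_correlations <- function(panel, cohort, reference,
                                    calendar = default_calendar(),
                                    strata = model_covariates(),
                                    periods = c("all", "before_maintenance"),
                                    width = 4, method = "pooled") {
  rows <- list()
  for (cov in strata) {
    val <- cohort[[cov]]
    lvls <- if (is.factor(val)) levels(val) else sort(unique(val))
    for (lv in lvls) {
      ids <- cohort$participant_id[!is.na(val) & val == lv]
      sub <- panel[panel$participant_id %in% ids, , drop = FALSE]
      if (length(ids) == 0 || nrow(sub) == 0) {
        for (p in periods) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            stratum = cov, level = as.character(lv), period = p,
            r = NA_real_, p_value = NA_real_, n_weeks = 0L, degenerate = TRUE
          )
        }
        next
      }
      inc <- weekly_incidence(sub, calendar)
      for (p in periods) {
        row <- surveillance_correlation(inc, reference, calendar,
          period = p, width = width, method = method
        )
        row$stratum <- cov
        row$level <- as.character(lv)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}
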