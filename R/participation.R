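#' Eligible study weeks of one participant
#'
#' The participation window is half-open: `[enrollment_week,
#' study_end_week)`, minus maintenance weeks. A participant followed for
#' exactly 78 weeks therefore has 78 candidate weeks before maintenance
#' removal.
#'
#' @param participant One roster row.
#' @param calendar A [study_calendar()].
#' @return Integer vector of eligible week indices.
#' @export
eligible_weeks <- function(participant, calendar) {
  if (participant$study_end_week <= participant$enrollment_week) {
    stop("study_end_week must be after enrollment_week", call. = FALSE)
  }
  setdiff(
    seq.int(participant$enrollment_week, participant$study_end_week - 1L),
    calendar$maintenance_weeks
  )
}

#' Individual submission rate of one participant
#'
#' Fraction of eligible weeks (enrollment through study end, maintenance
#' excluded) with at least one submitted survey. Reports after the
#' participant's study-end week are excluded from participation metrics.
#' Pre/post rates split the eligible weeks at the disruption week.
#'
#' @param reports Reports of this participant (rows for other ids are
#'   ignored).
#' @param participant One roster row.
#' @param calendar A [study_calendar()].
#' @return One-row tibble: `participant_id, n_eligible_weeks,
#'   n_submitted_weeks, submission_rate, submission_rate_pre,
#'   submission_rate_post` (pre/post are `NA` when the participant has no
#'   eligible weeks in that period).
#' @export
individual_submission_rate <- function(reports, participant, calendar) {
  elig <- eligible_weeks(participant, calendar)
  rep_weeks <- unique(reports$week[reports$participant_id == participant$participant_id])
  sub <- intersect(rep_weeks, elig)
  pre <- elig[elig < calendar$disruption_week]
  post <- elig[elig >= calendar$disruption_week]
  rate <- function(s, e) if (length(e) == 0) NA_real_ else length(intersect(s, e)) / length(e)
  tibble::tibble(
    participant_id = participant$participant_id,
    n_eligible_weeks = length(elig),
    n_submitted_weeks = length(sub),
    submission_rate = rate(sub, elig),
    submission_rate_pre = rate(sub, pre),
    submission_rate_post = rate(sub, post)
  )
}

#' Classify a committed user
#'
#' A participant is committed when they submitted at least `threshold`
#' reports (not distinct weeks) after the system maintenance, i.e. with week
#' at or after the disruption week and no later than their study-end week.
#'
#' @param reports Reports tibble.
#' @param participant One roster row.
#' @param calendar A [study_calendar()].
#' @param threshold Minimum post-maintenance report count (default 2).
#' @return Logical.
#' @export
classify_committed <- function(reports, participant, calendar, threshold = 2) {
  wk <- reports$week[reports$participant_id == participant$participant_id]
  sum(wk >= calendar$disruption_week & wk <= participant$study_end_week) >= threshold
}

#' Per-participant participation summary for a cohort
#'
#' Vectorized equivalent of applying [individual_submission_rate()] and
#' [classify_committed()] to every cohort member.
#'
#' @param reports Reports tibble.
#' @param cohort Analysis roster ([apply_exclusions()] output).
#' @param calendar A [study_calendar()].
#' @param committed_threshold Passed to the committed-user rule.
#' @return Tibble with one row per cohort participant: the
#'   [individual_submission_rate()] columns plus `n_reports_post` and
#'   `committed`.
#' @export
participation_summary <- function(reports, cohort, calendar,
                                  committed_threshold = 2) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (any(cohort$study_end_week <= cohort$enrollment_week)) {
    stop("study_end_week must be after enrollment_week", call. = FALSE)
  }
  maint <- calendar$maintenance_weeks
  disr <- calendar$disruption_week

  rp <- reports[reports$participant_id %in% cohort$participant_id, c("participant_id", "week")]
  # distinct reported weeks per participant
  dw <- dplyr::distinct(rp, .data$participant_id, .data$week)
  dw <- dplyr::left_join(dw,
    cohort[, c("participant_id", "enrollment_week", "study_end_week")],
    by = "participant_id"
  )
  dw <- dw[dw$week >= dw$enrollment_week & dw$week < dw$study_end_week &
    !(dw$week %in% maint), , drop = FALSE]
  counts <- dplyr::summarise(dplyr::group_by(dw, .data$participant_id),
    n_submitted_weeks = dplyr::n(),
    n_submitted_pre = sum(.data$week < disr),
    n_submitted_post = sum(.data$week >= disr)
  )

  # post-maintenance report counts (all reports, not distinct weeks)
  rp2 <- dplyr::left_join(rp,
    cohort[, c("participant_id", "study_end_week")],
    by = "participant_id"
  )
  rp2 <- rp2[rp2$week >= disr & rp2$week <= rp2$study_end_week, , drop = FALSE]
  post_counts <- dplyr::count(rp2, .data$participant_id, name = "n_reports_post")

  n_in_window <- function(from, to) {
    # count of maintenance weeks inside [from, to)
    vapply(
      seq_along(from),
      function(i) sum(maint >= from[i] & maint < to[i]), integer(1)
    )
  }
  out <- tibble::tibble(
    participant_id = cohort$participant_id,
    n_eligible_weeks = cohort$study_end_week - cohort$enrollment_week -
      n_in_window(cohort$enrollment_week, cohort$study_end_week),
    n_eligible_pre = pmax(pmin(disr, cohort$study_end_week) - cohort$enrollment_week, 0L) -
      n_in_window(cohort$enrollment_week, pmin(disr, cohort$study_end_week)),
    n_eligible_post = pmax(cohort$study_end_week - pmax(disr, cohort$enrollment_week), 0L)
  )
  out <- dplyr::left_join(out, counts, by = "participant_id")
  out <- dplyr::left_join(out, post_counts, by = "participant_id")
  out$n_submitted_weeks[is.na(out$n_submitted_weeks)] <- 0L
  out$n_submitted_pre[is.na(out$n_submitted_pre)] <- 0L
  out$n_submitted_post[is.na(out$n_submitted_post)] <- 0L
  out$n_reports_post[is.na(out$n_reports_post)] <- 0L
  out$submission_rate <- ifelse(out$n_eligible_weeks > 0,
    out$n_submitted_weeks / out$n_eligible_weeks, NA_real_
  )
  out$submission_rate_pre <- ifelse(out$n_eligible_pre > 0,
    out$n_submitted_pre / out$n_eligible_pre, NA_real_
  )
  out$submission_rate_post <- ifelse(out$n_eligible_post > 0,
    out$n_submitted_post / out$n_eligible_post, NA_real_
  )
  out$committed <- out$n_reports_post >= committed_threshold
  out
}

#' Weekly reporting rate series
#'
#' For each study week, the number of distinct reporters that week
#' (`n_survey`) over the cumulative number of participants enrolled to date
#' (`n_cumulative`). Reports after a participant's study-end week are
#' excluded, matching the participation-metric window; maintenance weeks and
#' weeks before anyone enrolled carry a flagged missing rate.
#'
#' @param reports Reports tibble.
#' @param cohort Analysis roster.
#' @param calendar A [study_calendar()].
#' @return Tibble `week, n_cumulative, n_survey, reporting_rate, flag` with
#'   `flag` in `"ok"`, `"maintenance"`, `"no_enrolled"`.
#' @export
weekly_reporting_rate <- function(reports, cohort, calendar) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  wk <- study_weeks(calendar)
  n_cum <- vapply(wk, function(w) sum(cohort$enrollment_week <= w), integer(1))

  rp <- dplyr::distinct(
    reports[reports$participant_id %in% cohort$participant_id, c("participant_id", "week")]
  )
  rp <- dplyr::left_join(rp,
    cohort[, c("participant_id", "enrollment_week", "study_end_week")],
    by = "participant_id"
  )
  rp <- rp[rp$week >= rp$enrollment_week & rp$week < rp$study_end_week, , drop = FALSE]
  n_survey <- vapply(wk, function(w) sum(rp$week == w), integer(1))

  flag <- rep("ok", length(wk))
  flag[wk %in% calendar$maintenance_weeks] <- "maintenance"
  flag[n_cum == 0] <- "no_enrolled"
  rate <- ifelse(flag == "ok", n_survey / n_cum, NA_real_)
  tibble::tibble(
    week = wk, n_cumulative = n_cum, n_survey = n_survey,
    reporting_rate = rate, flag = flag
  )
}

#' Paired pre/post-disruption t test on individual submission rates
#'
#' One-sample t test on the per-participant differences (pre minus post)
#' among participants with both rates defined; two-sided p with `n - 1`
#' degrees of freedom.
#'
#' @param summaries [participation_summary()] output.
#' @return List: `statistic`, `df`, `p_value`, `mean_diff`, `n`,
#'   `degenerate` (`TRUE` when the differences have zero variance, in which
#'   case the test statistics are `NA`).
#' @export
paired_pre_post_test <- function(summaries) {
  d <- summaries$submission_rate_pre - summaries$submission_rate_post
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 participants with both rates defined", call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(
      statistic = NA_real_, df = length(d) - 1L, p_value = NA_real_,
      mean_diff = mean(d), n = length(d), degenerate = TRUE
    ))
  }
  tt <- stats::t.test(d)
  list(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = mean(d), n = length(d),
    degenerate = FALSE
  )
}

participation_formula <- function(outcome) {
  stats::as.formula(paste(
    outcome, "~",
    paste(model_covariates(), collapse = " + ")
  ))
}

model_frame_cohort <- function(summaries, cohort) {
  df <- dplyr::inner_join(summaries, cohort, by = "participant_id")
  keep <- stats::complete.cases(df[, model_covariates()])
  df[keep, , drop = FALSE]
}

#' Multivariable linear model of individual submission rates
#'
#' Fits `submission_rate ~ gender + age_group + job_category + ethnicity +
#' children_in_household + vaccinated_past_year + allergy` (reference levels:
#' female, 21-30, nursing, chinese, no) and computes *adjusted submission
#' rates* per category level by marginal standardization: every cohort member
#' is given that level for the covariate, the fitted model predicts their
#' rate, and the predictions are averaged over the cohort. For a linear model
#' without interactions, the difference between a level's adjusted rate and
#' its reference level's equals the level's coefficient exactly.
#'
#' @param summaries [participation_summary()] output.
#' @param cohort Analysis roster.
#' @return Object of class `submission_model`: list with `fit` (the `lm`),
#'   `coefficients` (tibble `term, estimate, se, p_value`), `adjusted_rates`
#'   (tibble `covariate, level, adjusted_rate, is_reference`), and `n`.
#' @export
fit_submission_model <- function(summaries, cohort) {
  df <- model_frame_cohort(summaries, cohort)
  fit <- stats::lm(participation_formula("submission_rate"), data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop(
      sprintf(
        "design matrix is rank deficient; aliased column(s): %s",
        paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      fit = fit,
      coefficients = tibble::tibble(
        term = rownames(sm), estimate = unname(sm[, 1]), se = unname(sm[, 2]),
        p_value = unname(sm[, 4])
      ),
      adjusted_rates = marginal_standardization(fit, df),
      n = nrow(df)
    ),
    class = "submission_model"
  )
}

#' Adjusted outcome per covariate level by marginal standardization
#'
#' For each level of each model covariate, predicts the outcome for the whole
#' cohort with that covariate set to the level, and averages.
#'
#' @param fit A fitted `lm` or `glm` (predictions on the response scale).
#' @param data The data the model was fit on.
#' @param covariates Covariates to standardize over (default: the model's
#'   participation covariates).
#' @return Tibble `covariate, level, adjusted_rate, is_reference`.
#' @export
marginal_standardization <- function(fit, data, covariates = model_covariates()) {
  rows <- list()
  for (cov in covariates) {
    val <- data[[cov]]
    lvls <- if (is.factor(val)) levels(val) else sort(unique(val))
    for (lv in lvls) {
      nd <- data
      nd[[cov]] <- if (is.factor(val)) {
        factor(rep(lv, nrow(nd)), levels = levels(val))
      } else {
        rep(lv, nrow(nd))
      }
      pred <- stats::predict(fit, newdata = nd, type = "response")
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = cov, level = as.character(lv),
        adjusted_rate = mean(pred),
        is_reference = identical(lv, lvls[1])
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Reporting table of a fitted submission model
#'
#' Joins the adjusted rates with the corresponding coefficients, SEs and
#' p-values, one row per covariate level (reference levels carry the
#' adjusted rate only).
#'
#' @param model A [fit_submission_model()] result.
#' @return Tibble `covariate, level, adjusted_rate, estimate, se, p_value,
#'   is_reference`.
#' @export
submission_model_table <- function(model) {
  tab <- model$adjusted_rates
  j <- match(paste0(tab$covariate, tab$level), model$coefficients$term)
  tab$estimate <- model$coefficients$estimate[j]
  tab$se <- model$coefficients$se[j]
  tab$p_value <- model$coefficients$p_value[j]
  tab
}

#' @export
print.submission_model <- function(x, ...) {
  cat("<submission_model>  n =", x$n, "\n\nAdjusted submission rates:\n")
  print(as.data.frame(x$adjusted_rates), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Committed-user counts and percentages per covariate stratum
#'
#' For each level of each covariate: number committed, stratum size, and the
#' percentage committed within the stratum.
#'
#' @param cohort Analysis roster joined with a logical `committed` column, or
#'   a cohort plus separate `committed` vector.
#' @param committed Logical vector aligned with `cohort` rows (omit when
#'   `cohort` already has a `committed` column).
#' @param covariates Covariates to stratify by.
#' @return Tibble `covariate, level, committed_n, stratum_n, pct`.
#' @export
committed_stratum_table <- function(cohort, committed = cohort$committed,
                                    covariates = model_covariates()) {
  stopifnot(length(committed) == nrow(cohort))
  rows <- list()
  for (cov in covariates) {
    val <- cohort[[cov]]
    lvls <- if (is.factor(val)) levels(val) else sort(unique(val))
    for (lv in lvls) {
      in_stratum <- !is.na(val) & val == lv
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = cov, level = as.character(lv),
        committed_n = sum(committed & in_stratum),
        stratum_n = sum(in_stratum),
        pct = if (sum(in_stratum) > 0) 100 * sum(committed & in_stratum) / sum(in_stratum) else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Multivariable logistic model of committed users
#'
#' Logistic regression of the committed-user flag on the participation
#' covariates; adjusted odds ratios `exp(coefficient)` with Wald 95%
#' confidence intervals, plus per-stratum committed counts and percentages
#' for direct comparison with cohort summary tables. Reference levels carry
#' an OR of exactly 1.
#'
#' @param summaries [participation_summary()] output (needs `committed`).
#' @param cohort Analysis roster.
#' @return Object of class `committed_model`: list with `fit`, `or_table`
#'   (tibble `covariate, level, committed_n, stratum_n, pct, or, ci_low,
#'   ci_high, p_value, is_reference`), `n`, `n_committed`, and `separation`
#'   (`TRUE` when quasi-complete separation was detected; estimates are then
#'   unreliable and flagged, never silently returned).
#' @export
fit_committed_model <- function(summaries, cohort) {
  df <- model_frame_cohort(summaries, cohort)
  if (length(unique(df$committed)) < 2) {
    stop("committed outcome has no variation (all one class); model not identifiable",
      call. = FALSE
    )
  }
  fit <- suppressWarnings(
    stats::glm(participation_formula("committed"),
      data = df,
      family = stats::binomial()
    )
  )
  if (any(is.na(stats::coef(fit)))) {
    stop(
      sprintf(
        "design matrix is rank deficient; aliased column(s): %s",
        paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  sm <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(sm[, 1]) > 10) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)

  strata <- committed_stratum_table(df, df$committed)
  est <- tibble::tibble(
    term = rownames(sm), coef = unname(sm[, 1]), se = unname(sm[, 2]),
    p_value = unname(sm[, 4])
  )
  # map glm terms back to (covariate, level)
  strata$or <- 1
  strata$ci_low <- NA_real_
  strata$ci_high <- NA_real_
  strata$p_value <- NA_real_
  strata$is_reference <- FALSE
  for (i in seq_len(nrow(strata))) {
    term <- paste0(strata$covariate[i], strata$level[i])
    j <- match(term, est$term)
    if (is.na(j)) {
      strata$is_reference[i] <- TRUE
      strata$ci_low[i] <- 1
      strata$ci_high[i] <- 1
    } else {
      strata$or[i] <- exp(est$coef[j])
      strata$ci_low[i] <- exp(est$coef[j] - 1.96 * est$se[j])
      strata$ci_high[i] <- exp(est$coef[j] + 1.96 * est$se[j])
      strata$p_value[i] <- est$p_value[j]
    }
  }
  structure(
    list(
      fit = fit, or_table = strata, n = nrow(df),
      n_committed = sum(df$committed), separation = separation
    ),
    class = "committed_model"
  )
}

#' @export
print.committed_model <- function(x, ...) {
  cat(
    "<committed_model>  n =", x$n, "(", x$n_committed, "committed )",
    if (x$separation) " [flagged: possible separation]" else "", "\n\n"
  )
  tab <- as.data.frame(x$or_table)
  tab$p_value <- format_p(tab$p_value)
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Participant-week logistic adherence model
#'
#' Expands the cohort to one row per eligible participant-week (enrollment
#' through study end, maintenance excluded) with a binary reported/not
#' outcome, and fits a logistic regression on the participation covariates
#' plus a post-disruption indicator. Its coefficients are directly comparable
#' to the generative adherence parameters of the synthetic cohort (see
#' [adherence_true_coefficients()]).
#'
#' @param reports Reports tibble.
#' @param cohort Analysis roster.
#' @param calendar A [study_calendar()].
#' @return Object of class `adherence_model`: list with `fit`,
#'   `coefficients` (tibble `term, estimate, se, ci_low, ci_high, p_value`
#'   with Wald 95% intervals), and `n_obs`.
#' @export
fit_adherence_model <- function(reports, cohort, calendar) {
  maint <- calendar$maintenance_weeks
  n_weeks <- cohort$study_end_week - cohort$enrollment_week
  grid <- tibble::tibble(
    participant_id = rep(cohort$participant_id, n_weeks),
    week = unlist(Map(seq.int, cohort$enrollment_week, cohort$study_end_week - 1L),
      use.names = FALSE
    )
  )
  grid <- grid[!(grid$week %in% maint), , drop = FALSE]
  reported <- dplyr::distinct(reports[, c("participant_id", "week")])
  reported$reported <- TRUE
  grid <- dplyr::left_join(grid, reported, by = c("participant_id", "week"))
  grid$reported <- !is.na(grid$reported)
  grid$post_disruption <- grid$week >= calendar$disruption_week
  grid <- dplyr::left_join(grid, cohort, by = "participant_id")

  fml <- stats::as.formula(paste(
    "reported ~",
    paste(c(model_covariates(), "post_disruption"), collapse = " + ")
  ))
  fit <- stats::glm(fml, data = grid, family = stats::binomial())
  sm <- summary(fit)$coefficients
  structure(
    list(
      fit = fit,
      coefficients = tibble::tibble(
        term = rownames(sm), estimate = unname(sm[, 1]), se = unname(sm[, 2]),
        ci_low = unname(sm[, 1] - 1.96 * sm[, 2]),
        ci_high = unname(sm[, 1] + 1.96 * sm[, 2]),
        p_value = unname(sm[, 4])
      ),
      n_obs = nrow(grid)
    ),
    class = "adherence_model"
  )
}

#' @export
print.adherence_model <- function(x, ...) {
  cat("<adherence_model>  participant-weeks:", x$n_obs, "\n\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Format p-values for reporting
#'
#' Three decimals, floored at `<.001`. Raw values are always kept in CSV
#' output; this formatting is display-only.
#'
#' @param p Numeric vector.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
}
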