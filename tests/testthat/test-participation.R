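cal <- default_calendar()

test_that("individual submission rate counts eligible weeks on a hand-built fixture", {
  # enrolled week 0, study end week 78: 78 candidate weeks, 10 under
  # maintenance, 68 eligible; reports in 34 of them -> rate 0.5
  p <- fx_participant("A", 0, 78)
  elig <- setdiff(0:77, cal$maintenance_weeks)
  chosen <- elig[seq(1, length(elig), by = 2)] # 34 weeks
  expect_length(chosen, 34L)
  reps <- dplyr::bind_rows(lapply(chosen, function(w) fx_report_wk("A", w, "cough")))
  # decoys that must not count: a maintenance-week report and post-study-end ones
  reps <- dplyr::bind_rows(
    reps,
    fx_report_wk("A", cal$maintenance_weeks[1], "fever"),
    fx_report_wk("A", 80, "fever"),
    fx_report_wk("B", 5, "cough")
  )
  row <- individual_submission_rate(reps, p, cal)
  expect_equal(row$n_eligible_weeks, 68L)
  expect_equal(row$n_submitted_weeks, 34L)
  expect_equal(row$submission_rate, 0.5)

  # pre/post split at the disruption week
  pre_elig <- setdiff(0:(cal$disruption_week - 1), cal$maintenance_weeks)
  expect_equal(row$submission_rate_pre, length(intersect(chosen, pre_elig)) / length(pre_elig))
  post_elig <- cal$disruption_week:77
  expect_equal(row$submission_rate_post, length(intersect(chosen, post_elig)) / length(post_elig))

  # boundary cases
  full <- dplyr::bind_rows(lapply(elig, function(w) fx_report_wk("A", w)))
  expect_equal(individual_submission_rate(full, p, cal)$submission_rate, 1)
  none <- individual_submission_rate(fx_report_wk("Z", 3), p, cal)
  expect_equal(none$submission_rate, 0)
  expect_equal(none$submission_rate_pre, 0)
  expect_equal(none$submission_rate_post, 0)

  bad <- fx_participant("C", 10, 10)
  expect_error(individual_submission_rate(reps, bad, cal), "after enrollment")
})

test_that("cohort summary agrees with the per-participant operation", {
  cfg <- sim_config(n_participants = 30, seed = 21)
  sim <- simulate_study(cfg, cal)
  cohort <- apply_exclusions(sim$roster)$cohort
  summ <- participation_summary(sim$reports, cohort, cal)
  for (i in c(1, 7, 18, nrow(cohort))) {
    row <- individual_submission_rate(sim$reports, cohort[i, ], cal)
    j <- match(cohort$participant_id[i], summ$participant_id)
    expect_equal(summ$submission_rate[j], row$submission_rate)
    expect_equal(summ$submission_rate_pre[j], row$submission_rate_pre)
    expect_equal(summ$submission_rate_post[j], row$submission_rate_post)
    expect_equal(
      summ$committed[j],
      classify_committed(sim$reports, cohort[i, ], cal)
    )
  }
  # cohort mean is the mean of individual rates, and rates are proportions
  expect_true(all(dplyr::between(summ$submission_rate, 0, 1)))
  expect_true(all(summ$n_submitted_weeks <= summ$n_eligible_weeks))
})

test_that("weekly reporting rate uses cumulative enrollment denominators", {
  # 10 enroll at week 0, 10 at week 5; only week-0 enrollees report
  early <- dplyr::bind_rows(lapply(1:10, function(i) fx_participant(sprintf("E%02d", i), 0, 78)))
  late <- dplyr::bind_rows(lapply(1:10, function(i) fx_participant(sprintf("L%02d", i), 5, 83)))
  cohort <- dplyr::bind_rows(early, late)
  reps <- dplyr::bind_rows(lapply(0:10, function(w) {
    dplyr::bind_rows(lapply(early$participant_id, function(id) fx_report_wk(id, w)))
  }))
  wr <- weekly_reporting_rate(reps, cohort, cal)
  expect_equal(wr$reporting_rate[wr$week %in% 0:4], rep(1, 5))
  expect_equal(wr$reporting_rate[wr$week %in% 5:10], rep(0.5, 6))
  expect_equal(wr$n_cumulative[wr$week == 4], 10L)
  expect_equal(wr$n_cumulative[wr$week == 5], 20L)
  # maintenance weeks are flagged missing, never a number
  expect_true(all(is.na(wr$reporting_rate[wr$flag == "maintenance"])))
  expect_setequal(wr$week[wr$flag == "maintenance"], cal$maintenance_weeks)
  expect_true(all(wr$reporting_rate <= 1, na.rm = TRUE))

  # a week before anyone enrolled is flagged, not divided by zero
  cohort2 <- dplyr::mutate(cohort, enrollment_week = enrollment_week + 2L)
  wr2 <- weekly_reporting_rate(reps, cohort2, cal)
  expect_equal(wr2$flag[wr2$week %in% 0:1], rep("no_enrolled", 2))
  expect_true(all(is.na(wr2$reporting_rate[wr2$week %in% 0:1])))
})

test_that("committed-user rule counts post-maintenance reports against the threshold", {
  p <- fx_participant("A", 0, 78)
  two_post <- dplyr::bind_rows(
    fx_report_wk("A", cal$disruption_week, "cough"),
    fx_report_wk("A", cal$disruption_week + 2)
  )
  expect_true(classify_committed(two_post, p, cal))
  expect_false(classify_committed(two_post[1, ], p, cal))
  many_pre <- dplyr::bind_rows(lapply(0:49, function(w) fx_report_wk("A", w)))
  expect_false(classify_committed(many_pre, p, cal))

  # monotone in threshold and in report count
  expect_true(classify_committed(two_post, p, cal, threshold = 1))
  expect_false(classify_committed(two_post, p, cal, threshold = 3))
  three_post <- dplyr::bind_rows(two_post, fx_report_wk("A", cal$disruption_week + 4))
  expect_true(classify_committed(three_post, p, cal, threshold = 3))

  # dropping every post-disruption report clears all committed flags and
  # leaves pre-disruption rates untouched
  cfg <- sim_config(n_participants = 25, seed = 31)
  sim <- simulate_study(cfg, cal)
  cohort <- apply_exclusions(sim$roster)$cohort
  s1 <- participation_summary(sim$reports, cohort, cal)
  pre_only <- sim$reports[sim$reports$week < cal$disruption_week, ]
  s2 <- participation_summary(pre_only, cohort, cal)
  expect_false(any(s2$committed))
  expect_equal(s2$submission_rate_pre, s1$submission_rate_pre)
})

test_that("paired pre/post t test matches the closed form", {
  mk <- function(pre, post) {
    tibble::tibble(submission_rate_pre = pre, submission_rate_post = post)
  }
  res <- paired_pre_post_test(mk(c(0.4, 0.5, 0.6), c(0.3, 0.3, 0.3)))
  oracle <- oracle_paired_t(c(0.1, 0.2, 0.3))
  expect_equal(res$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)

  # zero-variance differences are flagged degenerate, not divided through
  res0 <- paired_pre_post_test(mk(c(0.5, 0.6, 0.7), c(0.4, 0.5, 0.6)))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$statistic))
  expect_equal(res0$mean_diff, 0.1)

  # identical pre and post -> t exactly 0
  resz <- paired_pre_post_test(mk(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9) - c(0.1, 0, -0.1)))
  expect_equal(resz$statistic, 0, tolerance = 1e-12)

  expect_error(paired_pre_post_test(mk(0.5, 0.4)), "at least 2")
})
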