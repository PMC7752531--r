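cal <- default_calendar()

test_that("within-week retention keeps the symptomatic, else latest, report", {
  # symptomatic first, clean later -> symptomatic retained
  two <- dplyr::bind_rows(
    fx_report_wk("A", 10, "cough", hour = 9),
    fx_report_wk("A", 10, character(), hour = 15)
  )
  panel <- dedupe_within_week(two)
  expect_equal(nrow(panel), 1L)
  expect_true(panel$cough)

  # two clean -> the later one
  clean <- dplyr::bind_rows(
    fx_report_wk("A", 10, character(), hour = 9),
    fx_report_wk("A", 10, character(), hour = 15)
  )
  panel <- dedupe_within_week(clean)
  expect_equal(format(panel$submitted_at, "%H"), "15")

  # several symptomatic -> the latest symptomatic
  three <- dplyr::bind_rows(
    fx_report_wk("A", 10, "fever", hour = 8),
    fx_report_wk("A", 10, "sneezing", hour = 12),
    fx_report_wk("A", 10, character(), hour = 20)
  )
  panel <- dedupe_within_week(three)
  expect_true(panel$sneezing)
  expect_false(panel$fever)

  # a single report is returned unchanged
  one <- fx_report_wk("A", 3, "headache")
  expect_equal(dedupe_within_week(one)$headache, TRUE)

  # panel invariants: one row per participant-week; ILI implies symptomatic
  cfg <- sim_config(n_participants = 60, p_multi = 0.3, seed = 14)
  sim <- simulate_study(cfg)
  panel <- dedupe_within_week(sim$reports)
  expect_equal(anyDuplicated(panel[, c("participant_id", "week")]), 0L)
  expect_true(all(panel$any_symptom[panel$is_ili]))
})

test_that("the retention rule honors a narrowed symptom subset", {
  # nausea-only report counts as symptomatic under the full 18-symptom rule,
  # but not under a respiratory-only subset
  two <- dplyr::bind_rows(
    fx_report_wk("A", 10, "nausea", hour = 9),
    fx_report_wk("A", 10, character(), hour = 15)
  )
  expect_true(dedupe_within_week(two)$nausea)
  resp <- c("fever", "cough", "sore_throat", "runny_or_blocked_nose")
  expect_false(dedupe_within_week(two, symptom_set = resp)$nausea)
})

test_that("ILI classification is fever plus cough or sore throat", {
  expect_true(is_ili(fx_report_wk("A", 1, c("fever", "cough"))))
  expect_true(is_ili(fx_report_wk("A", 1, c("fever", "sore_throat"))))
  expect_false(is_ili(fx_report_wk("A", 1, "fever")))
  expect_false(is_ili(fx_report_wk("A", 1, c("cough", "sore_throat"))))
  expect_false(is_ili(fx_report_wk("A", 1, character())))
})

test_that("consecutive ILI weeks collapse to one onset at the run start", {
  mk_panel <- function(spec) {
    # spec: named list participant -> list(ili = weeks, clean = weeks)
    rows <- lapply(names(spec), function(id) {
      dplyr::bind_rows(
        lapply(spec[[id]]$ili, function(w) fx_report_wk(id, w, c("fever", "cough"))),
        lapply(spec[[id]]$clean, function(w) fx_report_wk(id, w, character()))
      )
    })
    merge_episodes(dedupe_within_week(dplyr::bind_rows(rows)))
  }
  p <- mk_panel(list(A = list(ili = c(10, 11, 12))))
  expect_equal(p$week[p$onset], 10)

  p <- mk_panel(list(A = list(ili = c(10, 12))))
  expect_equal(p$week[p$onset], c(10, 12))

  p <- mk_panel(list(A = list(ili = c(10, 11, 13, 14))))
  expect_equal(p$week[p$onset], c(10, 13))

  # a non-ILI report between two ILI weeks still breaks the episode
  p <- mk_panel(list(A = list(ili = c(10, 12), clean = 11)))
  expect_equal(p$week[p$onset], c(10, 12))

  # runs never cross participants
  p <- mk_panel(list(A = list(ili = 10), B = list(ili = 11)))
  expect_equal(sum(p$onset), 2L)

  expect_error(merge_episodes(dplyr::bind_rows(
    fx_report_wk("A", 5, "fever"), fx_report_wk("A", 5, "cough")
  ) |> dplyr::mutate(is_ili = TRUE)), "deduplicated")
})

test_that("episode merging matches a set-membership oracle on random panels", {
  set.seed(77)
  for (trial in 1:300) {
    panel <- random_panel(
      n = sample(2:6, 1), n_weeks = sample(6:15, 1),
      p_present = stats::runif(1, 0.3, 0.9), p_ili = stats::runif(1, 0.1, 0.6)
    )
    if (nrow(panel) == 0) next
    merged <- merge_episodes(panel)
    for (id in unique(panel$participant_id)) {
      got <- sort(merged$week[merged$onset & merged$participant_id == id])
      want <- sort(oracle_onset_weeks(panel$week[panel$is_ili & panel$participant_id == id]))
      expect_equal(got, want)
    }
    # idempotence and order invariance
    expect_equal(merge_episodes(merged)$onset, merged$onset)
    shuffled <- panel[sample(nrow(panel)), ]
    expect_equal(merge_episodes(shuffled), merged)
  }
})

test_that("weekly incidence divides onsets by retained reports, never 0/0", {
  # 200 reports in one week, 2 of them ILI onsets -> 1.0%
  wk <- 20L
  reps <- dplyr::bind_rows(lapply(1:200, function(i) {
    fx_report_wk(sprintf("P%03d", i), wk, if (i <= 2) c("fever", "cough") else character())
  }))
  inc <- weekly_incidence(merge_episodes(dedupe_within_week(reps)), cal)
  expect_equal(inc$ili_pct_cohort[inc$week == wk], 1.0)
  expect_equal(inc$n_reports[inc$week == wk], 200L)

  # a continuing ILI week keeps its report in the denominator at 0 onsets
  reps2 <- dplyr::bind_rows(
    lapply(1:99, function(i) fx_report_wk(sprintf("Q%03d", i), 21L, character())),
    fx_report_wk("P001", 21L, c("fever", "cough")) # continues week-20 episode
  )
  inc2 <- weekly_incidence(merge_episodes(dedupe_within_week(dplyr::bind_rows(reps, reps2))), cal)
  expect_equal(inc2$n_reports[inc2$week == 21], 100L)
  expect_equal(inc2$n_ili_onsets[inc2$week == 21], 0L)
  expect_equal(inc2$ili_pct_cohort[inc2$week == 21], 0)

  # report-free weeks (maintenance among them) are flagged missing
  expect_true(all(is.na(inc$ili_pct_cohort[inc$n_reports == 0])))
  expect_equal(
    inc$flag[inc$week %in% cal$maintenance_weeks],
    rep("maintenance", 10)
  )
  expect_error(weekly_incidence(dedupe_within_week(reps), cal), "onset")
})

test_that("merged incidence never exceeds unmerged incidence", {
  set.seed(55)
  for (trial in 1:20) {
    panel <- merge_episodes(random_panel(n = 8, n_weeks = 20, p_ili = 0.4))
    merged <- weekly_incidence(panel, cal)
    unmerged <- panel
    unmerged$onset <- unmerged$is_ili
    raw <- weekly_incidence(unmerged, cal)
    both <- !is.na(merged$ili_pct_cohort) & !is.na(raw$ili_pct_cohort)
    expect_true(all(merged$ili_pct_cohort[both] <= raw$ili_pct_cohort[both]))
    # total onsets = number of distinct episodes
    n_episodes <- sum(vapply(
      split(panel$week[panel$is_ili], panel$participant_id[panel$is_ili]),
      function(w) length(oracle_onset_weeks(w)), integer(1)
    ))
    expect_equal(sum(merged$n_ili_onsets), n_episodes)
  }
})

test_that("trailing moving proportions pool windows as hand computation", {
  mk_series <- function(onsets, reports, start = 0L) {
    tibble::tibble(
      week = start + seq_along(onsets) - 1L,
      n_reports = reports, n_ili_onsets = onsets,
      ili_pct_cohort = ifelse(reports > 0, 100 * onsets / reports, NA_real_),
      flag = ifelse(reports > 0, "ok", "no_reports")
    )
  }
  s <- mk_series(c(0L, 1L, 1L, 2L), rep(100L, 4))
  m <- moving_proportion(s, width = 4)
  expect_equal(m$moving_pct, c(NA, NA, NA, 1.0))

  # equal-denominator constant series stays constant
  s2 <- mk_series(rep(1L, 8), rep(100L, 8))
  expect_equal(moving_proportion(s2, 4)$moving_pct[4:8], rep(1, 5))

  # width 1 is the identity on the raw series
  s3 <- mk_series(c(2L, 0L, 5L, 1L), c(50L, 40L, 100L, 25L))
  expect_equal(moving_proportion(s3, 1)$moving_pct, s3$ili_pct_cohort)

  # pooled vs mean differ under unequal denominators; oracle checks pooled
  s4 <- mk_series(c(1L, 1L, 1L, 18L), c(10L, 10L, 10L, 90L))
  m4 <- moving_proportion(s4, 4)
  expect_equal(m4$moving_pct[4], oracle_pooled_moving(s4$n_ili_onsets, s4$n_reports, 4)[4])
  expect_equal(m4$moving_pct[4], 100 * 21 / 120)
  expect_equal(moving_proportion(s4, 4, method = "mean")$moving_pct[4], mean(c(10, 10, 10, 20)))

  # windows touching a missing week propagate missing
  s5 <- mk_series(c(1L, 1L, 0L, 1L, 1L, 1L, 1L), c(50L, 50L, 0L, 50L, 50L, 50L, 50L))
  m5 <- moving_proportion(s5, 2)
  expect_true(is.na(m5$moving_pct[3]))
  expect_true(is.na(m5$moving_pct[4]))
  expect_false(is.na(m5$moving_pct[6]))

  expect_error(moving_proportion(s5, 0), "width")
})
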