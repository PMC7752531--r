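#' Simulation configuration for the synthetic cohort
#'
#' Defines the generative model of the synthetic surveillance study. The
#' defaults emulate the structure of a two-hospital health-care-worker
#' cohort: 690 analysis participants (plus 8 registration-incomplete and 2
#' background-incomplete recruits removed by [apply_exclusions()]), covariate
#' marginals matching the cohort's demographic table, 18 months (78 weeks) of
#' individual follow-up inside a 2-year study window, covariate-dependent
#' weekly reporting adherence with a discrete log-odds drop from the
#' disruption week onward, rare second submissions within a reporting week,
#' a sinusoidal sentinel reference curve, and ILI onset hazard coupled to
#' that curve on the log-odds scale.
#'
#' @param n_participants Analysis cohort size.
#' @param n_incomplete_registration,n_incomplete_background Extra recruits
#'   excluded at the registration / background-survey stage.
#' @param marginals Named list of category probabilities for `gender`,
#'   `age_group`, `job_category`, `ethnicity`, `hospital` (named vectors
#'   summing to 1) and scalar probabilities `children_in_household`,
#'   `vaccinated_past_year`, `allergy`.
#' @param enrollment_spread_weeks Enrollment week drawn uniformly from
#'   `0:(enrollment_spread_weeks - 1)`.
#' @param followup_weeks Individual follow-up length; study end week is
#'   enrollment week plus this.
#' @param p_report Baseline weekly reporting probability for a
#'   reference-level participant before the disruption.
#' @param adherence_effects Named list (by covariate) of named log-odds
#'   effects per non-reference level on weekly reporting.
#' @param post_disruption_logodds Additive log-odds effect on reporting for
#'   weeks at or after the disruption week.
#' @param p_multi Probability that a reporting participant-week carries a
#'   second submission.
#' @param p_multi_duplicate Probability that a second submission duplicates
#'   the first submission's symptoms; otherwise it is asymptomatic.
#' @param ref_baseline,ref_amplitude,ref_period,ref_noise_sd Sentinel
#'   reference curve: `baseline + amplitude * sin(2 * pi * week / period)`
#'   plus Gaussian noise, truncated to `[0, 100]` (percent units).
#' @param baseline_ili_logodds Intercept of the weekly ILI onset hazard on
#'   the log-odds scale.
#' @param ili_link_slope Log-odds of ILI onset per unit of reference ILI%.
#'   With slope 0, onsets are independent of the reference series.
#' @param ili_link_stratum `NULL`, or `list(covariate =, level =)`: restrict
#'   the reference coupling to participants in that stratum (others get slope
#'   0), for stratum-confined-signal experiments.
#' @param p_sore_throat_ili Probability an ILI week reports sore throat in
#'   addition to fever + cough.
#' @param episode_continuation Probability an active ILI episode persists
#'   into the next week.
#' @param background_symptom_probs Named per-symptom background probabilities
#'   applied to every report independently of ILI status (fever defaults to
#'   0 so that simulated ILI weeks coincide with episode weeks).
#' @param seed Integer seed; fixed seed reproduces bit-identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 690,
                       n_incomplete_registration = 8,
                       n_incomplete_background = 2,
                       marginals = default_marginals(),
                       enrollment_spread_weeks = 4,
                       followup_weeks = 78,
                       p_report = 0.5,
                       adherence_effects = default_adherence_effects(),
                       post_disruption_logodds = -1.4,
                       p_multi = 0.01,
                       p_multi_duplicate = 0.5,
                       ref_baseline = 3,
                       ref_amplitude = 1,
                       ref_period = 26,
                       ref_noise_sd = 0.3,
                       baseline_ili_logodds = -5.6,
                       ili_link_slope = 0.3,
                       ili_link_stratum = NULL,
                       p_sore_throat_ili = 0.5,
                       episode_continuation = 0.4,
                       background_symptom_probs = default_background_symptoms(),
                       seed = 1L) {
  cfg <- structure(
    list(
      n_participants = as.integer(n_participants),
      n_incomplete_registration = as.integer(n_incomplete_registration),
      n_incomplete_background = as.integer(n_incomplete_background),
      marginals = marginals,
      enrollment_spread_weeks = as.integer(enrollment_spread_weeks),
      followup_weeks = as.integer(followup_weeks),
      p_report = p_report,
      adherence_effects = adherence_effects,
      post_disruption_logodds = post_disruption_logodds,
      p_multi = p_multi,
      p_multi_duplicate = p_multi_duplicate,
      ref_baseline = ref_baseline,
      ref_amplitude = ref_amplitude,
      ref_period = ref_period,
      ref_noise_sd = ref_noise_sd,
      baseline_ili_logodds = baseline_ili_logodds,
      ili_link_slope = ili_link_slope,
      ili_link_stratum = ili_link_stratum,
      p_sore_throat_ili = p_sore_throat_ili,
      episode_continuation = episode_continuation,
      background_symptom_probs = background_symptom_probs,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_marginals <- function() {
  list(
    gender = c(female = 0.841, male = 0.159),
    age_group = c("21-30" = 0.374, "31-40" = 0.396, "41-50" = 0.133, ">50" = 0.097),
    job_category = c(
      nursing = 0.413, administration_other = 0.081, ancillary = 0.152,
      allied_health = 0.270, medical = 0.084
    ),
    ethnicity = c(chinese = 0.564, other = 0.436),
    hospital = c(TTSH = 5 / 7, KKH = 2 / 7),
    children_in_household = 0.184,
    vaccinated_past_year = 0.817,
    allergy = 0.258
  )
}

#' @rdname sim_config
#' @export
default_adherence_effects <- function() {
  list(
    gender = c(male = 0),
    age_group = c("31-40" = 0.35, "41-50" = 0.60, ">50" = 0.35),
    job_category = c(
      administration_other = 0, ancillary = 0, allied_health = 0, medical = 0
    ),
    ethnicity = c(other = -0.40),
    children_in_household = c("TRUE" = 0),
    vaccinated_past_year = c("TRUE" = 0.45),
    allergy = c("TRUE" = 0)
  )
}

#' @rdname sim_config
#' @export
default_background_symptoms <- function() {
  c(
    fever = 0, chills = 0.01, runny_or_blocked_nose = 0.08, sneezing = 0.08,
    cough = 0.06, sore_throat = 0.05, shortness_of_breath = 0.005,
    muscle_or_joint_pain = 0.02, headache = 0.05, malaise = 0.02,
    loss_of_appetite = 0.01, colored_phlegm = 0.02,
    watery_bloodshot_eyes = 0.01, nausea = 0.01, vomiting = 0.005,
    diarrhea = 0.01, stomach_ache = 0.01, chest_pain = 0.005
  )
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$p_report, cfg$p_multi, cfg$p_multi_duplicate, cfg$p_sore_throat_ili,
    cfg$episode_continuation, cfg$marginals$children_in_household,
    cfg$marginals$vaccinated_past_year, cfg$marginals$allergy,
    cfg$background_symptom_probs
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("gender", "age_group", "job_category", "ethnicity", "hospital")) {
    m <- cfg$marginals[[f]]
    if (is.null(m) || abs(sum(m) - 1) > 1e-6) {
      stop(sprintf("marginal probabilities for '%s' must sum to 1", f), call. = FALSE)
    }
    if (!all(names(m) %in% participant_levels()[[f]])) {
      stop(sprintf("unknown level name in marginals for '%s'", f), call. = FALSE)
    }
  }
  miss <- setdiff(ili_symptoms(), names(cfg$background_symptom_probs))
  if (length(miss) > 0) {
    stop(
      sprintf(
        "background_symptom_probs missing: %s",
        paste(miss, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  if (!is.null(cfg$ili_link_stratum)) {
    stopifnot(all(c("covariate", "level") %in% names(cfg$ili_link_stratum)))
  }
  if (cfg$n_participants < 1 || cfg$followup_weeks < 1) {
    stop("n_participants and followup_weeks must be positive", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(
    "  cohort:", x$n_participants, "analysis +",
    x$n_incomplete_registration + x$n_incomplete_background, "excluded recruits\n"
  )
  cat("  follow-up:", x$followup_weeks, "weeks; baseline p_report:", x$p_report, "\n")
  cat(
    "  ILI: baseline log-odds", x$baseline_ili_logodds,
    "| link slope", x$ili_link_slope,
    "| continuation", x$episode_continuation, "\n"
  )
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

draw_level <- function(n, probs, levels) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs), levels = levels)
}

#' Simulate a participant roster
#'
#' Draws `n_participants + n_incomplete_registration +
#' n_incomplete_background` recruits with independent covariates at the
#' configured marginals. Registration- and background-incomplete recruits are
#' interleaved at random positions so that [apply_exclusions()] has realistic
#' work to do.
#'
#' @param config A [sim_config()].
#' @param calendar A [study_calendar()].
#' @param seed Seed; defaults to `config$seed`. Pass `NULL` to draw from the
#'   current RNG state.
#' @return Roster tibble in the same typed layout as [load_roster()].
#' @export
simulate_roster <- function(config, calendar = default_calendar(),
                            seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  lv <- participant_levels()
  m <- config$marginals
  n <- config$n_participants + config$n_incomplete_registration +
    config$n_incomplete_background

  roster <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    gender = draw_level(n, m$gender, lv$gender),
    age_group = draw_level(n, m$age_group, lv$age_group),
    job_category = draw_level(n, m$job_category, lv$job_category),
    ethnicity = draw_level(n, m$ethnicity, lv$ethnicity),
    children_in_household = stats::runif(n) < m$children_in_household,
    vaccinated_past_year = stats::runif(n) < m$vaccinated_past_year,
    allergy = stats::runif(n) < m$allergy,
    hospital = draw_level(n, m$hospital, lv$hospital)
  )
  enrollment_week <- sample(seq_len(config$enrollment_spread_weeks) - 1L, n,
    replace = TRUE
  )
  roster$enrollment_date <- week_start_date(enrollment_week, calendar)
  roster$study_end_date <- week_start_date(
    enrollment_week + config$followup_weeks, calendar
  )
  roster$registration_complete <- TRUE
  roster$background_complete <- TRUE
  excl <- sample(n, config$n_incomplete_registration + config$n_incomplete_background)
  if (config$n_incomplete_registration > 0) {
    roster$registration_complete[excl[seq_len(config$n_incomplete_registration)]] <- FALSE
  }
  if (config$n_incomplete_background > 0) {
    roster$background_complete[excl[config$n_incomplete_registration +
      seq_len(config$n_incomplete_background)]] <- FALSE
  }
  roster$enrollment_week <- enrollment_week
  roster$study_end_week <- enrollment_week + config$followup_weeks
  roster
}

#' Simulate a sentinel reference ILI series
#'
#' One value per study week: `baseline + amplitude * sin(2 * pi * week /
#' period)` plus Gaussian noise, truncated to `[0, 100]`.
#'
#' @inheritParams simulate_roster
#' @return Reference tibble (`week, week_start_date, ili_pct`) covering every
#'   study week.
#' @export
simulate_reference <- function(config, calendar = default_calendar(),
                               seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  wk <- study_weeks(calendar)
  curve <- config$ref_baseline +
    config$ref_amplitude * sin(2 * pi * wk / config$ref_period) +
    stats::rnorm(length(wk), 0, config$ref_noise_sd)
  tibble::tibble(
    week = wk,
    week_start_date = week_start_date(wk, calendar),
    ili_pct = pmin(pmax(curve, 0), 100)
  )
}

# Per-participant adherence log-odds (before the post-disruption shift):
# logit(p_report) plus the configured covariate effects.
adherence_logodds <- function(roster, config) {
  lo <- rep(stats::qlogis(config$p_report), nrow(roster))
  for (cov in names(config$adherence_effects)) {
    eff <- config$adherence_effects[[cov]]
    val <- as.character(roster[[cov]])
    hit <- match(val, names(eff))
    lo <- lo + ifelse(is.na(hit), 0, eff[hit])
  }
  lo
}

#' True adherence model coefficients implied by a configuration
#'
#' Returns the generative log-odds coefficients of weekly reporting in the
#' parameterization used by [fit_adherence_model()], for parameter-recovery
#' checks: intercept `qlogis(p_report)`, one term per non-reference covariate
#' level, and `post_disruptionTRUE`.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector keyed by `glm` coefficient names.
#' @export
adherence_true_coefficients <- function(config) {
  out <- c("(Intercept)" = stats::qlogis(config$p_report))
  for (cov in names(config$adherence_effects)) {
    eff <- config$adherence_effects[[cov]]
    names(eff) <- paste0(cov, names(eff))
    out <- c(out, eff)
  }
  c(out, post_disruptionTRUE = config$post_disruption_logodds)
}

#' Simulate weekly symptom reports
#'
#' For every registered participant and every week from their enrollment week
#' through the study close week, excluding maintenance weeks, a report is
#' submitted with probability `logistic(logit(p_report) + covariate effects +
#' post_disruption_logodds * [week >= disruption week])`; a reporting
#' participant-week carries a second submission with probability `p_multi`.
#' Participants keep reporting past their individual study-end week (the app
#' stays open until study close); participation analyses apply their own
#' window.
#'
#' The underlying illness process runs over all weeks (including maintenance,
#' when it is simply unobserved): a participant without an active ILI episode
#' starts one with hazard `logistic(baseline_ili_logodds + ili_link_slope *
#' reference ILI%)`, and an active episode persists into the next week with
#' probability `episode_continuation`. An ILI week reports fever + cough (and
#' sore throat with probability `p_sore_throat_ili`); all 18 symptoms are
#' additionally drawn at their background rates.
#'
#' @param roster Roster tibble; only rows with `registration_complete` emit
#'   reports.
#' @param reference Reference series covering every study week.
#' @param calendar A [study_calendar()].
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`, `NULL` uses current RNG state.
#' @return Reports tibble in the layout of [load_reports()].
#' @export
simulate_reports <- function(roster, reference, calendar = default_calendar(),
                             config = sim_config(), seed = config$seed) {
  stopifnot(nrow(roster) > 0)
  if (!is.null(seed)) set.seed(seed)
  reg <- roster[roster$registration_complete, , drop = FALSE]
  n <- nrow(reg)
  wk <- study_weeks(calendar)
  n_w <- length(wk)
  ref <- reference$ili_pct[match(wk, reference$week)]
  if (anyNA(ref)) {
    stop("reference series must cover every study week", call. = FALSE)
  }

  slope <- rep(config$ili_link_slope, n)
  if (!is.null(config$ili_link_stratum)) {
    st <- config$ili_link_stratum
    slope <- slope * as.numeric(as.character(reg[[st$covariate]]) == as.character(st$level))
  }

  # Illness process: one uniform per participant-week decides both
  # continuation (if active) and onset (if not).
  active <- matrix(FALSE, n, n_w)
  prev <- rep(FALSE, n)
  enroll <- reg$enrollment_week
  for (j in seq_len(n_w)) {
    w <- wk[j]
    hazard <- stats::plogis(config$baseline_ili_logodds + slope * ref[j])
    hazard[w < enroll] <- 0
    u <- stats::runif(n)
    now <- ifelse(prev, u < config$episode_continuation, u < hazard)
    now <- now & (w >= enroll)
    active[, j] <- now
    prev <- now
  }

  # Reporting process.
  lo <- adherence_logodds(reg, config)
  post <- as.numeric(wk >= calendar$disruption_week)
  p_rep <- stats::plogis(outer(lo, post * config$post_disruption_logodds, "+"))
  eligible <- outer(enroll, wk, "<=") & !matrix(wk %in% calendar$maintenance_weeks,
    n, n_w,
    byrow = TRUE
  )
  reports <- eligible & (matrix(stats::runif(n * n_w), n, n_w) < p_rep)

  idx <- which(reports, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- nrow(idx)
  if (m == 0) {
    out <- empty_reports()
    return(out)
  }
  p_i <- idx[, 1]
  w_j <- idx[, 2]
  week_vec <- wk[w_j]
  ili <- active[cbind(p_i, w_j)]

  # Symptoms: background draws for all 18, then the ILI pattern on top.
  sy <- ili_symptoms()
  bg <- matrix(
    stats::runif(m * 18) < rep(config$background_symptom_probs[sy], each = m),
    m, 18,
    dimnames = list(NULL, sy)
  )
  bg[, "fever"] <- bg[, "fever"] | ili
  bg[, "cough"] <- bg[, "cough"] | ili
  bg[, "sore_throat"] <- bg[, "sore_throat"] |
    (ili & stats::runif(m) < config$p_sore_throat_ili)

  day1 <- stats::runif(m, 0, 5)
  t1 <- as.POSIXct(week_start_date(week_vec, calendar), tz = "UTC") +
    floor(day1 * 86400) # whole seconds so CSV round-trips are exact

  first <- tibble::as_tibble(bg)
  first <- tibble::add_column(first,
    participant_id = reg$participant_id[p_i],
    submitted_at = t1,
    week = week_vec,
    .before = 1
  )

  # Second submissions: duplicate the first report's symptoms with
  # probability p_multi_duplicate, otherwise asymptomatic.
  dup <- stats::runif(m) < config$p_multi
  if (any(dup)) {
    k <- which(dup)
    second <- first[k, , drop = FALSE]
    keep_sym <- stats::runif(length(k)) < config$p_multi_duplicate
    second[!keep_sym, sy] <- FALSE
    second$submitted_at <- second$submitted_at +
      pmax(1, floor((6.9 - day1[k]) * stats::runif(length(k)) * 86400))
    first <- rbind(first, second)
  }

  out <- first[order(first$participant_id, first$week, first$submitted_at), ]
  out <- out[, c("participant_id", "submitted_at", "week", sy)]
  out$in_maintenance <- out$week %in% calendar$maintenance_weeks
  tibble::as_tibble(out)
}

empty_reports <- function() {
  out <- tibble::tibble(
    participant_id = character(),
    submitted_at = as.POSIXct(character(), tz = "UTC"),
    week = integer()
  )
  for (s in ili_symptoms()) out[[s]] <- logical()
  out$in_maintenance <- logical()
  out
}

#' Simulate a complete study
#'
#' Runs [simulate_roster()], [simulate_reference()] and [simulate_reports()]
#' under one seed and optionally writes `roster.csv`, `reports.csv` and
#' `reference.csv`.
#'
#' @param config A [sim_config()].
#' @param calendar A [study_calendar()].
#' @param out_dir Optional output directory for the three CSVs.
#' @return List with `roster`, `reports`, `reference` (and `paths` if
#'   written).
#' @export
simulate_study <- function(config = sim_config(), calendar = default_calendar(),
                           out_dir = NULL) {
  set.seed(config$seed)
  roster <- simulate_roster(config, calendar, seed = NULL)
  reference <- simulate_reference(config, calendar, seed = NULL)
  reports <- simulate_reports(roster, reference, calendar, config, seed = NULL)
  out <- list(roster = roster, reports = reports, reference = reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(
      roster = write_roster(roster, file.path(out_dir, "roster.csv")),
      reports = write_reports(reports, file.path(out_dir, "reports.csv")),
      reference = write_reference(reference, file.path(out_dir, "reference.csv"))
    )
  }
  out
}
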