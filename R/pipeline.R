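#' Default pipeline configuration
#'
#' A single configuration list governs every pipeline stage: the study
#' calendar, the committed-user threshold, the moving-window width and
#' method, and either input CSV paths or a simulation request. It can be
#' written to / read from YAML ([read_config()]).
#'
#' @param simulate Generate inputs with the synthetic-cohort module instead
#'   of reading CSVs.
#' @param simulation Named list of [sim_config()] overrides.
#' @param inputs Named list of paths (`roster`, `reports`, `reference`) used
#'   when `simulate` is `FALSE`.
#' @return Configuration list.
#' @export
default_config <- function(simulate = TRUE, simulation = list(), inputs = list()) {
  list(
    calendar = list(
      study_start_date = "2016-04-03",
      study_close_date = "2018-03-31",
      maintenance_start = "2017-05-07",
      maintenance_end = "2017-07-15",
      week_convention = "sunday_start"
    ),
    committed_threshold = 2,
    moving_width = 4,
    moving_method = "pooled",
    simulate = simulate,
    simulation = simulation,
    inputs = inputs
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (k == "calendar" && is.list(user$calendar)) {
      for (kk in names(user$calendar)) cfg$calendar[[kk]] <- user$calendar[[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Build the study calendar described by a pipeline configuration
#'
#' @param config Configuration list ([default_config()] / [read_config()]).
#' @return A [study_calendar()].
#' @export
config_calendar <- function(config) {
  cl <- config$calendar
  study_calendar(
    cl$study_start_date, cl$study_close_date,
    cl$maintenance_start, cl$maintenance_end,
    week_convention = cl$week_convention
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full surveillance analysis pipeline
#'
#' Orchestrates `simulate -> participation -> incidence -> surveillance`,
#' writing every stage's output tables (and figures) under `out_dir` plus a
#' `manifest.json` recording the configuration hash, seed, input/output
#' checksums and per-stage row counts. With a fixed configuration and seed,
#' the output tables are byte-identical across runs.
#'
#' @param config Configuration list ([default_config()]) or path to a YAML
#'   file ([read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the simulation seed.
#' @param stages Character subset of
#'   `c("simulate", "participation", "incidence", "surveillance")`. Stages
#'   not requested are skipped; later stages load their inputs from
#'   `config$inputs` or from files produced earlier in the same run.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         seed = NULL,
                         stages = c("simulate", "participation", "incidence", "surveillance")) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calendar <- pipeline_stage("config", config_calendar(config))
  started <- Sys.time()

  manifest <- list(
    package_version = as.character(utils::packageVersion("ilisurv")),
    config_hash = config_hash(config[setdiff(names(config), "inputs")]),
    seed = seed,
    stages = stages,
    maintenance_week_count = length(calendar$maintenance_weeks),
    counts = list(),
    inputs = list(),
    outputs = list(),
    complete = FALSE
  )
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    outputs[[name]] <<- path
    outputs <<- outputs
    path
  }

  # --- inputs: simulate or load -------------------------------------------
  roster <- reports <- reference <- NULL
  if ("simulate" %in% stages && isTRUE(config$simulate)) {
    sim <- pipeline_stage("simulate", {
      sim_args <- config$simulation
      if (!is.null(seed)) sim_args$seed <- seed
      scfg <- do.call(sim_config, sim_args)
      simulate_study(scfg, calendar, out_dir = out_dir)
    })
    roster <- sim$roster
    reports <- sim$reports
    reference <- sim$reference
    manifest$inputs <- as.list(tools::md5sum(unname(sim$paths)))
    message(sprintf(
      "[simulate] roster: %d recruits; reports: %d; reference: %d weeks",
      nrow(roster), nrow(reports), nrow(reference)
    ))
  }
  need_input <- function(what) {
    path <- config$inputs[[what]]
    if (is.null(path) || !file.exists(path %||% "")) {
      stop(sprintf(
        "required input '%s' not found%s",
        what, if (is.null(path)) " (no path configured)" else sprintf(" at '%s'", path)
      ), call. = FALSE)
    }
    manifest$inputs[[path]] <<- unname(tools::md5sum(path))
    path
  }
  load_inputs <- function(need_reference = FALSE, need_roster = TRUE) {
    if (need_roster && is.null(roster)) {
      roster <<- pipeline_stage("load", load_roster(need_input("roster"), calendar))
    }
    if (is.null(reports)) {
      reports <<- pipeline_stage("load", load_reports(need_input("reports"), calendar))
    }
    if (need_reference && is.null(reference)) {
      reference <<- pipeline_stage("load", load_reference(need_input("reference"), calendar))
    }
  }

  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) {
      ex <- apply_exclusions(roster)
      cohort <<- ex$cohort
      manifest$counts$exclusions <<- as.list(stats::setNames(ex$exclusion_log$n, ex$exclusion_log$reason))
      manifest$counts$cohort <<- nrow(cohort)
      message(sprintf(
        "[exclusions] %d recruited; %d registration-incomplete, %d background-incomplete removed; cohort %d",
        nrow(roster), ex$exclusion_log$n[1], ex$exclusion_log$n[2], nrow(cohort)
      ))
    }
    cohort
  }

  # --- participation -------------------------------------------------------
  if ("participation" %in% stages) {
    pipeline_stage("participation", {
      load_inputs()
      co <- get_cohort()
      summ <- participation_summary(reports, co, calendar,
        committed_threshold = config$committed_threshold
      )
      weekly <- weekly_reporting_rate(reports, co, calendar)
      emit(summ, "participation_summary.csv")
      emit(weekly, "weekly_rates.csv")
      sub_m <- fit_submission_model(summ, co)
      com_m <- fit_committed_model(summ, co)
      emit(submission_model_table(sub_m), "model_submission.csv")
      emit(com_m$or_table, "model_committed.csv")
      if (com_m$separation) {
        message("[participation] committed model flagged: possible separation")
      }
      manifest$counts$participants_summarized <- nrow(summ)
      manifest$counts$committed <- sum(summ$committed)
      message(sprintf(
        "[participation] mean submission rate %.3f; %d committed users",
        mean(summ$submission_rate, na.rm = TRUE), sum(summ$committed)
      ))
      plot_weekly_rate(weekly, file.path(out_dir, "fig_weekly_rate.png"))
      manifest
    })
  }

  # --- incidence -----------------------------------------------------------
  panel <- incidence <- NULL
  if ("incidence" %in% stages || "surveillance" %in% stages) {
    pipeline_stage("incidence", {
      load_inputs(need_roster = "surveillance" %in% stages)
      panel <- merge_episodes(dedupe_within_week(reports))
      incidence <- moving_proportion(weekly_incidence(panel, calendar),
        width = config$moving_width, method = config$moving_method
      )
      manifest$counts$panel_rows <- nrow(panel)
      manifest$counts$episodes <- sum(panel$onset)
      message(sprintf(
        "[incidence] %d retained participant-weeks; %d episodes; mean weekly ILI %.2f%%",
        nrow(panel), sum(panel$onset), mean(incidence$ili_pct_cohort, na.rm = TRUE)
      ))
      if ("incidence" %in% stages) {
        emit(panel[, c("participant_id", "week", "any_symptom", "is_ili", "onset")], "panel.csv")
        emit(incidence, "incidence.csv")
      }
    })
  }

  # --- surveillance --------------------------------------------------------
  if ("surveillance" %in% stages) {
    pipeline_stage("surveillance", {
      load_inputs(need_reference = TRUE)
      co <- get_cohort()
      overall <- dplyr::bind_rows(
        surveillance_correlation(incidence, reference, calendar,
          period = "all",
          width = config$moving_width, method = config$moving_method
        ),
        surveillance_correlation(incidence, reference, calendar,
          period = "before_maintenance",
          width = config$moving_width, method = config$moving_method
        )
      )
      strat <- stratified_correlations(panel, co, reference, calendar,
        width = config$moving_width, method = config$moving_method
      )
      table4 <- dplyr::bind_rows(overall, strat)
      emit(table4, "table4.csv")
      manifest$counts$surveillance_rows <- nrow(table4)
      r_all <- overall$r[overall$period == "all"]
      r_pre <- overall$r[overall$period == "before_maintenance"]
      message(sprintf(
        "[surveillance] overall r = %.3f (all data), %.3f (before maintenance)",
        r_all, r_pre
      ))
      plot_incidence_vs_reference(
        incidence, reference_moving(reference, config$moving_width),
        file.path(out_dir, "fig_incidence_vs_reference.png")
      )
    })
  }

  manifest$outputs <- as.list(tools::md5sum(unname(unlist(outputs))))
  manifest$complete <- TRUE
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), started, units = "secs"))
  manifest$timestamp <- format(started, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plot_weekly_rate <- function(weekly, path) {
  p <- ggplot2::ggplot(weekly[weekly$flag == "ok", ], ggplot2::aes(x = .data$week)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_survey / max(.data$n_cumulative)),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reporting_rate), color = "steelblue") +
    ggplot2::labs(
      x = "study week", y = "weekly reporting rate",
      title = "Weekly reporting rate (line) and submitted surveys (bars)"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 120)
  invisible(path)
}

plot_incidence_vs_reference <- function(incidence, reference, path) {
  df <- dplyr::bind_rows(
    tibble::tibble(
      week = incidence$week, moving_pct = incidence$moving_pct,
      series = "cohort ILI%"
    ),
    tibble::tibble(
      week = reference$week, moving_pct = reference$moving_pct,
      series = "reference ILI%"
    )
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$week, .data$moving_pct, color = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "study week", y = "4-week moving proportion (%)",
      title = "Cohort vs reference ILI moving proportions", color = NULL
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 120)
  invisible(path)
}
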