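# ilisurv

Analysis toolkit for **participatory influenza-like-illness (ILI)
surveillance** cohorts — studies in which volunteers (here, hospital health
care workers) answer a short weekly symptom survey on their phones, and the
resulting self-reported series is compared against an official sentinel
series to ask whether crowdsourced reporting can track the epidemic signal.

The package takes raw study artifacts — a participant roster, weekly symptom
reports with 18 binary indicators, and a reference sentinel series — and
produces:

* **Participation metrics.** Per-participant *individual submission rate*
  (fraction of eligible study weeks with ≥1 survey, maintenance weeks
  excluded), week-level *reporting rate* `N_survey(t) / N_cumulative(t)`, a
  paired *t* test of the pre- vs post-disruption rates, *committed-user*
  classification (≥2 reports after the system-maintenance disruption), and
  two multivariable models: a linear model of submission rates with
  **marginally standardized adjusted rates** per covariate level, and a
  logistic model of committed users with adjusted odds ratios and Wald 95%
  CIs.
* **Weekly ILI incidence.** Within-week deduplication (keep the symptomatic
  report, else the latest), the syndromic case definition
  `ILI = fever ∧ (cough ∨ sore throat)`, consolidation of consecutive ILI
  weeks into single episodes (one onset per episode), weekly incidence
  `ILI%(t) = 100 · onsets(t) / reports(t)`, and trailing 4-week moving
  proportions (pooled or mean-of-weeks).
* **Surveillance power.** Pearson correlation *r* between the cohort's and
  the sentinel's 4-week moving proportions — overall, restricted to the
  pre-disruption period, and stratified by participant characteristics, with
  two-sided p-values from the *t* transform on `n_weeks − 2` df.
* **A synthetic cohort generator** reproducing the statistical structure of
  such a study (covariate-dependent weekly adherence on the log-odds scale,
  a discrete post-disruption participation drop, occasional within-week
  duplicate submissions, and ILI onset hazard coupled to the reference
  curve), so the entire pipeline is testable without any external data.

## Worked example

```r
library(ilisurv)

cal <- default_calendar()                 # Apr 2016 – Mar 2018, Sunday weeks,
                                          # 10 maintenance weeks (57–66)
sim <- simulate_study(sim_config(seed = 1), cal)
cohort <- apply_exclusions(sim$roster)$cohort   # 700 recruits -> 690 analyzed

summ <- participation_summary(sim$reports, cohort, cal)
round(100 * c(overall = mean(summ$submission_rate),
              pre  = mean(summ$submission_rate_pre,  na.rm = TRUE),
              post = mean(summ$submission_rate_post, na.rm = TRUE)), 1)
#> overall     pre    post
#>    55.3    61.2    28.8

tt <- paired_pre_post_test(summ)
sprintf("t(%d) = %.1f, p %s", tt$df, tt$statistic, format_p(tt$p_value))
#> "t(689) = 62.7, p <.001"

panel <- merge_episodes(dedupe_within_week(sim$reports))
inc   <- weekly_incidence(panel, cal)
round(mean(inc$ili_pct_cohort, na.rm = TRUE), 2)   # mean weekly ILI incidence
#> 1.11

surveillance_correlation(inc, sim$reference, cal, period = "before_maintenance")
#>   stratum   level             period        r      p_value n_weeks degenerate
#> 1 overall overall before_maintenance 0.872755 8.010161e-18      54      FALSE
```

The participation drop after week 67 (the disruption week) is the simulated
system shutdown plus incentive end; the pre-period correlation of 0.87
reflects the configured coupling (`ili_link_slope = 0.3`) between onset
hazard and the sentinel curve. Fitting the participant-week adherence model
recovers the generative log-odds effects — e.g. with `sim_config(seed = 1)`
the fitted age 41–50 effect is 0.62 (truth 0.60) and the post-disruption
shift −1.39 (truth −1.4):

```r
fit_adherence_model(sim$reports, cohort, cal)
```

The whole pipeline, driven by one YAML configuration, writes every table,
figure and a reproducibility manifest in one call (or via
`inst/cli/ilisurv.R` from a shell):

```r
run_pipeline(default_config(simulation = list(seed = 1)), out_dir = "out")
```

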