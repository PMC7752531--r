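---
title: "Methods: participatory ILI surveillance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: participatory ILI surveillance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilisurv)
```

# The study design being analyzed

The package analyzes a *targeted participatory surveillance* design: a fixed
cohort of hospital staff is prompted weekly to tick which of 18 acute
respiratory and gastrointestinal symptoms they experienced, over an
individual follow-up of 18 months inside a 2-year study window. Midway
through, the reporting system goes down for 10 weeks and the participation
incentive ends; both events are deliberately treated as a single *study
disruption* splitting the series into a pre and post period, because their
effects are not separable in this design. The scientific question is twofold:
who keeps reporting (participation engagement and its covariates), and how
well the self-reported ILI series tracks an official sentinel series
(*surveillance power*, operationalized as a Pearson correlation of smoothed
weekly series).

# Calendar conventions

All analyses run on an integer week grid. Week 0 is the surveillance week
containing the study start date; `week_of()` is translation-equivariant
(`week_of(d + 7k) = week_of(d) + k`). The default convention is
`sunday_start` because the maintenance window in the default calendar
(2017-05-07 through 2017-07-15) is Sunday-to-Saturday aligned, giving a
maintenance set of exactly 10 whole weeks (57–66) and a *disruption week* of
67. `monday_start` and `iso` (ISO-8601, also Monday-based) are available for
sentinel providers using other conventions; the reference loader aligns each
sentinel row to the study week containing its published week-start date, so
a provider's convention need not match the cohort's.

Two windows deliberately differ:

* **Participation metrics** use the half-open individual window
  `[enrollment_week, study_end_week)` minus maintenance weeks, so an
  18-month participant has exactly 78 candidate weeks before maintenance
  removal. Reports submitted after a participant's study end are excluded
  here.
* **Incidence** uses *all* retained reports, including post-study-end ones:
  a symptom report is epidemiologically informative regardless of the
  participant's administrative status. This distinction is why reports
  timestamped inside or after unusual windows are flagged on load rather
  than dropped — each module applies its own inclusion rule.

# Incidence estimation

**Within-week retention.** When a participant submits several surveys in
one week, the retained one is the *latest symptomatic* report if any report
is symptomatic, otherwise the *latest* report — implemented as the
lexicographic maximum of `(any_symptom, submitted_at)`, which makes the
tie-break explicit and order-independent. "Symptomatic" defaults to any of
the 18 indicators; the weekly questionnaire covers acute respiratory
illness but includes gastrointestinal items under the same heading, so the
symptom set is a parameter (`symptom_set`) for users who prefer a
respiratory-only rule.

**Case definition.** `ILI = fever ∧ (cough ∨ sore_throat)`; the fever flag
encodes self-reported fever ≥ 38.0 °C.

**Episode consolidation.** ILI reports in consecutive weeks (difference
exactly 1, each meeting the case definition) are one illness episode; only
the first week of each maximal run is an onset. A missing week *or* a
non-ILI report between two ILI weeks starts a new episode — the literal
reading of "consecutive". Non-onset ILI weeks keep their report in the
denominators. The operation is idempotent and invariant to row order, and
the tests verify it against an independent set-membership oracle
(`w` is an onset iff `w` is an ILI week and `w − 1` is not) on 1,000 random
panels.

**Weekly incidence and smoothing.** `ILI%(t) = 100 · onsets(t) /
reports(t)`; report-free weeks (maintenance included) are flagged missing,
never computed as 0/0. The 4-week *moving proportion* is a trailing window;
the default pools counts (`100 · Σ onsets / Σ reports`) because a
"proportion over a window" naturally pools numerators and denominators, but
a mean-of-weekly-percentages variant is exposed (`method = "mean"`) since
either reading of a published "4-week moving proportion" is defensible.
Windows touching a missing week propagate missingness, and the first
`width − 1` weeks are missing. After deduplication the denominator equals
the number of distinct reporting participants, so "reports" vs
"participants" in the denominator is moot by construction.

# Participation models

The linear model of individual submission rates and the logistic model of
committed users share one covariate set (gender, age group, job category,
ethnicity, children in household, past-year vaccination, allergy) with
reference levels female / 21–30 / nursing / Chinese / no. Three choices are
worth making explicit:

* **Adjusted submission rates** are computed by *marginal standardization*:
  predict for every cohort member with the covariate forced to a level,
  then average. For a linear model without interactions this makes
  `adjusted(level) − adjusted(reference)` equal the level's coefficient
  *exactly* — an algebraic identity the tests assert to 1e-10 — which is the
  natural way to present absolute rates alongside coefficients.
* **Odds-ratio intervals are Wald** (symmetric on the log scale), matching
  the conventional presentation of adjusted ORs; quasi-complete separation
  is detected (non-convergence, |coef| > 10, or fitted probabilities at the
  boundary) and flagged rather than silently returned.
* **The committed-user rule** counts *reports* (not distinct weeks) with
  week ≥ disruption week and ≤ the participant's study-end week, threshold 2
  by default. The model output also carries per-stratum committed counts and
  percentages so the tabulated stratum summaries can be reproduced directly.

A participant-week **adherence model** (`fit_adherence_model()`) expands the
cohort to one row per eligible week with a reported/not outcome and fits a
logistic regression on the covariates plus a post-disruption indicator.
This is the estimator whose coefficients are directly comparable to the
synthetic generator's parameters, and it is the vehicle for the
parameter-recovery checks below. The weekly reporting-rate series uses
cumulative enrollment as its denominator (never decremented after
enrollment closes) — attrition is invisible in this design because no exit
events are observed, only non-reporting.

# Surveillance power

`surveillance_correlation()` computes Pearson *r* between the cohort and
sentinel moving proportions on paired non-missing weeks, with the two-sided
p-value from `t = r·sqrt((n−2)/(1−r²))`. The `before_maintenance` period
keeps weeks strictly before the first maintenance week *after* smoothing,
so no window pools across the gap; post-gap windows on the cohort side are
missing anyway until `width` clean weeks accumulate. Fewer than 3 pairs or
zero variance on either side yields a flagged degenerate row, never a
number. The sentinel series is published as a percentage without counts, so
its moving proportion is the trailing mean of its weekly values over the
same width.

Stratified correlations rerun the *whole* incidence pipeline on the panel
restricted to each covariate level — strata partition participants, so
stratum numerators and denominators sum to the overall series week by week
(a conservation property the tests check).

**A caveat the tests make explicit:** the nominal t null for the p-value
assumes independent week pairs. Trailing windows of width 4 serially
correlate consecutive values of *both* series, so under a true null the
smoothed correlation is overdispersed relative to that t distribution
(empirically, null SD ≈ 0.20 vs ≈ 0.11 nominal at ~88 pairs) and its
p-values are anti-conservative. The test suite therefore checks p-value
uniformity under the null on the *unsmoothed* (width-1) correlation, where
the assumption holds, and checks only the centering of the smoothed
correlation at 0. Smoothed p-values should be read as descriptive, which is
also why raw p-values are kept in CSV output while display formatting
floors at "<.001".

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes, with
these defaults:

| Parameter | Default | Rationale |
|---|---|---|
| cohort | 690 analysis + 8 + 2 excluded recruits | recruitment arithmetic of the emulated study |
| covariate marginals | 84.1% female, 37.4/39.6/13.3/9.7% ages, 56.4% Chinese, 81.7% vaccinated, 25.8% allergy, 18.4% children | the cohort's demographic table (job categories renormalized to sum to the cohort) |
| follow-up | 78 weeks, enrollment spread over weeks 0–3 | 18-month participation with a short recruitment ramp |
| `p_report` | 0.5 | pre-disruption weekly reporting stabilizes near 50% |
| adherence effects (log-odds) | age 31–40 +0.35, 41–50 +0.60, >50 +0.35; non-Chinese −0.40; vaccinated +0.45; others 0 | signs and relative sizes of the participation-model findings being emulated |
| `post_disruption_logodds` | −1.4 | logit(0.5) → logit(≈0.2), the observed pre→post drop in weekly reporting |
| `p_multi` | 0.01 | "<1% of occasions" with duplicate submissions |
| reference curve | 3% + 1%·sin(2πt/26) + N(0, 0.3²), truncated to [0, 100] | a tropical sentinel series: moderate level, biannual seasonality, no sharp peaks |
| `baseline_ili_logodds` | −5.6, with `ili_link_slope` 0.3 | mean weekly ILI incidence near 1% at the reference level of the curve |
| `episode_continuation` | 0.4 | episodes lasting ~1.7 weeks on average |

Adherence, onset and continuation are independent Bernoulli processes given
covariates. The illness process runs through maintenance weeks (illness
does not pause when the app is down; it is simply unobserved), participants
keep reporting past their individual study end until study close (the app
accepts submissions), and second submissions duplicate the first's symptoms
with probability 0.5, else are asymptomatic — exercising both branches of
the retention rule. A stratum-confined coupling (`ili_link_stratum`)
restricts the reference link to one covariate level for
signal-localization experiments. The incentive end is *not* modeled
separately: no threshold-seeking behavior is generated, and the incentive's
termination is folded into the single post-disruption multiplier, because
the two events are confounded in the emulated design anyway.

What the generator deliberately does **not** emulate — and hence what
passing tests do not establish about real data: participant-level adherence
heterogeneity beyond covariates (real cohorts show far more overdispersion
in individual rates, so simulated committed-user fractions are higher than
real ones), autocorrelated reporting habits, care-seeking or
symptom-reporting biases, transmission dynamics or contact structure, and
reporting-propensity correlated with illness. The simulator validates the
*pipeline*, not any epidemiological claim.

# Verification strategy and problem sizes

The test suite pairs every nontrivial operation with an independent oracle:
episode merging against the set-membership scan (1,000 random panels),
Pearson r and the paired t against closed-form Σ formulas, moving windows
against explicit loops, and marginal standardization against the
coefficient identity. Stochastic behavior is checked at the study's own
scale — 690 participants over 78-week follow-up — with 20 replicates for
adherence parameter recovery and 200 seeds for the null-coupling check;
coverage indicators are pooled over effects × replicates before
thresholding at 90%, because thresholding a 95%-probability event per
effect on 20 draws would reject correctly calibrated estimators far too
often. Strong-coupling scenarios (`ili_link_slope = 1`, reference noise SD
0.05, baseline log-odds −6) are chosen so the systematic seasonal swing in
weekly onset counts dominates binomial noise by an order of magnitude.
Determinism is verified byte-for-byte on the full pipeline's CSV outputs
under a fixed seed.

# Known limitations

* Pre/post comparisons inherit the design's confounding: system downtime
  and incentive end are one "disruption".
* The adherence model assumes independent participant-weeks; with real
  (overdispersed, autocorrelated) reporting, its SEs would be too small.
  A mixed-effects extension is out of scope here.
* Smoothed-series correlation p-values are anti-conservative (see above).
* Rows with missing covariates are dropped from the models, mirroring the
  design's exclusion of incomplete background surveys; no imputation is
  attempted.
* The `before_maintenance` stratified correlations can rest on few pairs in
  small strata; degenerate flags, not numbers, are returned below 3 pairs.
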