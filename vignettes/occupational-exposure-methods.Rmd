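---
title: "Methods: survey-based occupational exposure scoring and case–control risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-based occupational exposure scoring and case-control risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occupex)
```

## The problem

Retrospective case–control studies of diseases with suspected
environmental etiology — ALS is the motivating example — often collect
two complementary views of a participant's working life: a detailed
exposure questionnaire repeated for up to four jobs (most recent, the one
before it, and the two longest held), and a free-text occupational
history that can be coded to the Standard Occupational Classification
(SOC). Neither view suffices alone. Job codes miss the within-occupation
variability of real exposures (some managers weld; most do not), while
self-reported exposures need the occupational context to be interpreted.
`occupex` implements both arms and their joint analysis as one tested
pipeline.

## Exposure scoring model

The scoring schema is a tree: nine **exposure types**, each composed of
one or more **factors** (source- or activity-specific components), each
factor quantified by survey **items** with a response→contribution map
into [0, 1]. For one job:

* factor score: sum of item contributions divided by the maximum
  attainable sum, so every factor spans [0, 1] exactly;
* type score: weighted mean of the non-missing factor scores,
  `Σ w_f s_f / Σ w_f`, with weights expressing the assessed contribution
  of each factor to the overall exposure.

Missingness is handled asymmetrically by design: an item skipped while
other items of the factor were answered contributes 0 (a respondent who
answered the block but left one line blank almost surely had nothing to
report), while a factor — and a type — is *missing* only when every one
of its items is unanswered. This reproduces the differing per-type Ns
seen in real survey data without imputing exposures.

Participant-level summaries over the eligible jobs:

* **ever** score: the maximum job score — whether the participant was
  ever exposed on any job. A mean-over-jobs alternative sits behind
  `ever_method = "mean"`.
* **duration-adjusted** score: the duration-weighted mean
  `Σ s_j d_j / Σ d_j`. We divide by total years rather than using a raw
  score×years product: the weighted mean preserves the [0, 1] scale that
  published score tables report (a product would exceed 1), keeps the
  score interpretable as an intensity, and still credits long-held
  exposed jobs.

Job durations are `end_year − start_year` at year resolution (surveys
collect years), floored at 0.5 for same-year jobs so they do not silently
vanish from duration-weighted quantities.

**Eligibility.** Cases contribute jobs beginning strictly before or in
the year of symptom onset; a job beginning *after* onset is excluded, as
are all jobs of cases lacking an onset year. Controls are filtered
against their consent year. Filtering is total and idempotent, and the
exclusion log plus the retained jobs always account for every input job.

The shipped schema (`default_schema()`) is deliberately labelled
illustrative: it carries the full nine-type structure — including the
two-factor, 18-item particulate-matter block and per-item metal
subcomponent tags (lead, mercury, cadmium, arsenic, iron, welding,
other) — with equal weights. Real deployments load their own
expert-weighted schema from YAML (`read_schema()`); the weights are
configuration, not code.

## Covariates

All adjusted models use age quartiles (three indicators), sex
(reference female) and military service (reference neither). Quartile
boundaries are empirical quartiles of the **combined** case+control
sample with half-open bins `[q0,q1) [q1,q2) [q2,q3) [q3,q4]`; a value
exactly on an interior boundary goes to the upper bin. Missing military
service is single-imputed with the mode, which matches how sparse
(~1%) categorical missingness is handled in this literature.

## Association models

* **Permutation tests**: two-sided on the difference in group means,
  with the add-one convention `p = (1 + #{|T_b| ≥ |T_obs|}) / (B + 1)`
  and B = 10,000 by default. The add-one form never reports p = 0 and is
  exact under the permutation null.
* **Logistic models**: maximum likelihood, Wald 95% intervals and
  p-values. Exposure scores enter standardized (combined-sample mean/SD,
  denominator n−1), so ORs are per SD; job-years predictors are divided
  by 5 so ORs read per 5 additional years worked. Participants missing
  the modelled score are dropped from that model, never imputed. GLM
  convergence is tightened (epsilon 1e-12) so small-sample ORs agree
  with closed-form cross-product ratios to ~1e-8. Fits showing
  separation (diverging coefficients or standard errors) abort with the
  offending term named.
* **Adaptive elastic net / adaptive lasso**: a two-stage scheme for
  selection among correlated predictors. Stage 1 is a ridge logistic fit
  (stable under correlation, unlike MLE weights); stage 2 penalizes each
  exposure by `|β_ridge|^(−γ)` with γ = 1, mixing α = 0.5 for the
  exposure-score model and α = 1 (pure lasso) for the SOC job-years
  model. Adjustment covariates always carry penalty factor 0. λ is
  chosen by seeded 10-fold cross-validated deviance at its minimum.
  Adaptive weights are capped at 1e6 so a ridge coefficient of exactly
  zero stays finite. These hyperparameters are package defaults — the
  estimators are standard but their tuning constants are rarely
  published, so we state ours explicitly.
* **Enrichment test**: one-sample z-test of a group's case proportion
  against the cohort case fraction, normal approximation *without*
  continuity correction: `z = (p̂ − p0)/√(p0(1−p0)/n)`, two-sided. On the
  published worked examples the uncorrected variant reproduces the
  printed p-values for the production and management rows (0.016, 0.002);
  the healthcare-practitioners row computes to ≈0.004 where 0.006 was
  printed (the corrected variant matches there but breaks the others).
  We document the discrepancy and report the uncorrected value.
* **BH correction**: `stats::p.adjust(method = "BH")` applied across the
  family of per-SOC models (mirroring published per-SOC tables);
  exposure-score models are reported unadjusted. Note that BH adjustment
  is *not* idempotent as a map on p-vectors — re-adjusting adjusted
  values inflates them — so the tests verify the step-up definition
  against a brute-force threshold scan instead.
* **Sparse groups**: single-group logistic models require at least five
  participants with any years in the group (`min_n`); sparser groups
  produce degenerate fits and are excluded from the BH family and the
  lasso design.

## Job-years and time windows

Job-years accumulate per participant within each 2-digit SOC major
group. Windowed variants intersect each job's span `[start, start+d)`
with three windows counted back from the reference year r (onset for
cases, consent for controls): within 10 years, 10–20 years, and more
than 20 years before. The most recent window is implemented as
`[r−10, ∞)`: the rare years worked at or after the reference year are
credited to the most recent window, which keeps the invariant that the
three windows sum exactly to the unsplit total.

## SOC triage

Automated coders are merged keeping coder A's top-ranked candidate (with
its fit score) and coder B's single code; agreement defaults to the full
6-digit code (2-digit available by configuration). The review-priority
cascade scores each job 0–3: 0 (indeterminate) when title plus
description fall below a minimum-information token threshold or the
title is on the insufficient-title list ("CEO", "owner", …) with no
description; otherwise a base priority from an exposure-potential lookup
on the major group (office/professional 1, service/field 2,
trades/production/military 3), lowered to 1 when the coders agree with
fit ≥ 0.8, then +1 (capped at 3) when the description contains an
exposure-context keyword — a secretary "in a military facility" rises
from 1 to 2. Manual review flags cover priority ≥ 2 jobs with coder
disagreement or fit < 0.3, and all indeterminate jobs. The lookup
tables and keyword lists are editable configuration: expert judgment
cannot be fully codified, only approximated and audited — which is what
the seeded `audit_sample()` supports, reporting the exact
misclassification fraction alongside the rounded percentage.

## Joint profiles

Mean exposure profiles per aggregated SOC group are clustered with
Euclidean distance. Linkage is complete by default (configurable to
average/single): the linkage behind published occupational dendrograms
is typically unstated, and complete linkage is the common default in the
apparent tooling and produces compact, interpretable clusters. The
plain variant averages job-level scores over a group's jobs; the
duration-adjusted variant averages participant-level duration-adjusted
scores over the participants who worked in the group. Trees export to
Newick with branch lengths from merge-height differences.

## The synthetic cohort generator

The generator emulates the study conditions the analysis targets: 381
cases / 272 controls by default, consent ages ~N(62, 10) truncated to
[25, 90], 51.6% male, 13.6% enlisted with ~1% missing military data,
1–4 jobs per participant with calendar-consistent spans and sector
persistence (a later job stays in the previous job's SOC group with
probability 0.6). Item responses are drawn conditional on a per-job
latent exposure indicator whose probability comes from the SOC group's
exposure profile; a Gaussian copula across types within a job
(ρ = 0.9) plus shared group profiles induces the between-type
correlation structure of real occupational mixtures — measured PM–metals
Spearman ≈ 0.6 at n = 2000, with the dusty-trades pairs strongest. The
per-item false-positive rate for unexposed jobs is 0.005; higher values
scatter spurious small scores through the unexposed mass and visibly
dilute rank correlations.

Case status is generated *retrospectively*: true duration-adjusted
scores are computed through the package's own scoring chain, and a
logistic model on the standardized scores (planted per-SD log ORs;
default: metals = log 1.5, all else null) plus age/sex/military effects
assigns status, with the intercept calibrated by root-finding so the
pool's marginal case probability equals the target case fraction. This
is a case–control emulation, not incidence modelling; because logistic
odds ratios are invariant to outcome-dependent sampling, planted
coefficients are recoverable by the analysis models, which is exactly
the property the recovery tests exploit. Onset years sit 0–2 years
before consent, so essentially every case keeps at least one pre-onset
job; a stress switch (`post_onset_job_rate`) plants post-onset jobs to
exercise the exclusion rules. Ground truth (planted coefficients,
linear predictors, true scores recomputed after eligibility filtering)
is emitted as a sidecar that analysis code never reads.

What the generator does **not** emulate: free-text job titles (drawn
from a fixed per-group list), recall bias, correlated item nonresponse,
education-dependent response behaviour, or secular trends in exposure
prevalence. Passing recovery tests therefore demonstrates that the
estimators are consistent and calibrated under the assumed data model,
not that real survey data meet those assumptions.

## Numerical conventions

* Quantiles: linear interpolation of the empirical CDF
  (`stats::quantile` type 7) everywhere.
* Standardization: combined-sample mean and SD (n−1); constant vectors
  are an error, never silently zeroed.
* Half-open age-quartile bins; boundary values go up.
* Same-year jobs: duration floor 0.5 years.
* Seeds: every stochastic stage consumes a seed derived
  deterministically from the global seed and stage name; all derived
  seeds stay below 2^31.
* Tie-breaks: the military-service mode breaks ties toward the
  alphabetically earlier category; coder A candidates tie-break by rank
  then fit.

## Problem sizes used by the test suite

The packaged checks run on: a 6-participant / 10-job toy fixture; a
shared simulated cohort of 210 participants for module-level tests;
full-size cohorts (653 participants) for recovery — 50 replicates for
the univariate metals OR (mean and CI coverage) and 25 for adaptive
elastic net selection; 500 null replicates at n = 50+50 with B = 2000
for permutation calibration; and n = 2000 for correlation-structure
checks. These sizes make the Monte-Carlo tolerances in the tests
(±0.15 on a mean OR of 1.5, [0.03, 0.07] on a 5% rejection rate)
comfortably wider than the corresponding standard errors.

## Known limitations

* Year-resolution job histories cannot express partial-year or
  part-time work; job-years are calendar years, not FTE-years.
* Overlapping jobs each contribute their full duration (no
  de-overlapping), matching how published job-years tables sum without
  de-duplication; participants holding concurrent jobs are accordingly
  up-weighted.
* The triage cascade approximates, but cannot replace, expert review;
  its lookup tables ship as editable defaults.
* Penalized ORs from the adaptive elastic net are shrunken point
  estimates without confidence intervals; inference after selection is
  out of scope.
* Generalized-additive-model nonlinearity diagnostics and
  profile-likelihood or bootstrap intervals are deliberately not
  implemented.
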