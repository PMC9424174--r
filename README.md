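# occupex

Survey-based occupational exposure assessment for case–control studies of
amyotrophic lateral sclerosis (ALS) and other diseases with suspected
environmental risk factors. The package is aimed at epidemiologists who
collect per-job exposure questionnaires plus occupational histories and
want a reproducible path from raw survey tables to adjusted odds ratios,
penalized variable selection over correlated exposure mixtures, and
occupation-level (SOC-coded) job-years analyses.

## What it computes

**Exposure scores.** A configurable schema maps each of nine exposure
types (particulate matter, VOCs, pesticides, metals, biologicals,
combustion/diesel exhaust, electromagnetic, radiation, corrosives) to
exposure *factors*, each factor to survey items with response→contribution
maps. For a job *j* and factor *f* with items *i*:

    s_f = Σ_i c_i / Σ_i max(c_i)                (normalized to [0, 1])
    s_j = Σ_f w_f s_f / Σ_f w_f                 (factor-weighted mean)

Participant-level scores summarise up to four jobs: the **ever** score is
max_j s_j, and the **duration-adjusted** score is the duration-weighted
mean Σ_j s_j d_j / Σ_j d_j over eligible jobs (jobs beginning after
symptom onset for cases, or after consent for controls, are excluded).
Scores enter models standardized, so odds ratios are per SD.

**Association battery.** Permutation tests for case/control score
differences; logistic regressions adjusted for age quartiles, sex and
military service; a two-stage adaptive elastic net over all nine scores
(ridge weights |β|^-γ, unpenalized covariates, seeded 10-fold CV) to
select within correlated mixtures; Benjamini–Hochberg correction.

**SOC analyses.** Dual autocoder candidates are merged, triaged with a
0–3 review-priority cascade, and aggregated into a participant ×
major-group job-years matrix (optionally windowed 0–10 / 10–20 / 20+
years before the reference year). Per group: a one-sample enrichment
z-test of the case proportion against the cohort fraction, logistic
models reporting OR per 5 job-years with BH correction, an adaptive
lasso over all groups jointly, and linear models of exposure scores on
job-years. Exposure profiles per aggregated SOC group are clustered
(Euclidean distance, complete linkage) and exported as Newick trees.

**Synthetic cohorts.** `simulate_cohort()` generates seeded case–control
cohorts (default 381 cases / 272 controls) with calendar-consistent job
histories, SOC-group-driven correlated item responses, planted per-SD
log odds ratios, and dual-coder files with controllable disagreement —
plus a ground-truth sidecar, so every stage is testable end to end.

## Worked example

```r
library(occupex)

sim <- simulate_cohort(sim_config(seed = 7))   # planted metals OR = 1.5
dir <- tempfile(); write_sim(sim, dir)

res <- run_all(file.path(dir, "participants.csv"),
               file.path(dir, "jobs.csv"),
               file.path(dir, "responses.csv"),
               sim$candidates_a, sim$candidates_b,
               out_dir = file.path(dir, "out"), seed = 7, B = 999)

read.csv(file.path(dir, "out", "exposure_models.csv"))[
  , c("type", "n", "or_uni", "ci_low_uni", "ci_high_uni", "p_uni", "or_aen")]
```

yields (duration-adjusted scores, OR per SD, adjusted for age quartiles,
sex and military service):

```
             type   n or_uni ci_low_uni ci_high_uni    p_uni or_aen
1              pm 652   1.21      1.029        1.43 2.14e-02   1.00
4          metals 651   1.52      1.250        1.84 2.43e-05   1.38
6      combustion 652   1.19      1.010        1.41 3.80e-02   1.00
...
```

The planted metals effect (true per-SD OR 1.5) is recovered at 1.52
(95% CI 1.25–1.84) by the univariate model, and the adaptive elastic net
keeps metals (penalized OR 1.38) while shrinking most null exposures to
exactly 1. Correlated bystander exposures (PM, combustion) show the
attenuated marginal associations expected from an exposure mixture. The
same run writes the job-years tabulation, SOC models, metals-by-SOC
summaries, subcomponent intersection counts, and the profile dendrograms
in Newick form; the duration-adjusted dendrogram groups
"Operator, welding and metals", "Trades, plumbing", "Mechanic, vehicle"
and "Trades, electrical and sheet metal" into one high-exposure cluster.

The same pipeline runs from a shell:

```sh
Rscript scripts/run_pipeline.R --simulate --out results/demo --seed 7
```

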