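# capmatch

A matched treatment-comparison pipeline for community-acquired pneumonia
(CAP) cohorts: does adding a macrolide to a beta-lactam (BLM) change
end-of-observation outcomes relative to beta-lactam monotherapy (BL)?

Observational CAP registries confound this comparison — dual therapy goes
preferentially to younger, less frail patients — and admission labs and
vitals are partly missing. `capmatch` implements the full analysis chain for
that setting, plus a synthetic-cohort generator so every stage is testable
without patient data:

- **Multiple imputation by chained equations** (`impute_chained()`):
  m completed datasets (default 50, 5 sweeps), predictive mean matching for
  continuous targets, logistic draws for binary/categorical ones.
- **Propensity-score matching** (`fit_propensity()`, `average_and_logit()`,
  `match_caliper()`): logistic PS on 34 pretreatment covariates per imputed
  dataset; scores averaged on the probability scale across datasets, then
  logit-transformed; greedy 1:1 nearest-neighbor matching without
  replacement inside a caliper of 0.05 × SD of the logit scores
  (0.01 in the sensitivity profile).
- **Balance diagnostics** (`balance_table()`): standardized mean
  differences before/after matching, |SMD| < 0.1 flagged as balanced.
- **Endpoints** (`endpoint_panel()`, `aalen_johansen()`): death % and
  recovery % per arm with absolute differences, antibiotic days, hospital
  stay among matched inpatients, and Aalen–Johansen cumulative incidence
  with death and recovery as competing events.
- **Bootstrap-within-imputation inference** (`mi_boot()`): B bootstrap
  samples per imputed dataset (default 1000), full re-estimation
  (PS fit → caliper → match → endpoints) in each replicate, all replicate
  estimates pooled; point estimate = pooled median, 95% CI = pooled
  2.5th/97.5th percentiles (type-7).
- **Subgroups and sensitivity analyses**: CURB-65 ≥ 3 (`filter_severe()`),
  microbiologically confirmed non-atypical bacterial pneumonia
  (`filter_micro_confirmed()`), complete-case (`filter_complete_case()`),
  narrow caliper.

The statistic at the core: for endpoint Y and arms t ∈ {BLM, BL}, each
bootstrap replicate b of imputed dataset i yields Δ̂⁽ⁱᵇ⁾ = Ȳ_BLM − Ȳ_BL on
the re-matched sample; the pooled distribution {Δ̂⁽ⁱᵇ⁾ : i ≤ m, b ≤ B} gives
the reported median and percentile interval.

## Worked example

```r
library(capmatch)

sim <- simulate_cohort(simulation_config(n = 1200, seed = 42))
sim$cohort
#> <cohort_table> 1200 patients (153 BLM / 1047 BL), 41 covariates
#>   missing covariate cells: 771

imp <- impute_chained(sim$cohort, imputation_config(m = 5, iterations = 5, seed = 7))
fits   <- lapply(imp$datasets, fit_propensity)
scores <- average_and_logit(fits)
m <- match_caliper(scores, imp$datasets[[1]]$arm, compute_caliper(scores, 0.05))
m
#> <match_result> 145 pairs, 8 unmatched treated, caliper 0.06881

b <- balance_table(imp$datasets[[1]], m)
sum(b$balanced_before); sum(b$balanced_after)   # 19 -> 27 of 34 covariates

mi_boot(imp, boot_config(B = 50, seed = 9))
#> <mi_boot_result> 250 valid / 0 invalid replicates
#>               endpoint   point   lower   upper n_used
#>         death_pct_diff   3.759  -2.179   9.840    250
#>      recovery_pct_diff  -3.113  -9.509   2.498    250
#>          abx_days_diff  -0.326  -1.235   0.569    250
#>          los_days_diff  -1.565  -4.993   1.370    250
#>              matched_n 137.000 118.000 163.000    250
#>                    ... (per-arm rows omitted here)
```

Reading it: after matching, 27 of the 34 propensity covariates sit under
the 0.1 SMD balance threshold (19 before). The matched death-rate
difference is +3.8 percentage points with a pooled-bootstrap 95% CI of
−2.2 to +9.8 — at this reduced n/m/B the interval comfortably contains the
generator's true null effect, and the matched n itself is summarised as a
median (137) with its own CI because unstratified resampling lets it vary.

One-call orchestration, with every stage artifact written as plain CSV/JSON:

```r
report <- run_pipeline(run_config(
  out_dir = "out", sim_config = simulation_config(n = 2784),
  seed = 1, analyses = c("main", "severe", "complete_case"), fast = TRUE))
```

A command-line front end with subcommands `simulate`, `impute`, `match`,
`analyze`, `run-all`, `report` ships in `inst/cli/capmatch.R`:

```sh
Rscript inst/cli/capmatch.R run-all --out out --seed 1 --fast --subgroup severe
Rscript inst/cli/capmatch.R report --out out
```

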