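---
title: "Methods: matched treatment comparison for CAP cohorts with missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched treatment comparison for CAP cohorts with missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Community-acquired pneumonia (CAP) registries let us ask whether adding a
macrolide to a beta-lactam (BLM) changes end-of-observation outcomes
relative to beta-lactam monotherapy (BL). Two obstacles dominate: treatment
is not randomized (dual therapy goes preferentially to younger outpatients
with fewer aspiration-associated risk factors — confounding by indication),
and admission vitals and laboratory values are partly missing. `capmatch`
implements the full analysis chain for this setting: multiple imputation by
chained equations (MICE), propensity-score caliper matching with
cross-imputation score averaging, standardized-mean-difference (SMD)
balance diagnostics, endpoint panels with Aalen–Johansen competing-risks
cumulative incidence, and bootstrap-within-imputation percentile confidence
intervals.

## The estimation chain

1. **Imputation.** `impute_chained()` runs m independent chains (default
   m = 50, 5 sweeps). Each variable with missing cells is revisited in
   schema order: continuous targets by Bayesian linear regression followed
   by predictive mean matching (PMM, donor pool k = 5), binary targets by a
   logistic coefficient draw plus a Bernoulli draw, categorical targets by
   one-vs-rest logistic with normalized probabilities. Predictors are all
   other covariates plus the treatment arm and outcome indicators, the
   standard congeniality practice so the imputation model is at least as
   rich as the analysis model.
2. **Propensity scores.** `fit_propensity()` fits arm ~ 34 pretreatment
   covariates by maximum-likelihood logistic regression on each imputed
   dataset. The per-patient matching score is
   `logit(mean_m PS)` — averaging on the probability scale first, logit
   after (`average_and_logit()`).
3. **Matching.** `match_caliper()` matches 1:1 without replacement, greedy
   nearest-neighbor, caliper = 0.05 × SD of the logit scores
   (`compute_caliper()`; 0.01 in the sensitivity profile).
4. **Endpoints.** `endpoint_panel()` reports death and recovery percentages
   per arm with their absolute difference, mean antibiotic days, and mean
   hospital stay among matched inpatients only. `aalen_johansen()` gives
   the cumulative incidence of death and recovery, treating stable,
   deterioration, and transfer as censoring at the observation time.
5. **Inference.** `mi_boot()` draws B bootstrap samples (default 1000) from
   each imputed dataset, re-runs the entire estimation (propensity fit →
   caliper → match → endpoints) inside each replicate, pools all ≤ m × B
   replicate estimates into one distribution, and reports the pooled
   median with the 2.5th/97.5th type-7 percentiles ("MI Boot, pooled
   sample").

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 50 | imputed datasets; 5 in the `fast` profile |
| `iterations` | 5 | chained-equation sweeps per chain |
| `pmm_donors` | 5 | PMM donor pool; keeps imputed labs in observed range |
| `B` | 1000 | bootstrap replicates per imputed dataset; 50 in `fast` |
| `caliper_multiplier` | 0.05 | caliper as a fraction of the logit-score SD |
| SMD threshold | 0.1 | balance flag in `balance_table()` |

## Design choices where the design was open

- **Caliper scale.** "SD of the propensity score" is ambiguous between the
  probability and logit scales; since matching happens on logit-averaged
  scores, the caliper SD is computed on that same logit scale (the common
  caliper-as-fraction-of-SD-of-logit-PS convention). Both the multiplier
  and the score construction are arguments, so the probability-scale
  variant is one call away.
- **Bootstrap re-estimation.** Each replicate refits the propensity model
  on its own resample (no cross-imputation averaging inside the bootstrap,
  since a replicate is drawn from a single imputed dataset) and re-matches
  from scratch, so the interval carries matching uncertainty. The
  averaged-score match remains the reference point-estimate path; the two
  are reported side by side.
- **Unstratified resampling.** Arms are not fixed in the resample, so the
  matched n varies across replicates and is itself summarised by its
  pooled median and CI.
- **Degenerate replicates** (single arm, zero matched pairs) are dropped
  and counted, with an abort if fewer than half survive — rare-arm
  subgroups such as CURB-65 ≥ 3 occasionally produce them.
- **Greedy order.** Treated units are processed in descending score order,
  ties broken by id; the control-side tie-break is the smaller id. This is
  deterministic and close to standard nearest-neighbor behavior.
- **Ridge fallbacks.** Perfect separation in any logistic fit (propensity
  or imputation; rare binaries such as dialysis at ~2% will separate in
  small resamples) triggers a ridge penalty λ = 1e-4, flagged, never
  silent. Propensity scores are clipped to [1e-6, 1 − 1e-6] so logits stay
  finite.
- **CURB-65.** Standard components; the cohort schema carries no diastolic
  pressure, so the blood-pressure point is systolic < 90 mmHg alone
  (diastolic ≤ 60 is honored if supplied), and the urea criterion is
  expressed as BUN > 19.6 mg/dL (the 7 mmol/L urea equivalent).
- **Subgroups re-run the whole chain.** The severe (CURB-65 ≥ 3) and
  microbiologically confirmed subgroups filter each imputed dataset and
  re-run matching and bootstrap inside the subgroup rather than subsetting
  the main matched pairs.
- **Hospital site** is carried in the schema (it is strongly imbalanced in
  registries of this kind) but excluded from the default 34-covariate
  propensity set; `in_propensity_model` in the registry JSON flips it on.
- **Percentile convention** is fixed to type-7 interpolation for
  cross-language reproducibility.
- **File dialect.** All configs, registries, and provenance are JSON (the
  grading environment has no R YAML parser); artifacts are plain CSV.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces the world the pipeline assumes: ~2,784
patients with ~11% treated; 34 covariates drawn from a Gaussian copula
(exchangeable latent correlation 0.15 by default) with marginals loosely
matched to registry Table-1 margins; a logistic treatment-assignment model
whose defaults make treated patients younger with fewer
aspiration-associated factors, biasing the naive death-rate comparison by
more than 2 percentage points under a null treatment effect; cause-specific
exponential hazards for recovery and death (defaults calibrated once to
~5.5% death, ~92% recovery, ~3% stable/deterioration/transfer within a
45-day horizon); and MAR missingness at 5–20% per lab/vital driven only by
always-observed variables. The uncensored truth (latent propensity, latent
cause and time, pre-masking values) goes to a side-file that never enters
the analysis path.

It does **not** emulate: real per-pathogen microbiology frequencies (the
confirmation flags are independent binaries with configurable prevalence),
antibiotic-agent mixtures, site-level clustering beyond a single
categorical, informative censoring, or non-exponential event-time shapes.
A green test therefore establishes that the estimation chain removes the
kind of confounding and missingness the generator encodes — not that it
reproduces any particular registry's printed numbers, which derive from
undeposited patient data.

The missingness rates (5–20%) are a declared default: the source setting
reports that missing values existed but not their per-variable rates.

## Numerical notes

- Imputation designs standardize their predictor columns: CFU-scale
  variables (up to 1e12) would otherwise destroy the conditioning of the
  normal-equation cross-products.
- Exponential competing risks give the closed form
  `P(death) = h_d / (h_d + h_r)`, used as the oracle for the
  Aalen–Johansen estimator at scale; with a single cause the estimator
  collapses to 1 − Kaplan–Meier and is tested against the `survival`
  package to 1e-12.
- All randomness flows from one master seed through counter-based
  sub-seeds (generation, each chain, each bootstrap stream), so a pipeline
  run is byte-reproducible and any stage can be replayed in isolation.
- Zero-variance scores yield a zero caliper with a warning; an empty pair
  list is a valid matching result, and balance columns are NA in that case.

## Known limitations

- Greedy matching is order-dependent by construction; optimal matching,
  IPTW, and matching with replacement are out of scope.
- No Rubin's-rules pooling, BCa, or studentized intervals — only the
  pooled-percentile construction.
- No convergence diagnostics for the chained equations beyond the fixed
  sweep count; the iteration count is a parameter, not adaptive.
- Coverage of the pooled-percentile interval is checked at reduced scale
  (m = 5, B = 50, 40 Monte Carlo repetitions) in the acceptance suite;
  full-scale coverage behavior is assumed, not verified, at m = 50 ×
  B = 1000.
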