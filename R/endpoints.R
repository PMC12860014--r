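# endpoint panels on a matched cohort, CURB-65 scoring, subgroup and
# sensitivity filters, and the Aalen-Johansen cumulative incidence estimator

#' Primary and secondary endpoint panel on a matched cohort
#'
#' Proportions of death and recovery per arm over the matched patients,
#' mean antibiotic duration per arm, mean hospital stay over matched
#' inpatients only, and the between-arm absolute differences (BLM - BL).
#' Percentages are on the 0--100 scale.
#'
#' @param cohort a cohort table.
#' @param match a `match_result` (non-empty).
#' @return an `endpoint_panel`: named list of per-arm values, differences,
#'   and matched-set sizes. Hospital-stay cells are NA when no matched
#'   inpatients exist.
#' @export
endpoint_panel <- function(cohort, match) {
  stopifnot(nrow(match$pairs) > 0)
  ids <- c(match$pairs$treated_id, match$pairs$control_id)
  sub <- cohort[cohort$id %in% ids, , drop = FALSE]
  one_arm <- function(arm) sub[sub$arm == arm, , drop = FALSE]
  stat_for <- function(d) {
    inpat <- d[!is.na(d$los_days), , drop = FALSE]
    list(n = nrow(d),
         death_pct = 100 * mean(d$outcome == "death"),
         recovery_pct = 100 * mean(d$outcome == "recovery"),
         abx_days = mean(d$abx_days),
         los_days = if (nrow(inpat)) mean(inpat$los_days) else NA_real_,
         n_inpatient = nrow(inpat))
  }
  blm <- stat_for(one_arm("BLM")); bl <- stat_for(one_arm("BL"))
  diff_or_na <- function(a, b) {
    if (is.na(a) || is.na(b)) NA_real_ else a - b
  }
  structure(list(
    n_pairs = nrow(match$pairs),
    BLM = blm, BL = bl,
    diff = list(death_pct = blm$death_pct - bl$death_pct,
                recovery_pct = blm$recovery_pct - bl$recovery_pct,
                abx_days = blm$abx_days - bl$abx_days,
                los_days = diff_or_na(blm$los_days, bl$los_days))),
    class = "endpoint_panel")
}

#' Flatten an endpoint panel to a named numeric vector
#' @param panel an `endpoint_panel`.
#' @return named numeric vector (the bootstrap estimand set).
#' @export
panel_to_vector <- function(panel) {
  c(death_pct_BLM = panel$BLM$death_pct,
    death_pct_BL = panel$BL$death_pct,
    death_pct_diff = panel$diff$death_pct,
    recovery_pct_BLM = panel$BLM$recovery_pct,
    recovery_pct_BL = panel$BL$recovery_pct,
    recovery_pct_diff = panel$diff$recovery_pct,
    abx_days_BLM = panel$BLM$abx_days,
    abx_days_BL = panel$BL$abx_days,
    abx_days_diff = panel$diff$abx_days,
    los_days_BLM = panel$BLM$los_days,
    los_days_BL = panel$BL$los_days,
    los_days_diff = panel$diff$los_days,
    matched_n = panel$n_pairs,
    matched_inpatient_BLM = panel$BLM$n_inpatient,
    matched_inpatient_BL = panel$BL$n_inpatient)
}

#' CURB-65 severity score
#'
#' One point each for: impaired consciousness; BUN > 19.6 mg/dL (urea
#' > 7 mmol/L); respiratory rate >= 30 /min; systolic blood pressure
#' < 90 mmHg (diastolic pressure is not collected in this schema, so the
#' blood-pressure criterion is systolic-only unless `diastolic_bp` is
#' supplied, in which case < 60 mmHg also scores); age >= 65 years.
#'
#' @param confusion 0/1 impaired consciousness flag.
#' @param bun blood urea nitrogen, mg/dL.
#' @param respiratory_rate breaths/min.
#' @param systolic_bp mmHg.
#' @param age years.
#' @param diastolic_bp optional, mmHg.
#' @return integer score(s) 0--5.
#' @export
curb65 <- function(confusion, bun, respiratory_rate, systolic_bp, age,
                   diastolic_bp = NULL) {
  stopifnot(!anyNA(confusion), !anyNA(bun), !anyNA(respiratory_rate),
            !anyNA(systolic_bp), !anyNA(age))
  bp <- systolic_bp < 90
  if (!is.null(diastolic_bp)) bp <- bp | diastolic_bp <= 60
  as.integer((confusion > 0) + (bun > 19.6) + (respiratory_rate >= 30) +
               bp + (age >= 65))
}

curb65_cohort <- function(cohort) {
  curb65(cohort$impaired_consciousness, cohort$bun,
         cohort$respiratory_rate, cohort$systolic_bp, cohort$age)
}

#' Severe-pneumonia subgroup (CURB-65 >= 3)
#'
#' @param cohort a complete cohort table (CURB-65 components imputed).
#' @return the row subset with CURB-65 >= 3 (possibly empty); matching and
#'   endpoints are meant to be re-run from scratch inside the subgroup.
#' @export
filter_severe <- function(cohort) {
  cohort[curb65_cohort(cohort) >= 3, , drop = FALSE]
}

#' Microbiologically confirmed non-atypical bacterial pneumonia subgroup
#'
#' Keeps rows meeting at least one of: positive blood culture for a
#' non-atypical bacterial pathogen; pleural fluid culture yielding such a
#' pathogen; a high-quality sputum sample with predominant growth at
#' >= 1e6 CFU/mL or a semiquantitative score of 3+; or a positive
#' pneumococcal urinary antigen test.
#'
#' @param cohort a cohort table carrying the flag columns `micro_blood`,
#'   `micro_pleural`, `sputum_quality`, `sputum_cfu`, `sputum_semiquant`,
#'   `micro_urinary`.
#' @return the confirmed row subset.
#' @export
filter_micro_confirmed <- function(cohort) {
  need <- c("micro_blood", "micro_pleural", "sputum_quality", "sputum_cfu",
            "sputum_semiquant", "micro_urinary")
  absent <- setdiff(need, names(cohort))
  if (length(absent)) {
    stop("missing microbiology column(s): ", paste(absent, collapse = ", "))
  }
  keep <- cohort$micro_blood == 1 |
    cohort$micro_pleural == 1 |
    (cohort$sputum_quality == 1 &
       (cohort$sputum_cfu >= 1e6 | cohort$sputum_semiquant >= 3)) |
    cohort$micro_urinary == 1
  cohort[!is.na(keep) & keep, , drop = FALSE]
}

#' Complete-case subcohort
#'
#' Rows with zero missing covariate cells (the pre-imputation sensitivity
#' analysis).
#'
#' @param cohort a cohort table.
#' @return the complete rows.
#' @export
filter_complete_case <- function(cohort) {
  spec <- attr(cohort, "covariate_spec")
  ok <- stats::complete.cases(cohort[, spec$name, drop = FALSE])
  cohort[ok, , drop = FALSE]
}

#' Aalen-Johansen cumulative incidence estimator
#'
#' Nonparametric CIF for competing terminal events:
#' `CIF_k(t) = sum over event times t_i <= t of S(t_i-) d_ki / n_i`, with
#' `S` the Kaplan-Meier survival of the event-free state (all causes
#' pooled). Nonterminal outcomes (stable, deterioration, transfer) enter as
#' censoring at their observation time.
#'
#' @param time nonnegative event/censoring times.
#' @param cause character, one of "death", "recovery", "censored".
#' @return a `cif_curve` data frame: `time`, `n_risk`, `surv` (event-free
#'   KM just after `time`), and one cumulative-incidence column per cause.
#' @export
aalen_johansen <- function(time, cause) {
  stopifnot(length(time) == length(cause))
  if (any(time < 0)) stop("negative time")
  bad <- setdiff(unique(cause), c("death", "recovery", "censored"))
  if (length(bad)) stop("unknown cause: ", bad[1])
  ut <- sort(unique(time[cause != "censored"]))
  n <- length(time)
  sorted <- sort(time)
  # at risk just before t_i: all with time >= t_i
  n_risk <- n - findInterval(ut, sorted, left.open = TRUE)
  d_d <- vapply(split(rep(1, sum(cause == "death")),
                      factor(time[cause == "death"], levels = ut)),
                sum, 0)
  d_r <- vapply(split(rep(1, sum(cause == "recovery")),
                      factor(time[cause == "recovery"], levels = ut)),
                sum, 0)
  S <- cumprod(1 - (d_d + d_r) / n_risk)   # KM just after each event time
  S_prev <- c(1, S[-length(S)])
  out <- data.frame(time = ut, n_risk = n_risk, surv = unname(S),
                    cif_death = cumsum(S_prev * d_d / n_risk),
                    cif_recovery = cumsum(S_prev * d_r / n_risk))
  rownames(out) <- NULL
  class(out) <- c("cif_curve", "data.frame")
  out
}

#' Per-arm CIF curves in tidy form
#'
#' @param cohort a cohort table; outcomes other than death/recovery censor
#'   at `obs_days`.
#' @return tidy data frame (`arm`, `time`, `cause`, `estimate`, `n_risk`).
#' @export
cif_by_arm <- function(cohort) {
  cause <- ifelse(cohort$outcome %in% c("death", "recovery"),
                  cohort$outcome, "censored")
  res <- lapply(ARM_LEVELS, function(a) {
    idx <- cohort$arm == a
    if (!any(idx)) return(NULL)
    cc <- aalen_johansen(cohort$obs_days[idx], cause[idx])
    rbind(data.frame(arm = a, time = cc$time, cause = "death",
                     estimate = cc$cif_death, n_risk = cc$n_risk),
          data.frame(arm = a, time = cc$time, cause = "recovery",
                     estimate = cc$cif_recovery, n_risk = cc$n_risk))
  })
  do.call(rbind, res)
}
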