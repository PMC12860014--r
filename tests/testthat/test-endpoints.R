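# endpoint panels, CURB-65, subgroup filters, Aalen-Johansen CIF

make_match <- function(cohort) {
  t_ids <- cohort$id[cohort$arm == "BLM"]
  c_ids <- cohort$id[cohort$arm == "BL"][seq_along(t_ids)]
  structure(list(pairs = data.frame(treated_id = t_ids, control_id = c_ids,
                                    score_t = 0, score_c = 0,
                                    stringsAsFactors = FALSE),
                 caliper_width = Inf, unmatched_treated = character(0),
                 score_used = numeric(0)), class = "match_result")
}

test_that("endpoint_panel reproduces hand arithmetic", {
  co <- mini_cohort(age = rep(70, 8),
                    arm = rep(c("BLM", "BL"), each = 4),
                    outcome = c("death", "recovery", "recovery", "recovery",
                                rep("recovery", 4)))
  co$abx_days <- c(7, 9, 7, 9, 10, 10, 10, 10)
  p <- endpoint_panel(co, make_match(co))
  expect_equal(p$BLM$death_pct, 25)
  expect_equal(p$BL$death_pct, 0)
  expect_equal(p$diff$death_pct, 25)
  expect_equal(p$BLM$abx_days, 8)
  expect_equal(p$BL$abx_days, 10)
  expect_equal(p$diff$abx_days, -2)
  # identical outcome vectors in both arms: zero differences
  co2 <- mini_cohort(age = rep(70, 6), arm = rep(c("BLM", "BL"), 3),
                     outcome = rep(c("death", "recovery", "stable"),
                                   each = 2))
  p2 <- endpoint_panel(co2, make_match(co2))
  expect_equal(p2$diff$death_pct, 0)
  expect_equal(p2$diff$recovery_pct, 0)
})

test_that("endpoint differences are antisymmetric under arm relabeling", {
  co <- sim_cohort(n = 200, seed = 61, miss_probs = list())$cohort
  fit <- fit_propensity(co)
  sc <- qlogis(fit$scores)
  m <- match_caliper(sc, co$arm, compute_caliper(sc, 0.5))
  p <- endpoint_panel(co, m)
  flipped <- co
  flipped$arm <- ifelse(co$arm == "BLM", "BL", "BLM")
  m2 <- m
  m2$pairs <- data.frame(treated_id = m$pairs$control_id,
                         control_id = m$pairs$treated_id,
                         score_t = m$pairs$score_c, score_c = m$pairs$score_t,
                         stringsAsFactors = FALSE)
  pf <- endpoint_panel(flipped, m2)
  expect_equal(pf$diff$death_pct, -p$diff$death_pct)
  expect_equal(pf$diff$abx_days, -p$diff$abx_days)
})

test_that("hospital stay is assessed exclusively in inpatients", {
  co <- mini_cohort(age = rep(70, 4))
  co$los_days <- c(10, NA, 20, NA)   # one inpatient per arm
  p <- endpoint_panel(co, make_match(co))
  expect_equal(p$BLM$los_days, 10)
  expect_equal(p$BL$los_days, 20)
  expect_equal(p$BLM$n_inpatient, 1)
  co$los_days <- NA_real_            # no inpatients at all
  p0 <- endpoint_panel(co, make_match(co))
  expect_true(is.na(p0$BLM$los_days))
  expect_true(is.na(p0$diff$los_days))
})

test_that("curb65 scores the standard components", {
  expect_equal(curb65(0, 10, 20, 120, 40), 0L)
  expect_equal(curb65(1, 30, 32, 85, 80), 5L)
  # boundaries: age 65 scores, RR 30 scores, BUN 19.6 does not (> rule)
  expect_equal(curb65(0, 10, 20, 120, 65), 1L)
  expect_equal(curb65(0, 19.6, 29.9, 90, 64), 0L)
  expect_equal(curb65(0, 19.7, 30, 89.9, 64), 3L)
  # monotone: worsening any single component never decreases the score
  base <- c(confusion = 0, bun = 15, rr = 25, sbp = 100, age = 60)
  s0 <- curb65(base[1], base[2], base[3], base[4], base[5])
  worse <- list(c(1, 15, 25, 100, 60), c(0, 25, 25, 100, 60),
                c(0, 15, 35, 100, 60), c(0, 15, 25, 80, 60),
                c(0, 15, 25, 100, 70))
  for (w in worse) {
    expect_gte(curb65(w[1], w[2], w[3], w[4], w[5]), s0)
  }
})

test_that("subgroup and sensitivity filters behave as defined", {
  co <- sim_cohort(n = 500, seed = 62, miss_probs = list())$cohort
  sev <- filter_severe(co)
  scores <- curb65(co$impaired_consciousness, co$bun, co$respiratory_rate,
                   co$systolic_bp, co$age)
  expect_equal(nrow(sev), sum(scores >= 3))
  # all-mild cohort: empty subgroup, not an error
  mild <- co
  mild$age <- 40; mild$bun <- 10; mild$respiratory_rate <- 18
  mild$systolic_bp <- 120; mild$impaired_consciousness <- 0
  expect_equal(nrow(filter_severe(mild)), 0)

  # micro confirmation boolean logic, boundary inclusive at 1e6 CFU
  mc <- co[1:5, ]
  mc$micro_blood <- c(1, 0, 0, 0, 0)
  mc$micro_pleural <- 0
  mc$micro_urinary <- c(0, 0, 0, 0, 1)
  mc$sputum_quality <- c(0, 1, 0, 1, 0)
  mc$sputum_cfu <- c(0, 1e6, 1e9, 1e3, 0)
  mc$sputum_semiquant <- c(0, 0, 0, 3, 0)
  got <- filter_micro_confirmed(mc)
  expect_equal(got$id, mc$id[c(1, 2, 4, 5)])  # row 3: quality 0 excludes
  mc$micro_blood <- NULL
  expect_error(filter_micro_confirmed(mc), "micro_blood")

  # complete-case filter partitions the cohort
  masked <- sim_cohort(n = 300, seed = 63)$cohort
  cc <- filter_complete_case(masked)
  spec_names <- ps_covariates()
  expect_equal(nrow(cc),
               sum(stats::complete.cases(masked[, covariate_spec()$name])))
  expect_equal(sum(is.na(cc[, spec_names, drop = FALSE])), 0)
  expect_identical(as.data.frame(filter_complete_case(cc)),
                   as.data.frame(cc))
})

test_that("aalen_johansen reproduces hand values and the KM degeneracy", {
  aj <- aalen_johansen(c(1, 2), c("death", "recovery"))
  expect_equal(aj$cif_death, c(0.5, 0.5))
  expect_equal(aj$cif_recovery, c(0, 0.5))
  expect_error(aalen_johansen(c(-1, 2), c("death", "recovery")), "negative")
  expect_error(aalen_johansen(1, "relapse"), "unknown cause")
  # no censoring: CIF_k(inf) equals the sample proportion of cause k and
  # mass is conserved at every event time
  set.seed(64)
  tm <- rexp(300); cs <- sample(c("death", "recovery"), 300, TRUE, c(.3, .7))
  aj2 <- aalen_johansen(tm, cs)
  expect_equal(tail(aj2$cif_death, 1), mean(cs == "death"), tolerance = 1e-12)
  expect_lt(max(abs(aj2$cif_death + aj2$cif_recovery + aj2$surv - 1)), 1e-12)
  expect_true(all(diff(aj2$cif_death) >= 0))
  expect_true(all(diff(aj2$cif_recovery) >= 0))
})

test_that("single-cause CIF equals 1 - Kaplan-Meier (survival oracle)", {
  skip_if_not_installed("survival")
  set.seed(65)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    tm <- round(rexp(n), 2)
    cs <- ifelse(runif(n) < 0.6, "recovery", "censored")
    if (!any(cs == "recovery")) next
    aj <- aalen_johansen(tm, cs)
    km <- summary(survival::survfit(survival::Surv(tm, cs == "recovery") ~ 1),
                  times = aj$time)
    expect_lt(max(abs(aj$cif_recovery - (1 - km$surv))), 1e-12)
  }
})

test_that("cif_by_arm censors nonterminal outcomes and tidies per arm", {
  co <- sim_cohort(n = 400, seed = 66, miss_probs = list())$cohort
  cif <- cif_by_arm(co)
  expect_setequal(unique(cif$arm), c("BLM", "BL"))
  expect_setequal(unique(cif$cause), c("death", "recovery"))
  for (a in c("BLM", "BL")) {
    for (cs in c("death", "recovery")) {
      est <- cif$estimate[cif$arm == a & cif$cause == cs]
      expect_true(all(diff(est) >= 0))
      expect_true(all(est >= 0 & est <= 1))
    }
  }
})
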