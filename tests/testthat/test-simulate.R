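# synthetic cohort generator: determinism, copula marginals, confounded
# assignment, competing outcomes, MAR masking

test_that("generation is deterministic given the seed and varies across seeds", {
  a <- simulate_cohort(simulation_config(n = 60, seed = 5))
  b <- simulate_cohort(simulation_config(n = 60, seed = 5))
  c <- simulate_cohort(simulation_config(n = 60, seed = 6))
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c$cohort)))
})

test_that("n = 0 yields an empty cohort; outcome categories partition", {
  empty <- simulate_cohort(simulation_config(n = 0, seed = 1))
  expect_equal(nrow(empty$cohort), 0)
  co <- sim_cohort(n = 400, seed = 2)$cohort
  expect_true(all(co$outcome %in%
                    c("recovery", "stable", "deterioration", "death",
                      "transfer")))
  expect_equal(nrow(co), 400)
})

test_that("identity copula gives near-zero pairwise covariate correlations", {
  covs <- generate_covariates(simulation_config(n = 10000, seed = 3,
                                                rho = 0))
  cont <- c("age", "heart_rate", "respiratory_rate", "systolic_bp",
            "hematocrit", "bun", "sodium", "glucose", "albumin")
  cm <- stats::cor(covs[, cont])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  # non-positive-definite correlation matrix is rejected
  p <- length(covariate_spec()$name)
  bad <- matrix(0.99, p, p); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(generate_covariates(simulation_config(n = 10, rho = bad)),
               "positive definite")
})

test_that("treatment assignment hits its marginal rate and confounds by age", {
  cfg <- simulation_config(n = 50000, seed = 4,
                           treat_coefs = c(`(Intercept)` = qlogis(0.11)))
  covs <- generate_covariates(cfg)
  trt <- assign_treatment(covs, cfg)
  expect_lt(abs(mean(trt$arm == "BLM") - 0.11), 0.01)
  # large negative intercept: everyone is BL
  cfg2 <- simulation_config(n = 500, seed = 4,
                            treat_coefs = c(`(Intercept)` = -40))
  expect_true(all(assign_treatment(generate_covariates(cfg2),
                                   cfg2)$arm == "BL"))
  # negative age coefficient: treated are younger on average
  cfg3 <- simulation_config(n = 20000, seed = 4)
  covs3 <- generate_covariates(cfg3)
  trt3 <- assign_treatment(covs3, cfg3)
  expect_lt(mean(covs3$age[trt3$arm == "BLM"]),
            mean(covs3$age[trt3$arm == "BL"]))
  # unknown covariate in the coefficient map is an error
  cfg_bad <- simulation_config(n = 10,
                               treat_coefs = c(`(Intercept)` = 0,
                                               not_a_var = 1))
  expect_error(assign_treatment(generate_covariates(cfg_bad), cfg_bad),
               "unknown covariate")
})

test_that("competing exponential hazards match their closed form", {
  # equal constant hazards: P(death before recovery) = h_d/(h_r + h_d) = 1/2
  cfg <- simulation_config(
    n = 50000, seed = 5,
    outcome_coefs = list(base_death = 0.1, base_recovery = 0.1,
                         death = c(), recovery = c()),
    max_followup_days = 500)
  covs <- generate_covariates(cfg)
  out <- simulate_outcomes(covs, rep("BL", cfg$n), cfg)
  expect_lt(abs(mean(out$latent_cause == "death") - 0.5), 0.01)
  # zero death hazard: nobody dies
  cfg0 <- simulation_config(
    n = 2000, seed = 5,
    outcome_coefs = list(base_death = 0, base_recovery = 0.1,
                         death = c(), recovery = c()))
  out0 <- simulate_outcomes(generate_covariates(cfg0), rep("BL", 2000), cfg0)
  expect_equal(sum(out0$outcome == "death"), 0)
})

test_that("MAR masking hits its rates and rejects non-MAR models", {
  cfg <- simulation_config(
    n = 10000, seed = 6,
    miss_probs = list(bun = list(intercept = qlogis(0.3), coefs = NULL)))
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(is.na(sim$cohort$bun)) - 0.30), 0.02)
  expect_equal(sum(is.na(sim$cohort$albumin)), 0)
  # no masking configured: complete cohort (los_days NA only for outpatients)
  cfg0 <- simulation_config(n = 200, seed = 6, miss_probs = list())
  co0 <- simulate_cohort(cfg0)$cohort
  expect_equal(sum(is.na(co0[, ps_covariates(), drop = FALSE])), 0)
  # missingness depending on treatment setting differs by setting
  cfg2 <- simulation_config(
    n = 10000, seed = 7,
    miss_probs = list(bun = list(intercept = -2, coefs = c(outpatient = 1.5))))
  co2 <- simulate_cohort(cfg2)$cohort
  r_out <- mean(is.na(co2$bun[co2$outpatient == 1]))
  r_in <- mean(is.na(co2$bun[co2$outpatient == 0]))
  expect_gt(r_out, r_in + 0.05)
  # model referencing a maskable covariate violates MAR
  cfg_bad <- simulation_config(
    n = 50,
    miss_probs = list(bun = list(intercept = -2, coefs = c(albumin = 1)),
                      albumin = list(intercept = -2, coefs = NULL)))
  expect_error(simulate_cohort(cfg_bad), "MAR")
})

test_that("truth side-file never leaks into the analysis cohort", {
  sim <- sim_cohort(n = 50, seed = 8)
  expect_false(any(c("latent_ps", "latent_cause", "latent_time") %in%
                     names(sim$cohort)))
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(c("latent_ps", "latent_cause", "latent_time") %in%
                    names(sim$truth)))
})
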