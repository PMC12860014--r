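# propensity estimation, score averaging, caliper matching, SMD balance

test_that("null propensity model scores concentrate at the treated fraction", {
  # arm independent of the 34 covariates: fitted scores approach the
  # marginal treated fraction as n grows (overfitting noise shrinks)
  max_dev <- function(n) {
    sim <- simulate_cohort(simulation_config(
      n = n, seed = 41, miss_probs = list(),
      treat_coefs = c(`(Intercept)` = qlogis(0.2))))
    fit <- fit_propensity(sim$cohort)
    p <- mean(sim$cohort$arm == "BLM")
    c(max = max(abs(fit$scores - p)), mean = mean(abs(fit$scores - p)))
  }
  small <- max_dev(1500)
  big <- max_dev(12000)
  expect_lt(big["max"], small["max"])
  expect_lt(big["mean"], 0.03)
})

test_that("perfect separation falls back to ridge with finite coefficients", {
  co <- sim_cohort(n = 200, seed = 42)$cohort
  co <- initialize_fill(co, seed = 1)
  co$pleural_effusion <- as.numeric(co$arm == "BLM")  # perfect predictor
  fit <- fit_propensity(co)
  expect_true(fit$ridge_used)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(fit$scores > 0 & fit$scores < 1))
  # single-arm input is an error
  co_bl <- co[co$arm == "BL", ]
  expect_error(fit_propensity(co_bl), "both arms")
  expect_error(fit_propensity(sim_cohort(n = 50, seed = 1)$cohort),
               "complete")
})

test_that("propensity estimates recover the generator's coefficients", {
  cfg <- simulation_config(n = 20000, seed = 43, miss_probs = list())
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  co$age <- co$age - 65        # generator centers age at 65
  X <- capmatch:::build_design(as.data.frame(co), ps_covariates(),
                               covariate_spec())
  fit <- capmatch:::fit_logit(X, as.numeric(co$arm == "BLM"))
  se <- sqrt(diag(fit$vcov))
  names(se) <- colnames(X)
  cf <- stats::setNames(fit$coef, colnames(X))
  truth <- default_treat_coefs()
  for (nm in c("age", "aspiration_episodes", "dementia", "nursing_home")) {
    expect_lt(abs(cf[nm] - truth[nm]), 2.5 * se[nm])
  }
})

test_that("average_and_logit averages on the probability scale", {
  mk <- function(scores) {
    structure(list(coefficients = c(), scores = scores, fitted_on = "x",
                   ridge_used = FALSE), class = "propensity_fit")
  }
  ids <- c(a = 0.5)
  expect_equal(average_and_logit(list(mk(c(a = 0.5)))), c(a = 0))
  two <- average_and_logit(list(mk(c(a = 0.2)), mk(c(a = 0.4))))
  expect_equal(unname(two), qlogis(0.3), tolerance = 1e-9)
  expect_equal(unname(two), -0.8472979, tolerance = 1e-6)
  # constant across datasets: exactly logit(p)
  many <- average_and_logit(lapply(1:5, function(i) mk(c(a = 0.37))))
  expect_equal(unname(many), qlogis(0.37), tolerance = 1e-12)
  expect_error(average_and_logit(list(mk(c(a = .1)), mk(c(b = .1)))),
               "different patient sets")
})

test_that("compute_caliper follows the SD formula, linearly in multiplier", {
  s <- c(-1, 1)
  expect_equal(compute_caliper(s, 0.05), 0.05 * sqrt(2), tolerance = 1e-9)
  expect_equal(compute_caliper(s, 0.05), 0.070711, tolerance = 1e-5)
  expect_equal(compute_caliper(s, 0.01), compute_caliper(s, 0.05) / 5,
               tolerance = 1e-12)
  expect_warning(w <- compute_caliper(c(2, 2, 2), 0.05), "zero variance")
  expect_equal(w, 0)
})

test_that("greedy caliper matching handles the worked examples", {
  # one treated at 0.0, controls at 0.1 and 0.5, caliper 0.2
  scores <- c(t1 = 0.0, c1 = 0.1, c2 = 0.5)
  arms <- c("BLM", "BL", "BL")
  m <- match_caliper(scores, arms, 0.2)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$control_id, "c1")
  # caliper 0 with no exact ties: zero pairs, all treated unmatched
  m0 <- match_caliper(scores, arms, 0)
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(m0$unmatched_treated, "t1")
  # every emitted pair respects the caliper; ids used at most once
  set.seed(1)
  sc <- stats::setNames(rnorm(40), sprintf("p%02d", 1:40))
  ar <- rep(c("BLM", "BL"), each = 20)
  mm <- match_caliper(sc, ar, 0.3)
  expect_true(all(abs(mm$pairs$score_t - mm$pairs$score_c) <= 0.3))
  expect_false(anyDuplicated(c(mm$pairs$treated_id,
                               mm$pairs$control_id)) > 0)
})

test_that("matching equals the brute-force greedy oracle and shift-invariance", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    scores <- stats::setNames(round(rnorm(n), 2), sprintf("u%02d", 1:n))
    arms <- ifelse(runif(n) < 0.4, "BLM", "BL")
    cal <- runif(1, 0, 1.5)
    got <- match_caliper(scores, arms, cal)
    want <- oracle_greedy_match(scores, arms, cal)
    expect_equal(got$pairs$treated_id, want$treated)
    expect_equal(got$pairs$control_id, want$control)
    shifted <- match_caliper(scores + 5, arms, cal)
    expect_equal(shifted$pairs$treated_id, got$pairs$treated_id)
    expect_equal(shifted$pairs$control_id, got$pairs$control_id)
  }
})

test_that("compute_smd matches hand formulas for each kind", {
  expect_equal(compute_smd(c(1, 2, 3), c(1, 2, 3), "continuous"), 0)
  x1 <- c(rep(1, 6), rep(0, 4)); x0 <- c(rep(1, 4), rep(0, 6))
  expect_equal(compute_smd(x1, x0, "binary"), 0.2 / sqrt(0.24),
               tolerance = 1e-9)
  expect_equal(compute_smd(x1, x0, "binary"), 0.40825, tolerance = 1e-5)
  # exact hand case: means 1 and 0, equal SDs
  xa <- c(0, 1, 2); xb <- c(-1, 0, 1)
  expect_equal(compute_smd(xa, xb, "continuous"), 1.0, tolerance = 1e-12)
  set.seed(2)
  a <- rnorm(20000, 1, 1); b <- rnorm(20000, 0, 1)
  expect_equal(compute_smd(a, b, "continuous"), 1.0, tolerance = 0.05)
  # zero pooled variance: 0 when equal, Inf when not
  expect_equal(compute_smd(c(2, 2), c(2, 2), "continuous"), 0)
  expect_equal(compute_smd(c(2, 2), c(3, 3), "continuous"), Inf)
  # categorical: two levels reduces to the binary formula
  g1 <- rep(c("x", "y"), c(6, 4)); g0 <- rep(c("x", "y"), c(4, 6))
  expect_equal(compute_smd(g1, g0, "categorical", levels = c("x", "y")),
               0.2 / sqrt(0.24), tolerance = 1e-9)
})

test_that("balance improves after matching on a confounded cohort", {
  sim <- simulate_cohort(simulation_config(n = 3000, seed = 44,
                                           miss_probs = list()))
  co <- sim$cohort
  fit <- fit_propensity(co)
  sc <- qlogis(fit$scores)
  m <- match_caliper(sc, co$arm, compute_caliper(sc, 0.05))
  b <- balance_table(co, m)
  expect_equal(nrow(b), 34)
  expect_gt(sum(b$balanced_after), sum(b$balanced_before))
  expect_lt(mean(b$smd_after), mean(b$smd_before))
  # empty match: after column undefined
  b0 <- balance_table(co, match_caliper(sc, co$arm, 0))
  expect_true(all(is.na(b0$smd_after)))
})
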