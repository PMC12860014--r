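# fixtures built in code: a miniature 3-covariate schema for hand-checkable
# cases, a generator-backed cohort for realistic cases, and an independent
# brute-force greedy matching oracle

mini_spec <- function() {
  spec <- data.frame(
    name = c("age", "female", "hospital"),
    kind = c("continuous", "binary", "categorical"),
    unit = c("years", "", ""),
    in_propensity_model = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  spec$levels <- list(character(0), character(0), c("site_A", "site_B"))
  spec
}

mini_cohort <- function(age = c(60, 70, 55, 80),
                        arm = c("BLM", "BLM", "BL", "BL"),
                        outcome = c("recovery", "death", "recovery",
                                    "stable")) {
  n <- length(age)
  cohort_table(data.frame(
    id = sprintf("M%02d", seq_len(n)),
    arm = arm,
    age = age,
    female = rep_len(c(0, 1), n),
    hospital = rep_len(c("site_A", "site_B"), n),
    outcome = outcome,
    obs_days = rep(10, n),
    los_days = rep(10, n),
    abx_days = rep(7, n),
    stringsAsFactors = FALSE
  ), spec = mini_spec())
}

sim_cohort <- function(n = 300, seed = 1, ...) {
  simulate_cohort(simulation_config(n = n, seed = seed, ...))
}

# Independent re-derivation of greedy nearest-neighbor caliper matching:
# treated in descending score order (ties by id), each scans every control
# by brute force, ties on |delta| broken by the smaller control id.
oracle_greedy_match <- function(scores, arms, caliper) {
  ids <- names(scores)
  treated <- ids[arms == "BLM"]
  controls <- ids[arms == "BL"]
  treated <- treated[order(-scores[treated], treated)]
  used <- character(0)
  pairs <- list()
  for (t_id in treated) {
    best <- NULL; best_d <- Inf
    for (c_id in sort(setdiff(controls, used))) {
      d <- abs(scores[t_id] - scores[c_id])
      if (d < best_d) {
        best <- c_id; best_d <- d
      }
    }
    if (!is.null(best) && best_d <= caliper) {
      used <- c(used, best)
      pairs[[length(pairs) + 1]] <- c(treated = t_id, control = best)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(treated = character(0), control = character(0)))
  }
  as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
}
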