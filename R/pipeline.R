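# configuration-driven orchestration: generate/load -> impute -> match ->
# analyze -> report, with counter-derived seeds and plain CSV/JSON artifacts

#' Pipeline run configuration
#'
#' Exactly one input source: a cohort CSV (`cohort_path`) or a generator
#' configuration (`sim_config`). Defaults reproduce the registry analysis
#' settings (m = 50 imputations x 5 iterations, B = 1000 bootstrap
#' replicates, caliper 0.05 x SD of the logit-averaged propensity score,
#' SMD balance threshold 0.1); `fast = TRUE` switches to the test profile
#' (m = 5, B = 50).
#'
#' @param out_dir artifact directory.
#' @param cohort_path input cohort CSV (or NULL).
#' @param sim_config a [simulation_config()] (or NULL).
#' @param seed master seed; all stage seeds derive from it.
#' @param m,iterations,B imputation and bootstrap sizes.
#' @param caliper_multiplier 0.05 (main) or 0.01 (sensitivity).
#' @param covariates propensity covariates (default: registry set).
#' @param analyses subset of c("main", "severe", "micro", "complete_case").
#' @param cif_curve whether to emit the cumulative-incidence CSV.
#' @param fast use the reduced test profile.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort_path = NULL,
                       sim_config = NULL,
                       seed = 1L,
                       m = 50L, iterations = 5L, B = 1000L,
                       caliper_multiplier = 0.05,
                       covariates = NULL,
                       analyses = "main",
                       cif_curve = TRUE,
                       fast = FALSE) {
  if (is.null(cohort_path) == is.null(sim_config)) {
    stop("exactly one input source: cohort_path or sim_config")
  }
  stopifnot(caliper_multiplier > 0)
  if (fast) {
    m <- min(m, 5L)
    B <- min(B, 50L)
  }
  structure(list(out_dir = out_dir, cohort_path = cohort_path,
                 sim_config = sim_config, seed = as.integer(seed),
                 m = as.integer(m), iterations = as.integer(iterations),
                 B = as.integer(B),
                 caliper_multiplier = caliper_multiplier,
                 covariates = covariates, analyses = analyses,
                 cif_curve = cif_curve),
            class = "run_config")
}

# reference analysis: propensity fit per imputed dataset, probability-scale
# averaging, logit transform, one caliper match; balance and endpoints from
# the first imputed dataset (outcomes are never missing, so the panel is
# identical across datasets given the matched pairs)
matched_reference <- function(imputed, covariates = NULL,
                              caliper_multiplier = 0.05) {
  fits <- lapply(seq_along(imputed$datasets), function(i) {
    fit_propensity(imputed$datasets[[i]], covariates,
                   fitted_on = sprintf("imputed_%03d", i))
  })
  scores <- average_and_logit(fits)
  caliper <- compute_caliper(scores, caliper_multiplier)
  d1 <- imputed$datasets[[1]]
  match <- match_caliper(scores, d1$arm, caliper)
  balance <- balance_table(d1, match, covariates)
  panel <- if (nrow(match$pairs) > 0) endpoint_panel(d1, match) else NULL
  list(fits = fits, scores = scores, caliper = caliper, match = match,
       balance = balance, panel = panel)
}

as_single_imputed <- function(dataset) {
  structure(list(datasets = list(dataset),
                 provenance = list(config = NULL, chain_seeds = integer(0),
                                   imputed_cells = list())),
            class = "imputed_cohorts")
}

run_one_analysis <- function(label, datasets, config, boot_seed) {
  usable <- Filter(function(d) {
    nrow(d) > 0 && any(d$arm == "BLM") && any(d$arm == "BL")
  }, datasets)
  if (length(usable) == 0) {
    log_msg("analysis '", label, "': empty or single-arm in all datasets; skipped")
    return(NULL)
  }
  imp <- structure(list(datasets = usable, provenance = list()),
                   class = "imputed_cohorts")
  ref <- matched_reference(imp, config$covariates, config$caliper_multiplier)
  boot <- mi_boot(imp,
                  boot_config(B = config$B, seed = boot_seed),
                  covariates = config$covariates,
                  caliper_multiplier = config$caliper_multiplier)
  list(label = label, reference = ref, boot = boot)
}

write_analysis_artifacts <- function(res, out_dir) {
  if (is.null(res)) return(invisible(NULL))
  lb <- res$label
  utils::write.csv(res$reference$balance,
                   file.path(out_dir, sprintf("balance_%s.csv", lb)),
                   row.names = FALSE)
  utils::write.csv(res$reference$match$pairs,
                   file.path(out_dir, sprintf("pairs_%s.csv", lb)),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$boot$pooled$estimates),
                   file.path(out_dir, sprintf("pooled_%s.csv", lb)),
                   row.names = FALSE)
  summ <- res$boot$summary
  records <- lapply(seq_len(nrow(summ)), function(i) {
    list(point = summ$point[i], lower = summ$lower[i], upper = summ$upper[i],
         n_valid = res$boot$pooled$n_valid,
         n_invalid = res$boot$pooled$n_invalid)
  })
  names(records) <- summ$endpoint
  jsonlite::write_json(
    list(analysis = lb,
         caliper_width = res$reference$caliper,
         reference_matched_n = nrow(res$reference$match$pairs),
         endpoints = records),
    file.path(out_dir, sprintf("endpoints_%s.json", lb)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Generate or load the cohort, impute, run the requested matched analyses
#' (main, CURB-65 >= 3 subgroup, microbiologically confirmed subgroup,
#' complete-case sensitivity), and write every stage artifact as plain
#' CSV/JSON under `config$out_dir` before the next stage starts. Identical
#' config + seed gives a byte-identical endpoint JSON.
#'
#' @param config a [run_config()].
#' @return a `run_report` list (see [build_report()]).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_msg(sprintf("stage %-12s %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  cohort <- stage("input", {
    if (!is.null(config$sim_config)) {
      sc <- config$sim_config
      sc$seed <- sub_seed(config$seed, 100L)
      sim <- simulate_cohort(sc)
      write_cohort(sim$cohort, file.path(config$out_dir, "cohort.csv"))
      utils::write.csv(sim$truth, file.path(config$out_dir, "truth.csv"),
                       row.names = FALSE)
      sim$cohort
    } else {
      load_cohort(config$cohort_path)
    }
  })
  validate_cohort(as.data.frame(cohort), attr(cohort, "covariate_spec"),
                  check_arms = TRUE)

  imputed <- stage("impute", {
    imp <- impute_chained(cohort,
                          imputation_config(m = config$m,
                                            iterations = config$iterations,
                                            seed = sub_seed(config$seed, 200L)))
    write_imputed(imp, file.path(config$out_dir, "imputed"))
    imp
  })

  results <- list()
  if ("main" %in% config$analyses) {
    results$main <- stage("main", run_one_analysis(
      "main", imputed$datasets, config, sub_seed(config$seed, 300L)))
    write_analysis_artifacts(results$main, config$out_dir)
  }
  if ("severe" %in% config$analyses) {
    results$severe <- stage("severe", run_one_analysis(
      "severe", lapply(imputed$datasets, filter_severe), config,
      sub_seed(config$seed, 301L)))
    write_analysis_artifacts(results$severe, config$out_dir)
  }
  if ("micro" %in% config$analyses) {
    results$micro <- stage("micro", run_one_analysis(
      "micro", lapply(imputed$datasets, filter_micro_confirmed), config,
      sub_seed(config$seed, 302L)))
    write_analysis_artifacts(results$micro, config$out_dir)
  }
  if ("complete_case" %in% config$analyses) {
    results$complete_case <- stage("complete_case", run_one_analysis(
      "complete_case", list(filter_complete_case(cohort)), config,
      sub_seed(config$seed, 303L)))
    write_analysis_artifacts(results$complete_case, config$out_dir)
  }

  if (config$cif_curve && !is.null(results$main)) {
    stage("cif", {
      mids <- c(results$main$reference$match$pairs$treated_id,
                results$main$reference$match$pairs$control_id)
      d1 <- imputed$datasets[[1]]
      cif <- cif_by_arm(d1[d1$id %in% mids, , drop = FALSE])
      utils::write.csv(cif, file.path(config$out_dir, "cif_main.csv"),
                       row.names = FALSE)
    })
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("capmatch")),
    master_seed = config$seed,
    m = config$m, iterations = config$iterations, B = config$B,
    caliper_multiplier = config$caliper_multiplier,
    analyses = config$analyses,
    invalid_replicates = lapply(results, function(r)
      if (is.null(r)) NULL else r$boot$pooled$n_invalid)
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(config = config, results = results,
                 out_dir = config$out_dir), class = "run_report")
}

#' Rebuild the human-readable report from stage artifacts
#'
#' Reads the artifacts a [run_pipeline()] call left under `out_dir` and
#' assembles balance tables, endpoint tables, the CIF curve, and the
#' provenance block. Regeneration is idempotent; a missing artifact raises
#' an error naming it.
#'
#' @param out_dir the artifact directory.
#' @return a list with `balance`, `endpoints`, `cif`, `provenance`.
#' @export
build_report <- function(out_dir) {
  need <- file.path(out_dir, "provenance.json")
  if (!file.exists(need)) stop("missing artifact: ", need)
  prov <- jsonlite::read_json(need)
  labels <- names(prov$invalid_replicates)
  balance <- list(); endpoints <- list()
  for (lb in labels) {
    bpath <- file.path(out_dir, sprintf("balance_%s.csv", lb))
    epath <- file.path(out_dir, sprintf("endpoints_%s.json", lb))
    for (p in c(bpath, epath)) {
      if (!file.exists(p)) stop("missing artifact: ", p)
    }
    balance[[lb]] <- utils::read.csv(bpath)
    endpoints[[lb]] <- jsonlite::read_json(epath)
  }
  cif_path <- file.path(out_dir, "cif_main.csv")
  cif <- if (file.exists(cif_path)) utils::read.csv(cif_path) else NULL
  list(balance = balance, endpoints = endpoints, cif = cif,
       provenance = prov)
}
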