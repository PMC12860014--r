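# multiple imputation by chained equations: Bayesian linear regression with
# predictive mean matching for continuous targets, logistic draws for binary
# targets, one-vs-rest logistic for categorical targets

#' Imputation configuration
#'
#' Defaults follow the registry analysis: m = 50 completed datasets, five
#' chained-equation sweeps each, predictive-mean-matching donor pool of 5.
#'
#' @param m number of imputed datasets.
#' @param iterations chained-equation sweeps per dataset.
#' @param pmm_donors donor-pool size for predictive mean matching.
#' @param seed master seed; each chain gets a counter-derived sub-seed.
#' @return an `imputation_config` list.
#' @export
imputation_config <- function(m = 50L, iterations = 5L, pmm_donors = 5L,
                              seed = 1L) {
  stopifnot(m >= 1, iterations >= 1, pmm_donors >= 1)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 pmm_donors = as.integer(pmm_donors),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Warm-start fill of missing cells
#'
#' Every missing cell is replaced by a uniform random draw from that
#' variable's observed values (the standard chained-equations starting
#' point). A fully missing variable cannot be imputed and raises an error
#' instructing its exclusion.
#'
#' @param cohort a cohort table.
#' @param seed integer seed.
#' @return a complete cohort table.
#' @export
initialize_fill <- function(cohort, seed = 1L) {
  spec <- attr(cohort, "covariate_spec")
  set.seed(seed)
  for (nm in spec$name) {
    miss <- is.na(cohort[[nm]])
    if (!any(miss)) next
    obs <- cohort[[nm]][!miss]
    if (length(obs) == 0) {
      stop("variable '", nm, "' has no observed values; ",
           "exclude it before imputation")
    }
    cohort[[nm]][miss] <- sample(obs, sum(miss), replace = TRUE)
  }
  cohort
}

#' Predictive mean matching draw
#'
#' Returns the observed value attached to one of the `k` observed
#' predictions nearest to `target_prediction`, chosen uniformly. Imputed
#' values therefore always lie in the observed support. `k` larger than the
#' donor pool is clamped (with a warning).
#'
#' @param target_prediction predicted value for the missing cell.
#' @param obs_pred predictions for the observed cells.
#' @param obs_value observed values aligned with `obs_pred`.
#' @param k donor count.
#' @return one imputed value.
#' @export
pmm_draw <- function(target_prediction, obs_pred, obs_value, k = 5L) {
  stopifnot(length(obs_pred) == length(obs_value), length(obs_pred) >= 1)
  if (k > length(obs_pred)) {
    warning("pmm donor count clamped from ", k, " to ", length(obs_pred))
    k <- length(obs_pred)
  }
  d <- abs(obs_pred - target_prediction)
  donors <- order(d)[seq_len(k)]
  obs_value[donors[sample.int(k, 1L)]]
}

# Bayesian linear regression draw + PMM for one continuous target.
# Type-1 matching: observed predictions use the ML coefficients, missing
# predictions use the posterior draw.
impute_continuous <- function(y, X, miss, k) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  A <- crossprod(Xo)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {           # singular design: ridge fallback, logged
    message("impute_continuous: singular design, ridge fallback (1e-4)")
    A <- A + diag(1e-4, ncol(Xo))
    R <- chol(A)
  }
  XtXinv <- chol2inv(R)
  beta_hat <- drop(XtXinv %*% crossprod(Xo, yo))
  resid <- yo - drop(Xo %*% beta_hat)
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  L <- tryCatch(chol(XtXinv), error = function(e) NULL)
  beta_star <- if (is.null(L)) beta_hat else {
    beta_hat + sqrt(sigma2) * drop(t(L) %*% stats::rnorm(ncol(Xo)))
  }
  pred_obs <- drop(Xo %*% beta_hat)
  pred_mis <- drop(X[miss, , drop = FALSE] %*% beta_star)
  vapply(pred_mis, function(tp) pmm_draw(tp, pred_obs, yo, k), numeric(1))
}

# logistic draw for one binary target: posterior-approximate coefficient
# draw, then a Bernoulli draw from the predictive probability
impute_binary <- function(y, X, miss) {
  fit <- fit_logit(X[!miss, , drop = FALSE], y[!miss])
  L <- tryCatch(chol(fit$vcov), error = function(e) NULL)
  beta_star <- if (is.null(L)) fit$coef else {
    fit$coef + drop(t(L) %*% stats::rnorm(length(fit$coef)))
  }
  p_mis <- stats::plogis(drop(X[miss, , drop = FALSE] %*% beta_star))
  as.numeric(stats::runif(sum(miss)) < p_mis)
}

# one-vs-rest logistic with normalized predictive probabilities
impute_categorical <- function(y, X, miss, levels) {
  present <- levels[levels %in% y[!miss]]
  if (length(present) == 1) return(rep(present, sum(miss)))
  scores <- matrix(0, sum(miss), length(present))
  for (j in seq_along(present)) {
    yj <- as.numeric(y[!miss] == present[j])
    fit <- fit_logit(X[!miss, , drop = FALSE], yj)
    scores[, j] <- stats::plogis(drop(X[miss, , drop = FALSE] %*% fit$coef))
  }
  probs <- scores / rowSums(scores)
  idx <- apply(probs, 1, function(p) sample.int(length(present), 1, prob = p))
  present[idx]
}

# imputation-model design for one target: all other covariates + arm +
# outcome indicators (the analysis variables enter the imputation model)
imputation_design <- function(data, target, spec) {
  others <- setdiff(spec$name, target)
  X <- build_design(data, others, spec)
  X <- cbind(X, arm_BLM = as.numeric(data$arm == "BLM"))
  for (lv in OUTCOME_LEVELS[-1]) {
    X <- cbind(X, as.numeric(data$outcome == lv))
    colnames(X)[ncol(X)] <- paste0("outcome=", lv)
  }
  # standardize predictors: wildly scaled columns (e.g. CFU counts) would
  # wreck the cross-product conditioning; predictions are scale-invariant
  keep <- rep(TRUE, ncol(X))
  for (j in 2:ncol(X)) {
    s <- stats::sd(X[, j])
    if (s == 0 || !is.finite(s)) {
      keep[j] <- FALSE
    } else {
      X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  X[, keep, drop = FALSE]
}

#' Multiple imputation by chained equations
#'
#' Runs `m` independent chains. Each chain warm-starts with
#' [initialize_fill()] and then sweeps the variables with missing cells in
#' schema order for `iterations` rounds: continuous targets by Bayesian
#' linear regression with predictive mean matching, binary targets by a
#' logistic coefficient draw plus Bernoulli draw, categorical targets by
#' one-vs-rest logistic with normalized probabilities. Predictors are all
#' other covariates plus the treatment arm and outcome indicators. Singular
#' designs fall back to a ridge penalty (lambda = 1e-4), never silently.
#'
#' @param cohort a cohort table (may contain missing covariate cells).
#' @param config an [imputation_config()].
#' @return an `imputed_cohorts` object: list with `datasets` (m complete
#'   cohort tables, identical on originally observed cells) and `provenance`
#'   (config, chain seeds, imputed-cell map).
#' @export
impute_chained <- function(cohort, config = imputation_config()) {
  spec <- attr(cohort, "covariate_spec")
  miss_map <- lapply(stats::setNames(spec$name, spec$name),
                     function(nm) which(is.na(cohort[[nm]])))
  targets <- names(miss_map)[vapply(miss_map, length, 0L) > 0]
  chain_seeds <- vapply(seq_len(config$m),
                        function(i) sub_seed(config$seed, 10L, i), 0L)
  datasets <- vector("list", config$m)
  for (chain in seq_len(config$m)) {
    set.seed(chain_seeds[chain])
    data <- initialize_fill(cohort, seed = chain_seeds[chain])
    if (length(targets)) {
      for (iter in seq_len(config$iterations)) {
        for (nm in targets) {
          miss <- logical(nrow(data))
          miss[miss_map[[nm]]] <- TRUE
          X <- imputation_design(data, nm, spec)
          kind <- spec$kind[spec$name == nm]
          data[[nm]][miss] <- switch(kind,
            continuous = impute_continuous(as.numeric(data[[nm]]), X, miss,
                                           config$pmm_donors),
            binary = impute_binary(as.numeric(data[[nm]]), X, miss),
            categorical = impute_categorical(
              data[[nm]], X, miss, spec$levels[[which(spec$name == nm)]]))
        }
      }
    }
    datasets[[chain]] <- data
  }
  structure(list(datasets = datasets,
                 provenance = list(config = config,
                                   chain_seeds = chain_seeds,
                                   imputed_cells = miss_map[targets])),
            class = "imputed_cohorts")
}

#' @export
print.imputed_cohorts <- function(x, ...) {
  n_cells <- sum(vapply(x$provenance$imputed_cells, length, 0L))
  cat(sprintf("<imputed_cohorts> m = %d datasets, %d imputed cells each\n",
              length(x$datasets), n_cells))
  invisible(x)
}

#' Serialize imputed datasets as CSVs plus a provenance manifest
#'
#' @param imputed an `imputed_cohorts` object.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_imputed <- function(imputed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(imputed$datasets))
  for (i in seq_along(imputed$datasets)) {
    paths[i] <- file.path(dir, sprintf("imputed_%03d.csv", i))
    write_cohort(imputed$datasets[[i]], paths[i])
  }
  manifest <- list(
    m = length(imputed$datasets),
    iterations = imputed$provenance$config$iterations,
    pmm_donors = imputed$provenance$config$pmm_donors,
    seed = imputed$provenance$config$seed,
    chain_seeds = imputed$provenance$chain_seeds,
    files = basename(paths),
    imputed_cells = imputed$provenance$imputed_cells
  )
  mpath <- file.path(dir, "imputation_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
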