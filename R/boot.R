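# bootstrap-within-multiple-imputation inference ("MI Boot, pooled sample"):
# B bootstrap replicates per imputed dataset, full re-estimation
# (propensity fit -> caliper -> match -> endpoints) inside each replicate,
# all replicate estimates pooled into one distribution, percentile CIs and
# pooled-median point estimates

#' Bootstrap configuration
#'
#' @param B bootstrap replicates per imputed dataset (registry default
#'   1000).
#' @param seed master seed; each (dataset, replicate) stream is
#'   counter-derived.
#' @param min_valid_fraction abort threshold: pooling stops with an error if
#'   fewer than this fraction of replicates are usable.
#' @return a `boot_config` list.
#' @export
boot_config <- function(B = 1000L, seed = 1L, min_valid_fraction = 0.5) {
  stopifnot(B >= 1)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 min_valid_fraction = min_valid_fraction),
            class = "boot_config")
}

#' One bootstrap replicate of the full matched analysis
#'
#' Resamples n rows with replacement (unstratified, so the matched n varies
#' across replicates), refits the propensity model on the replicate,
#' recomputes the caliper from the replicate's logit scores, matches, and
#' evaluates the endpoint panel. Degenerate replicates (single arm, zero
#' matched pairs) return an invalid marker with a reason, never an error.
#'
#' @param data one complete (imputed) cohort table.
#' @param seed integer seed for the resample.
#' @param covariates propensity covariates.
#' @param caliper_multiplier caliper multiplier (0.05 default).
#' @return list with `valid`, `reason`, and (when valid) `estimates` --
#'   the [panel_to_vector()] of the replicate.
#' @export
bootstrap_replicate <- function(data, seed, covariates = NULL,
                                caliper_multiplier = 0.05) {
  set.seed(seed)
  idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
  rep_data <- data[idx, , drop = FALSE]
  # resampling duplicates rows; re-key ids so matching stays 1:1 on draws
  rep_data$id <- sprintf("%s#%d", rep_data$id, seq_along(idx))
  attr(rep_data, "covariate_spec") <- attr(data, "covariate_spec")
  class(rep_data) <- class(data)
  if (length(unique(rep_data$arm)) < 2) {
    return(list(valid = FALSE, reason = "single arm"))
  }
  fit <- tryCatch(fit_propensity(rep_data, covariates),
                  error = function(e) NULL)
  if (is.null(fit)) return(list(valid = FALSE, reason = "propensity fit failed"))
  scores <- stats::qlogis(fit$scores)
  cal <- suppressWarnings(compute_caliper(scores, caliper_multiplier))
  match <- match_caliper(scores, rep_data$arm, cal)
  if (nrow(match$pairs) == 0) {
    return(list(valid = FALSE, reason = "zero matched pairs"))
  }
  panel <- endpoint_panel(rep_data, match)
  list(valid = TRUE, reason = NA_character_,
       estimates = panel_to_vector(panel))
}

#' Pool replicate estimates across imputed datasets
#'
#' Concatenates valid replicate estimates from all m datasets into one
#' distribution per endpoint; invalid replicates are dropped and counted by
#' reason. Errors when nothing is valid or the valid fraction falls below
#' `min_valid_fraction`.
#'
#' @param replicates list of [bootstrap_replicate()] results.
#' @param min_valid_fraction abort threshold.
#' @return a `pooled_distribution`: list with `estimates` (matrix, one
#'   column per endpoint), `n_valid`, `n_invalid`, `invalid_reasons`.
#' @export
pool_estimates <- function(replicates, min_valid_fraction = 0.5) {
  valid <- vapply(replicates, function(r) isTRUE(r$valid), TRUE)
  if (!any(valid)) stop("no valid bootstrap replicates")
  frac <- mean(valid)
  if (frac < min_valid_fraction) {
    stop(sprintf("only %.1f%% of replicates valid (< %.0f%% threshold)",
                 100 * frac, 100 * min_valid_fraction))
  }
  est <- do.call(rbind, lapply(replicates[valid], function(r) r$estimates))
  reasons <- table(vapply(replicates[!valid], function(r) r$reason, ""))
  structure(list(estimates = est,
                 n_valid = sum(valid), n_invalid = sum(!valid),
                 invalid_reasons = as.list(reasons)),
            class = "pooled_distribution")
}

#' Percentile confidence interval (type-7 order statistics)
#'
#' Linear-interpolation percentiles at `(1 - level)/2` and
#' `1 - (1 - level)/2` of the pooled distribution.
#'
#' @param x numeric vector of pooled replicate estimates.
#' @param level confidence level.
#' @return named vector `c(lower, upper)`.
#' @export
percentile_ci <- function(x, level = 0.95) {
  stopifnot(length(x) >= 1)
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(alpha, 1 - alpha), type = 7, names = FALSE,
                       na.rm = TRUE)
  c(lower = q[1], upper = q[2])
}

#' Pooled point estimate (median of the bootstrap distribution)
#'
#' @param x numeric vector of pooled replicate estimates.
#' @return the type-7 interpolated median.
#' @export
point_estimate <- function(x) {
  stopifnot(length(x) >= 1)
  unname(stats::quantile(x, probs = 0.5, type = 7, names = FALSE,
                         na.rm = TRUE))
}

#' Bootstrap-within-MI endpoint inference
#'
#' Runs `B` bootstrap replicates inside each of the m imputed datasets,
#' pools everything, and summarises each endpoint as the pooled median with
#' a percentile 95% CI. Endpoint cells that are undefined in a replicate
#' (e.g. hospital stay with no matched inpatients) are dropped per endpoint.
#'
#' @param imputed an `imputed_cohorts` object.
#' @param config a [boot_config()].
#' @param covariates propensity covariates.
#' @param caliper_multiplier caliper multiplier.
#' @param level confidence level.
#' @return an `mi_boot_result`: list with `summary` (data frame: endpoint,
#'   point, lower, upper, n_used), `pooled` (the pooled distribution), and
#'   `config`.
#' @export
mi_boot <- function(imputed, config = boot_config(),
                    covariates = NULL, caliper_multiplier = 0.05,
                    level = 0.95) {
  reps <- vector("list", length(imputed$datasets) * config$B)
  k <- 0L
  for (d in seq_along(imputed$datasets)) {
    data <- imputed$datasets[[d]]
    for (b in seq_len(config$B)) {
      k <- k + 1L
      reps[[k]] <- bootstrap_replicate(
        data, seed = sub_seed(config$seed, 20L + d, b),
        covariates = covariates,
        caliper_multiplier = caliper_multiplier)
    }
  }
  pooled <- pool_estimates(reps, config$min_valid_fraction)
  ep <- colnames(pooled$estimates)
  summ <- do.call(rbind, lapply(ep, function(e) {
    x <- pooled$estimates[, e]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      return(data.frame(endpoint = e, point = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_used = 0L))
    }
    ci <- percentile_ci(x, level)
    data.frame(endpoint = e, point = point_estimate(x),
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               n_used = length(x), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, pooled = pooled, config = config),
            class = "mi_boot_result")
}

#' @export
print.mi_boot_result <- function(x, ...) {
  cat(sprintf("<mi_boot_result> %d valid / %d invalid replicates\n",
              x$pooled$n_valid, x$pooled$n_invalid))
  print(transform(x$summary,
                  point = round(point, 3), lower = round(lower, 3),
                  upper = round(upper, 3)), row.names = FALSE)
  invisible(x)
}
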