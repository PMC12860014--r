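# propensity-score estimation, cross-imputation averaging, greedy 1:1
# caliper matching without replacement, SMD balance diagnostics

#' Fit the propensity model
#'
#' Maximum-likelihood logistic regression of treatment arm (BLM vs BL) on
#' the propensity covariates; categoricals are dummy-coded against their
#' first declared level. Perfect separation triggers a ridge fallback
#' (lambda = 1e-4), flagged in the result. Fitted probabilities are clipped
#' to [1e-6, 1 - 1e-6] so later logits stay finite.
#'
#' @param data a complete cohort table with both arms present.
#' @param covariates covariate names; defaults to the registry's propensity
#'   set (34 variables).
#' @return a `propensity_fit`: list with `coefficients`, `scores` (named by
#'   patient id), `fitted_on`, `ridge_used`.
#' @export
fit_propensity <- function(data, covariates = NULL, fitted_on = "cohort") {
  spec <- attr(data, "covariate_spec")
  if (is.null(covariates)) covariates <- ps_covariates(spec)
  if (anyNA(data[, covariates, drop = FALSE])) {
    stop("propensity model requires complete covariates (impute first)")
  }
  if (!any(data$arm == "BLM") || !any(data$arm == "BL")) {
    stop("both arms must be present to fit a propensity model")
  }
  X <- build_design(data, covariates, spec)
  y <- as.numeric(data$arm == "BLM")
  fit <- fit_logit(X, y)
  scores <- pmin(pmax(fit$fitted, 1e-6), 1 - 1e-6)
  structure(list(coefficients = stats::setNames(fit$coef, colnames(X)),
                 scores = stats::setNames(scores, data$id),
                 fitted_on = fitted_on, ridge_used = fit$ridge_used),
            class = "propensity_fit")
}

#' Average propensity scores across imputed datasets, then logit
#'
#' The matching score is `logit(mean over the m datasets of PS_i)`:
#' averaging happens on the probability scale, the logit transform after.
#'
#' @param fits list of `propensity_fit` objects covering identical patients.
#' @return named numeric vector of logit-scale matching scores.
#' @export
average_and_logit <- function(fits) {
  stopifnot(length(fits) >= 1)
  ids <- names(fits[[1]]$scores)
  for (f in fits[-1]) {
    if (!identical(names(f$scores), ids)) {
      stop("propensity fits cover different patient sets")
    }
  }
  mat <- vapply(fits, function(f) f$scores, numeric(length(ids)))
  if (length(ids) == 1) mat <- matrix(mat, nrow = 1)
  stats::setNames(stats::qlogis(rowMeans(mat)), ids)
}

#' Caliper width from the matching-score spread
#'
#' `multiplier` times the sample standard deviation (n - 1 denominator) of
#' the logit-scale matching scores over all patients. The registry analysis
#' used 0.05; its sensitivity analysis 0.01.
#'
#' @param scores logit-scale matching scores (all patients).
#' @param multiplier caliper multiplier.
#' @return caliper width (same scale as the scores).
#' @export
compute_caliper <- function(scores, multiplier = 0.05) {
  stopifnot(length(scores) >= 2, multiplier >= 0)
  s <- stats::sd(scores)
  if (s == 0) {
    warning("matching scores have zero variance; caliper width 0")
    return(0)
  }
  multiplier * s
}

#' Greedy 1:1 caliper matching without replacement
#'
#' Treated patients are processed in descending score order (ties by id);
#' each takes the still-unmatched control minimizing |score difference|,
#' with ties broken by the smaller control id, and is left unmatched when
#' that minimum exceeds the caliper.
#'
#' @param scores named (by patient id) matching scores.
#' @param arms arm labels aligned with `scores`.
#' @param caliper nonnegative caliper width.
#' @return a `match_result`: list with `pairs` (data frame of treated_id,
#'   control_id, score_t, score_c), `caliper_width`, `unmatched_treated`,
#'   `score_used`.
#' @export
match_caliper <- function(scores, arms, caliper) {
  stopifnot(caliper >= 0, length(scores) == length(arms))
  ids <- names(scores)
  t_idx <- which(arms == "BLM")
  c_idx <- which(arms == "BL")
  ord <- t_idx[order(-scores[t_idx], ids[t_idx])]
  c_ord <- c_idx[order(ids[c_idx])]   # id order makes ties pick smaller id
  c_scores <- scores[c_ord]
  c_ids <- ids[c_ord]
  free <- rep(TRUE, length(c_ord))
  pairs_t <- character(0); pairs_c <- character(0)
  st <- numeric(0); sc <- numeric(0)
  unmatched <- character(0)
  for (ti in ord) {
    if (!any(free)) {
      unmatched <- c(unmatched, ids[ti])
      next
    }
    d <- abs(c_scores - scores[ti])
    d[!free] <- Inf
    j <- which.min(d)               # first minimum = smallest control id
    if (d[j] <= caliper) {
      free[j] <- FALSE
      pairs_t <- c(pairs_t, ids[ti]); pairs_c <- c(pairs_c, c_ids[j])
      st <- c(st, unname(scores[ti])); sc <- c(sc, unname(c_scores[j]))
    } else {
      unmatched <- c(unmatched, ids[ti])
    }
  }
  structure(list(
    pairs = data.frame(treated_id = pairs_t, control_id = pairs_c,
                       score_t = st, score_c = sc,
                       stringsAsFactors = FALSE),
    caliper_width = caliper,
    unmatched_treated = unmatched,
    score_used = scores), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d unmatched treated, caliper %.4g\n",
              nrow(x$pairs), length(x$unmatched_treated), x$caliper_width))
  invisible(x)
}

#' Standardized mean difference
#'
#' Continuous: `|m1 - m0| / sqrt((s1^2 + s0^2) / 2)`. Binary:
#' `|p1 - p0| / sqrt((p1 (1 - p1) + p0 (1 - p0)) / 2)`. Categorical with K
#' levels: the Mahalanobis-type `sqrt(T' S^-1 T)` where T is the
#' (K - 1)-vector of proportion differences and S the average of the two
#' multinomial covariance matrices. Zero pooled variance yields 0 for equal
#' means and +Inf otherwise.
#'
#' @param x1,x0 values in the two groups (BLM, BL).
#' @param kind "continuous", "binary", or "categorical".
#' @param levels declared levels (categorical only).
#' @return a nonnegative scalar (possibly Inf).
#' @export
compute_smd <- function(x1, x0, kind = "continuous", levels = NULL) {
  x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
  stopifnot(length(x1) > 0, length(x0) > 0)
  if (kind == "categorical") {
    if (is.null(levels)) levels <- sort(unique(c(x1, x0)))
    p1 <- vapply(levels, function(l) mean(x1 == l), 0)
    p0 <- vapply(levels, function(l) mean(x0 == l), 0)
    Tv <- (p1 - p0)[-1]
    Sg <- function(p) diag(p[-1], length(p) - 1) - tcrossprod(p[-1])
    S <- (Sg(p1) + Sg(p0)) / 2
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) {
      sv <- svd(S)
      pos <- sv$d > max(sv$d) * 1e-10
      if (!any(pos)) return(if (all(abs(Tv) < 1e-12)) 0 else Inf)
      Si <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    }
    val <- drop(t(Tv) %*% Si %*% Tv)
    return(sqrt(max(val, 0)))
  }
  if (kind == "binary") {
    p1 <- mean(x1); p0 <- mean(x0)
    denom <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    if (denom == 0) return(if (p1 == p0) 0 else Inf)
    return(abs(p1 - p0) / denom)
  }
  s1 <- if (length(x1) > 1) stats::var(x1) else 0
  s0 <- if (length(x0) > 1) stats::var(x0) else 0
  denom <- sqrt((s1 + s0) / 2)
  if (denom == 0) return(if (mean(x1) == mean(x0)) 0 else Inf)
  abs(mean(x1) - mean(x0)) / denom
}

#' Covariate balance before and after matching
#'
#' SMD per propensity covariate on the full cohort and on the matched pairs
#' only, flagging |SMD| < 0.1 as balanced.
#'
#' @param data the complete cohort table the match was derived from.
#' @param match a `match_result`.
#' @param covariates covariate names (default: the propensity set).
#' @return data frame with `variable`, `smd_before`, `smd_after`,
#'   `balanced_before`, `balanced_after`.
#' @export
balance_table <- function(data, match, covariates = NULL) {
  spec <- attr(data, "covariate_spec")
  if (is.null(covariates)) covariates <- ps_covariates(spec)
  matched_ids <- c(match$pairs$treated_id, match$pairs$control_id)
  sub <- data[data$id %in% matched_ids, , drop = FALSE]
  smd_of <- function(d, nm) {
    i <- which(spec$name == nm)
    compute_smd(d[[nm]][d$arm == "BLM"], d[[nm]][d$arm == "BL"],
                kind = spec$kind[i], levels = spec$levels[[i]])
  }
  before <- vapply(covariates, function(nm) smd_of(data, nm), 0)
  after <- if (nrow(match$pairs) == 0) {
    rep(NA_real_, length(covariates))
  } else {
    vapply(covariates, function(nm) smd_of(sub, nm), 0)
  }
  data.frame(variable = covariates,
             smd_before = unname(before), smd_after = unname(after),
             balanced_before = unname(before) < 0.1,
             balanced_after = unname(after) < 0.1,
             stringsAsFactors = FALSE)
}
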