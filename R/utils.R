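# Internal numerics shared across modules: deterministic seed derivation,
# an IRLS logistic fitter with a ridge fallback, and design-matrix assembly.

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based split: each (stage, counter) pair maps to a distinct seed so
#' independent random streams (cohort generation, each imputation chain, each
#' bootstrap stream) can be replayed in isolation. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage index (generation = 1, imputation = 2, ...).
#' @param counter integer counter within the stage (chain or replicate index).
#' @return a single integer seed.
#' @keywords internal
sub_seed <- function(master, stage, counter = 0L) {
  m <- 2147483629               # largest prime < 2^31
  s <- (as.double(master) %% m) * 48271 %% m
  s <- (s + as.double(stage) * 16807) %% m
  s <- (s * 69621 + as.double(counter)) %% m
  as.integer(s %% 2147483646) + 1L
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Plain maximum-likelihood IRLS with an optional ridge penalty. On
#' non-convergence, a singular weighted cross-product, or coefficients
#' diverging (the separation signature), the fit is retried once with ridge
#' lambda = 1e-4 and flagged -- never silently.
#'
#' @param X numeric design matrix including an intercept column.
#' @param y 0/1 response.
#' @param ridge ridge penalty lambda (0 = plain ML).
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @return list with `coef`, `fitted`, `vcov` (inverse curvature),
#'   `ridge_used`, `converged`.
#' @keywords internal
fit_logit <- function(X, y, ridge = 0, maxit = 30L, tol = 1e-8) {
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  pen <- diag(ridge, p)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  converged <- FALSE
  failed <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w) + pen
    b <- crossprod(X, w * z)
    new_beta <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
    if (is.null(new_beta) || any(!is.finite(new_beta))) {
      failed <- TRUE
      break
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if ((failed || !converged || max(abs(beta)) > 15) && ridge == 0) {
    refit <- fit_logit(X, y, ridge = 1e-4, maxit = maxit, tol = tol)
    refit$ridge_used <- TRUE
    return(refit)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  A <- crossprod(X, X * w) + pen
  V <- tryCatch(solve(A), error = function(e) {
    solve(A + diag(1e-4, p))
  })
  list(coef = beta, fitted = mu, vcov = V,
       ridge_used = ridge > 0, converged = converged || failed)
}

#' Build a numeric design matrix from cohort columns
#'
#' Continuous and binary covariates enter as-is; categorical covariates are
#' dummy-coded against their first declared level. An intercept column is
#' prepended.
#'
#' @param data data frame holding the covariate columns.
#' @param covariates character vector of covariate names to include.
#' @param spec covariate spec data frame (see [covariate_spec()]).
#' @return numeric matrix with named columns, intercept first.
#' @keywords internal
build_design <- function(data, covariates, spec) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (nm in covariates) {
    kind <- spec$kind[spec$name == nm]
    if (length(kind) == 0) stop("unknown covariate in design: ", nm)
    if (kind == "categorical") {
      levs <- spec$levels[[which(spec$name == nm)]]
      for (lv in levs[-1]) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(data[[nm]] == lv)
      }
    } else {
      cols[[nm]] <- as.numeric(data[[nm]])
    }
  }
  do.call(cbind, cols)
}

# stderr logger used by the pipeline stages
log_msg <- function(...) {
  message(sprintf("[capmatch %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}
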