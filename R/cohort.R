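# data model: cohort schema, validation, CSV IO, Table-1-style summaries

OUTCOME_LEVELS <- c("recovery", "stable", "deterioration", "death", "transfer")
ARM_LEVELS <- c("BLM", "BL")
NON_COVARIATE_COLS <- c("id", "arm", "outcome", "obs_days", "los_days", "abx_days")

#' Covariate registry
#'
#' The default registry ships with the package as a JSON file. It carries the
#' 34 pretreatment covariates entering the propensity model (demographics,
#' treatment setting, drug-resistance risks, comorbidities, pre-admission
#' medication, aspiration-associated factors, vital signs, admission
#' laboratory values, pleural effusion), plus schema-only columns excluded
#' from the propensity model by default: the enrolling hospital and the
#' microbiological-confirmation flags used by subgroup filters.
#'
#' @param path path to a registry JSON file; defaults to the shipped registry.
#' @return a data frame with columns `name`, `kind` (binary / continuous /
#'   categorical), `unit`, `levels` (list column), `in_propensity_model`.
#' @examples
#' spec <- covariate_spec()
#' sum(spec$in_propensity_model)  # 34
#' @export
covariate_spec <- function(path = system.file("extdata",
                                              "covariates_apsg_like.json",
                                              package = "capmatch")) {
  raw <- jsonlite::read_json(path)
  spec <- data.frame(
    name = vapply(raw, function(x) x$name, ""),
    kind = vapply(raw, function(x) x$kind, ""),
    unit = vapply(raw, function(x) if (is.null(x$unit)) "" else x$unit, ""),
    in_propensity_model = vapply(raw, function(x)
      isTRUE(x$in_propensity_model), TRUE),
    stringsAsFactors = FALSE
  )
  spec$levels <- lapply(raw, function(x)
    if (is.null(x$levels)) character(0) else unlist(x$levels))
  validate_covariate_spec(spec)
  spec
}

validate_covariate_spec <- function(spec) {
  if (anyDuplicated(spec$name)) {
    stop("duplicate covariate names: ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  }
  bad_kind <- setdiff(spec$kind, c("binary", "continuous", "categorical"))
  if (length(bad_kind)) stop("unknown covariate kind: ", bad_kind[1])
  for (i in which(spec$kind == "categorical")) {
    if (length(spec$levels[[i]]) < 2) {
      stop("categorical covariate '", spec$name[i], "' needs >= 2 levels")
    }
  }
  invisible(spec)
}

#' Names of the covariates entering the propensity model
#' @param spec a covariate spec data frame.
#' @return character vector.
#' @export
ps_covariates <- function(spec = covariate_spec()) {
  spec$name[spec$in_propensity_model]
}

#' Construct a validated cohort table
#'
#' A cohort table is a data frame of patient records (one row per patient)
#' carrying its covariate spec as an attribute. Fixed columns: `id`, `arm`
#' (BLM = beta-lactam plus macrolide, BL = beta-lactam monotherapy), one
#' column per registered covariate, `outcome` (recovery / stable /
#' deterioration / death / transfer), `obs_days`, `los_days` (NA for
#' outpatients), `abx_days`.
#'
#' @param data data frame with the columns above.
#' @param spec covariate spec data frame.
#' @return a `cohort_table` (data frame subclass).
#' @export
cohort_table <- function(data, spec = covariate_spec()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  validate_cohort(data, spec)
  data <- data[, c("id", "arm", spec$name, "outcome",
                   "obs_days", "los_days", "abx_days")]
  attr(data, "covariate_spec") <- spec
  class(data) <- c("cohort_table", "data.frame")
  data
}

#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  spec <- attr(x, "covariate_spec")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "covariate_spec") <- spec
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  spec <- attr(x, "covariate_spec")
  cat(sprintf("<cohort_table> %d patients (%d BLM / %d BL), %d covariates\n",
              nrow(x), sum(x$arm == "BLM"), sum(x$arm == "BL"), nrow(spec)))
  n_miss <- sum(is.na(x[, spec$name, drop = FALSE]))
  cat(sprintf("  missing covariate cells: %d\n", n_miss))
  invisible(x)
}

validate_cohort <- function(data, spec, check_arms = FALSE) {
  need <- c("id", "arm", spec$name, "outcome", "obs_days", "los_days",
            "abx_days")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(data), need)
  if (length(extra)) {
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  }
  if (anyDuplicated(data$id)) {
    stop("duplicate patient id(s): ",
         paste(unique(data$id[duplicated(data$id)])[1], collapse = ", "))
  }
  bad_arm <- which(!data$arm %in% ARM_LEVELS | is.na(data$arm))
  if (length(bad_arm)) {
    stop("row ", bad_arm[1], ": arm '", data$arm[bad_arm[1]],
         "' is not one of ", paste(ARM_LEVELS, collapse = "/"))
  }
  bad_out <- which(!data$outcome %in% OUTCOME_LEVELS | is.na(data$outcome))
  if (length(bad_out)) {
    stop("row ", bad_out[1], ": outcome '", data$outcome[bad_out[1]],
         "' is not one of ", paste(OUTCOME_LEVELS, collapse = ", "))
  }
  if (any(!is.na(data$obs_days) & data$obs_days < 0)) {
    stop("obs_days must be nonnegative")
  }
  if (anyNA(data$obs_days)) stop("obs_days must not be missing")
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    v <- data[[nm]]
    if (spec$kind[i] == "categorical") {
      bad <- which(!is.na(v) & !v %in% spec$levels[[i]])
      if (length(bad)) {
        stop("row ", bad[1], ", column '", nm, "': value '", v[bad[1]],
             "' not in declared levels (",
             paste(spec$levels[[i]], collapse = ", "), ")")
      }
    } else {
      if (!is.numeric(v)) {
        stop("column '", nm, "' must be numeric (", spec$kind[i], ")")
      }
      if (spec$kind[i] == "binary") {
        bad <- which(!is.na(v) & !v %in% c(0, 1))
        if (length(bad)) {
          stop("row ", bad[1], ", column '", nm,
               "': binary covariate must be 0/1, got ", v[bad[1]])
        }
      }
    }
  }
  if (check_arms && (!any(data$arm == "BLM") || !any(data$arm == "BL"))) {
    stop("analysis entry points require both arms non-empty")
  }
  invisible(data)
}

#' Read a cohort CSV
#'
#' Missing cells must be empty CSV cells; sentinel numerics are rejected by
#' type validation. Values are coerced per the covariate spec and the table
#' is validated (unknown column, non-coercible value, or duplicate id raise
#' an error naming the offending row/column).
#'
#' @param path CSV file path (UTF-8, header row, RFC-4180 quoting).
#' @param spec covariate spec data frame.
#' @return a [cohort_table()].
#' @export
load_cohort <- function(path, spec = covariate_spec()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  for (col in names(raw)) {
    if (col %in% c("id", "arm", "outcome")) next
    if (col %in% spec$name && spec$kind[spec$name == col] == "categorical") next
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(num))
    if (length(bad)) {
      stop("row ", bad[1], ", column '", col, "': cannot coerce '",
           raw[[col]][bad[1]], "' to numeric")
    }
    raw[[col]] <- num
  }
  cohort_table(raw, spec)
}

#' Write a cohort CSV
#'
#' Canonical column order (id, arm, covariates in spec order, outcome,
#' times); missing values as empty cells. `write_cohort` then
#' [load_cohort()] round-trips to an equal table.
#'
#' @param cohort a cohort table.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-arm cohort summary (Table-1 layout)
#'
#' One row per covariate (per level for categoricals) with the arm columns
#' holding `mean (SD)` for continuous covariates and `count (%)` for binary
#' and categorical ones, computed on non-missing values.
#'
#' @param cohort a cohort table.
#' @return data frame with columns `variable`, `level`, `BLM`, `BL`,
#'   and numeric helper columns `BLM_value`, `BL_value`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  spec <- attr(cohort, "covariate_spec")
  rows <- list()
  fmt_cont <- function(v) {
    v <- v[!is.na(v)]
    sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  }
  fmt_bin <- function(v, n) {
    k <- sum(v, na.rm = TRUE)
    sprintf("%d (%.1f)", k, 100 * k / n)
  }
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    for_arm <- function(arm) cohort[[nm]][cohort$arm == arm]
    n_arm <- function(arm) sum(cohort$arm == arm)
    if (spec$kind[i] == "continuous") {
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = "",
        BLM = fmt_cont(for_arm("BLM")), BL = fmt_cont(for_arm("BL")),
        BLM_value = mean(for_arm("BLM"), na.rm = TRUE),
        BL_value = mean(for_arm("BL"), na.rm = TRUE),
        stringsAsFactors = FALSE)
    } else if (spec$kind[i] == "binary") {
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = "",
        BLM = fmt_bin(for_arm("BLM"), n_arm("BLM")),
        BL = fmt_bin(for_arm("BL"), n_arm("BL")),
        BLM_value = sum(for_arm("BLM"), na.rm = TRUE),
        BL_value = sum(for_arm("BL"), na.rm = TRUE),
        stringsAsFactors = FALSE)
    } else {
      for (lv in spec$levels[[i]]) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = nm, level = lv,
          BLM = fmt_bin(for_arm("BLM") == lv, n_arm("BLM")),
          BL = fmt_bin(for_arm("BL") == lv, n_arm("BL")),
          BLM_value = sum(for_arm("BLM") == lv, na.rm = TRUE),
          BL_value = sum(for_arm("BL") == lv, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- c(BLM = sum(cohort$arm == "BLM"),
                      BL = sum(cohort$arm == "BL"))
  out
}
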