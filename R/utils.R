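#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the covariate columns of a cohort table
#'
#' A cohort table is a data frame with reserved columns `subject_id`, `time`
#' (months of follow-up) and `event` (0 censored / 1 event); every other
#' column is a covariate.
#'
#' @param cohort A cohort data frame.
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "time", "event"))
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a cohort table: positive follow-up
#' times, 0/1 event indicator, unique column names, at least one covariate.
#'
#' @param cohort A cohort data frame.
#' @param require_complete If `TRUE`, missing covariate values are an error.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, require_complete = FALSE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  req <- c("subject_id", "time", "event")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(names(cohort))) stop("cohort column names must be unique")
  if (any(!is.finite(cohort$time)) || any(cohort$time <= 0)) {
    stop("cohort$time must be finite and > 0")
  }
  if (!all(cohort$event %in% c(0, 1))) stop("cohort$event must be 0 or 1")
  if (!length(covariate_names(cohort))) stop("cohort has no covariate columns")
  if (require_complete) {
    cv <- covariate_names(cohort)
    if (anyNA(cohort[cv])) stop("cohort covariates contain missing values")
  }
  invisible(cohort)
}

# Derive a per-stage seed from a global seed so pipeline stages are
# independently reproducible. Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  s <- (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(stage)) %% 997L
  as.integer(s %% 2147483587L)
}

# Columns whose observed values are all in {0, 1} (binary covariates and
# missingness flags); used to decide which columns quantile normalization
# should pass through.
is_binary_column <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

covariate_matrix <- function(cohort, covariates = covariate_names(cohort)) {
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols)) {
    stop("covariate(s) absent from cohort: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(cohort[covariates])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}
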