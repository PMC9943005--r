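#' Partial dependence of the predicted log-hazard on one covariate
#'
#' For each grid value `x_k`, the covariate of interest is clamped to that
#' value in every row of the data while all other covariates keep their
#' observed values; the model's predicted log-hazards are averaged:
#' `pd(x_k) = (1/n) * sum_i f(x_k, x_{-k}^i)`. The automatic grid is 20
#' equispaced points between the 1st and 99th percentile for continuous
#' covariates and `{0, 1}` for binary ones. When the covariate has a
#' missingness-flag companion (`<name>_missing`), the flag is clamped to 0 —
#' the curve answers "what if this value had been observed".
#'
#' @param model A fitted hazard model.
#' @param data Cohort or covariate data frame (complete, post-transform).
#' @param covariate Name of the covariate of interest.
#' @param grid `"auto"` or a numeric vector of grid values.
#' @return A `pdp_curve` data frame: `covariate`, `grid_value`,
#'   `mean_log_hazard`, with attribute `n` (rows averaged over).
#' @export
partial_dependence <- function(model, data, covariate, grid = "auto") {
  data <- as.data.frame(data)
  if (!covariate %in% names(data)) {
    stop("covariate '", covariate, "' absent from data")
  }
  x <- data[[covariate]]
  if (anyNA(x)) stop("data must be complete (post-transform)")
  if (identical(grid, "auto")) {
    grid <- if (is_binary_column(x)) {
      c(0, 1)
    } else {
      q <- stats::quantile(x, c(0.01, 0.99))
      seq(q[1], q[2], length.out = 20)
    }
  }
  grid <- sort(unique(as.numeric(grid)))
  flag <- paste0(covariate, "_missing")
  avg <- vapply(grid, function(v) {
    d <- data
    d[[covariate]] <- v
    if (flag %in% names(d)) d[[flag]] <- 0
    mean(predict_log_hazard(model, d))
  }, numeric(1))
  out <- data.frame(covariate = covariate, grid_value = grid,
                    mean_log_hazard = avg, stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(data)
  class(out) <- c("pdp_curve", "data.frame")
  out
}

#' Partial-dependence curves for many covariates
#'
#' @param model A fitted hazard model.
#' @param data Complete covariate data.
#' @param covariates Covariates to profile (default: the model schema minus
#'   missingness-flag columns).
#' @return A single long data frame of stacked [partial_dependence()] curves.
#' @export
partial_dependence_all <- function(model, data, covariates = NULL) {
  covariates <- covariates %||%
    grep("_missing$", model$schema, value = TRUE, invert = TRUE)
  do.call(rbind, lapply(covariates, function(cv) {
    partial_dependence(model, data, cv)
  }))
}
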