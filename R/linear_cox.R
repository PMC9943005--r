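# Group subjects by distinct observed time and accumulate the quantities the
# Breslow partial likelihood needs: per distinct time, the number of events,
# the sum of event scores, and the risk-set sum of exp(score).
risk_set_summary <- function(scores, time, event) {
  ord <- order(time)
  s <- scores[ord]; tt <- time[ord]; ev <- event[ord]
  grp <- cumsum(!duplicated(tt))
  n_g <- max(grp)
  es <- exp(s)
  # sum of exp(score) over subjects with time >= group time
  tail_sum <- rev(cumsum(rev(es)))
  first_idx <- which(!duplicated(tt))
  s0 <- tail_sum[first_idx]
  d <- as.numeric(tapply(ev, grp, sum))
  s_ev <- as.numeric(tapply(s * ev, grp, sum))
  list(times = tt[first_idx], d = d, score_event_sum = s_ev, s0 = s0,
       order = ord, group = grp)
}

#' Cox partial log-likelihood of a score vector (Breslow ties)
#'
#' The log partial likelihood with an arbitrary per-subject risk score in
#' place of the linear predictor:
#' `sum over event times of [sum of event scores - d * log(sum of exp(score) over the risk set)]`.
#'
#' @param scores Finite numeric vector, one log-relative-hazard per subject.
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return The log partial likelihood (a finite scalar).
#' @export
partial_loglik_scores <- function(scores, time, event) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(time) || length(time) != length(event)) {
    stop("scores, time and event must have equal length")
  }
  if (sum(event) < 1) stop("at least one event is required")
  # the partial likelihood is invariant to a constant score shift; center
  # for numerical stability of exp()
  scores <- scores - mean(scores)
  rs <- risk_set_summary(scores, time, event)
  keep <- rs$d > 0
  sum(rs$score_event_sum[keep] - rs$d[keep] * log(rs$s0[keep]))
}

#' Cox partial log-likelihood of a coefficient vector
#'
#' @param beta Named coefficient vector (names select covariate columns) or
#'   unnamed vector matching the cohort's covariate columns in order.
#' @param data Cohort data frame with complete covariates.
#' @param ties Tie handling; only `"breslow"` is implemented.
#' @return The log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, data, ties = "breslow") {
  ties <- match.arg(ties, "breslow")
  validate_cohort(data, require_complete = TRUE)
  covs <- if (!is.null(names(beta))) names(beta) else covariate_names(data)
  x <- covariate_matrix(data, covs)
  partial_loglik_scores(drop(x %*% beta), data$time, data$event)
}

#' Negative Cox partial likelihood for neural scores
#'
#' The training objective of the neural hazard model: identical to
#' [partial_loglik_scores()] up to sign, with the network output in place of
#' the linear predictor.
#'
#' @inheritParams partial_loglik_scores
#' @param data Cohort data frame (covariates are not used, only `time` and
#'   `event`).
#' @param ties Only `"breslow"`.
#' @return Negative log partial likelihood.
#' @export
neural_partial_loss <- function(scores, data, ties = "breslow") {
  ties <- match.arg(ties, "breslow")
  -partial_loglik_scores(scores, data$time, data$event)
}

#' Elastic-net penalized Cox coefficient path
#'
#' Fits the penalized proportional-hazards coefficient path over a decreasing
#' lambda grid (log-spaced from the all-zero solution down to
#' `lambda_min_ratio` times it) via penalized partial-likelihood maximization.
#' The elastic-net penalty is `lambda * ((1 - alpha)/2 * ||beta||_2^2 +
#' alpha * ||beta||_1)`.
#'
#' @param train Training cohort with complete covariates.
#' @param covariates Covariate subset (default: all covariate columns).
#' @param alpha Elastic-net mixing in (0, 1\]; `alpha = 1` is the lasso,
#'   smaller values add an L2 component.
#' @param lambda Optional user lambda grid (positive, decreasing).
#' @param nlambda,lambda_min_ratio Grid resolution and extent.
#' @param ... Further arguments to the underlying solver (e.g. `thresh`).
#' @return A `coxnet_path` object: the glmnet fit plus the design metadata.
#' @export
fit_penalized_cox <- function(train, covariates = NULL, alpha = 0.5,
                              lambda = NULL, nlambda = 100,
                              lambda_min_ratio = 0.001, ...) {
  validate_cohort(train, require_complete = TRUE)
  covariates <- covariates %||% covariate_names(train)
  x <- covariate_matrix(train, covariates)
  y <- survival::Surv(train$time, train$event)
  fit <- if (is.null(lambda)) {
    glmnet::glmnet(x, y, family = "cox", alpha = alpha, nlambda = nlambda,
                   lambda.min.ratio = lambda_min_ratio, ...)
  } else {
    if (length(lambda) > 1 && any(diff(lambda) >= 0) || any(lambda <= 0)) {
      stop("lambda grid must be positive and decreasing")
    }
    glmnet::glmnet(x, y, family = "cox", alpha = alpha, lambda = lambda, ...)
  }
  structure(list(fit = fit, covariates = covariates, alpha = alpha),
            class = "coxnet_path")
}

#' Coefficients along a penalized Cox path
#'
#' @param object A `coxnet_path`.
#' @param ... Passed to the underlying coefficient extractor (e.g. `s =` a
#'   lambda value).
#' @return Sparse coefficient matrix (covariates by lambda).
#' @export
coef.coxnet_path <- function(object, ...) {
  stats::coef(object$fit, ...)
}

#' One-standard-error lambda selection rule
#'
#' Given a cross-validation error curve, returns the largest lambda whose CV
#' error is within one standard error of the minimum:
#' `lambda_1se = max(lambda : cv_error(lambda) <= min(cv_error) + se(at the minimizer))`.
#' By construction `lambda_1se >= lambda_min`.
#'
#' @param lambda Lambda grid.
#' @param cvm Mean CV error per lambda.
#' @param cvsd Standard error of the CV error per lambda.
#' @return List with `lambda_1se`, `lambda_min` and the threshold used.
#' @export
one_se_lambda <- function(lambda, cvm, cvsd) {
  stopifnot(length(lambda) == length(cvm), length(cvm) == length(cvsd))
  imin <- which.min(cvm)
  thr <- cvm[imin] + cvsd[imin]
  list(lambda_1se = max(lambda[cvm <= thr]),
       lambda_min = lambda[imin],
       threshold = thr)
}

event_stratified_folds <- function(event, k, seed) {
  foldid <- integer(length(event))
  set.seed(seed)
  for (ev in c(1, 0)) {
    idx <- sample(which(event == ev))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Cross-validated lambda selection for the penalized Cox path
#'
#' k-fold cross-validation (event-stratified folds) of the partial-likelihood
#' deviance over the path's lambda grid, followed by the one-standard-error
#' rule. A fold that ends up with zero events triggers refolding with a new
#' derived seed (logged via a message).
#'
#' @param path A `coxnet_path` from [fit_penalized_cox()].
#' @param train The training cohort the path was fitted on.
#' @param k Number of folds (>= 2).
#' @param rule `"one_se"` or `"min"`.
#' @param seed Integer seed for fold assignment.
#' @return List with the selected `lambda`, `lambda_min`, `lambda_1se`, and
#'   the CV curve (`lambda`, `cvm`, `cvsd`).
#' @export
cv_select_lambda <- function(path, train, k = 10, rule = c("one_se", "min"),
                             seed = 1L) {
  rule <- match.arg(rule)
  if (k < 2) stop("k must be >= 2")
  if (sum(train$event) < k) stop("need at least k events for k-fold CV")
  x <- covariate_matrix(train, path$covariates)
  y <- survival::Surv(train$time, train$event)
  foldid <- event_stratified_folds(train$event, k, seed)
  tries <- 0
  while (any(tapply(train$event, foldid, sum) == 0) && tries < 10) {
    tries <- tries + 1
    message("cv_select_lambda: fold without events; refolding (attempt ", tries, ")")
    foldid <- event_stratified_folds(train$event, k, seed + tries)
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = path$alpha,
                             lambda = path$fit$lambda, foldid = foldid)
  sel <- one_se_lambda(cvfit$lambda, cvfit$cvm, cvfit$cvsd)
  list(lambda = if (rule == "one_se") sel$lambda_1se else sel$lambda_min,
       lambda_min = sel$lambda_min, lambda_1se = sel$lambda_1se,
       cv_curve = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                             cvsd = cvfit$cvsd))
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' `H0(t) = sum over event times t_i <= t of d_i / sum over the risk set of
#' exp(score_j)`. With all scores zero this is the Nelson-Aalen estimator.
#'
#' @param time,event Follow-up times and event indicators.
#' @param scores Per-subject log-relative-hazard.
#' @return A `breslow_baseline` object: data frame of event times and
#'   cumulative hazard, with an `H0(t)` evaluator.
#' @export
breslow_baseline <- function(time, event, scores = rep(0, length(time))) {
  rs <- risk_set_summary(scores, time, event)
  keep <- rs$d > 0
  knots <- rs$times[keep]
  cumhaz <- cumsum(rs$d[keep] / rs$s0[keep])
  structure(list(time = knots, cumhaz = cumhaz, max_time = max(time)),
            class = "breslow_baseline")
}

# Evaluate a Breslow baseline cumulative hazard at arbitrary horizons.
baseline_cumhaz_at <- function(baseline, t) {
  if (any(t < 0)) stop("t must be >= 0")
  beyond <- t > baseline$max_time
  if (any(beyond)) {
    message("predict_survival: horizon beyond last observed time; ",
            "using the baseline at the last observed time")
  }
  idx <- findInterval(pmin(t, baseline$max_time), baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Fit the elastic-net penalized Cox model end to end
#'
#' Path fit, event-stratified cross-validation, one-standard-error lambda
#' selection, refit coefficients at the selected lambda, and Breslow baseline
#' cumulative hazard on the training data — the complete linear model of the
#' two-family pipeline.
#'
#' @inheritParams fit_penalized_cox
#' @param k CV folds.
#' @param rule Lambda selection rule (`"one_se"` default).
#' @param seed Integer seed for fold assignment.
#' @return A `cox_hazard_model` with named coefficients (`beta`), the chosen
#'   `lambda`, the CV curve, the Breslow `baseline`, and the covariate schema.
#' @export
fit_linear_cox <- function(train, covariates = NULL, alpha = 0.5, k = 10,
                           rule = "one_se", seed = 1L, lambda = NULL,
                           nlambda = 100, lambda_min_ratio = 0.001) {
  covariates <- covariates %||% covariate_names(train)
  path <- fit_penalized_cox(train, covariates, alpha = alpha, lambda = lambda,
                            nlambda = nlambda,
                            lambda_min_ratio = lambda_min_ratio)
  cv <- cv_select_lambda(path, train, k = k, rule = rule, seed = seed)
  beta <- drop(as.matrix(stats::coef(path$fit, s = cv$lambda)))
  names(beta) <- path$covariates
  scores <- drop(covariate_matrix(train, covariates) %*% beta)
  structure(list(beta = beta, lambda = cv$lambda, alpha = alpha,
                 cv = cv, baseline = breslow_baseline(train$time, train$event,
                                                      scores),
                 schema = covariates),
            class = c("cox_hazard_model", "hazard_model"))
}

#' Unpenalized Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Breslow ties) wrapped into the common
#' hazard-model contract; used for parameter-recovery checks and as the
#' linear reference the neural model is compared against.
#'
#' @param train Training cohort with complete covariates.
#' @param covariates Covariate subset.
#' @return A `cox_hazard_model` with `beta`, standard errors `se`, the
#'   Breslow `baseline`, and the underlying `survival::coxph` fit.
#' @export
fit_cox_mle <- function(train, covariates = NULL) {
  validate_cohort(train, require_complete = TRUE)
  covariates <- covariates %||% covariate_names(train)
  x <- covariate_matrix(train, covariates)
  fit <- survival::coxph(survival::Surv(train$time, train$event) ~ x,
                         ties = "breslow")
  beta <- stats::setNames(stats::coef(fit), covariates)
  scores <- drop(x %*% beta)
  structure(list(beta = beta, se = stats::setNames(sqrt(diag(stats::vcov(fit))),
                                                   covariates),
                 lambda = 0, alpha = NA_real_,
                 baseline = breslow_baseline(train$time, train$event, scores),
                 schema = covariates, coxph = fit),
            class = c("cox_hazard_model", "hazard_model"))
}

#' Predicted log-relative-hazard
#'
#' @param model A fitted hazard model.
#' @param newdata Cohort or covariate data frame with the model's schema
#'   columns, complete.
#' @param ... Unused.
#' @return Numeric vector of log-relative-hazard scores (higher = higher risk).
#' @export
predict_log_hazard <- function(model, newdata, ...) UseMethod("predict_log_hazard")

#' @rdname predict_log_hazard
#' @export
predict_log_hazard.cox_hazard_model <- function(model, newdata, ...) {
  x <- covariate_matrix(as.data.frame(newdata), model$schema)
  if (anyNA(x)) stop("newdata covariates must be complete")
  drop(x %*% model$beta)
}

#' Predicted survival probability at a horizon
#'
#' `S(t | X) = exp(-H0(t) * exp(score(X)))` with the model's Breslow baseline
#' `H0`. Horizons beyond the last observed training time use the baseline at
#' the last time (logged via a message).
#'
#' @param model A fitted hazard model.
#' @param newdata Covariate data frame.
#' @param t Horizon in months (scalar, `t >= 0`).
#' @param ... Unused.
#' @return Survival probabilities in (0, 1\].
#' @export
predict_survival <- function(model, newdata, t, ...) UseMethod("predict_survival")

#' @export
predict_survival.default <- function(model, newdata, t, ...) {
  if (is.null(model$baseline)) stop("model has no baseline cumulative hazard")
  h0 <- baseline_cumhaz_at(model$baseline, t)
  exp(-h0 * exp(predict_log_hazard(model, newdata)))
}

#' Scaled Schoenfeld residuals for proportional-hazards diagnostics
#'
#' For each event time `t_i`, the Schoenfeld residual is
#' `X_i - xbar(t_i)` with `xbar` the `exp(score)`-weighted mean of the
#' covariates over the risk set. Scaling follows the standard diagnostic:
#' `d * I^{-1} r_i + beta`, with `d` the number of events and `I` the sum of
#' the per-event weighted covariance matrices. Under proportional hazards
#' the residuals show no time trend.
#'
#' @param model A `cox_hazard_model`.
#' @param data Cohort with complete covariates (>= 2 events).
#' @return Data frame: `time` (event times, ascending) plus one residual
#'   column per covariate.
#' @export
scaled_schoenfeld <- function(model, data) {
  validate_cohort(data, require_complete = TRUE)
  if (sum(data$event) < 2) stop("need >= 2 events for Schoenfeld residuals")
  x <- covariate_matrix(data, model$schema)
  beta <- model$beta
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(data$time)
  x <- x[ord, , drop = FALSE]; w <- w[ord]
  tt <- data$time[ord]; ev <- data$event[ord]
  ev_idx <- which(ev == 1)
  d <- length(ev_idx)
  p <- ncol(x)
  res <- matrix(0, d, p, dimnames = list(NULL, model$schema))
  info <- matrix(0, p, p)
  for (k in seq_len(d)) {
    i <- ev_idx[k]
    risk <- which(tt >= tt[i])
    wr <- w[risk]
    xr <- x[risk, , drop = FALSE]
    xbar <- colSums(xr * wr) / sum(wr)
    res[k, ] <- x[i, ] - xbar
    xc <- sweep(xr, 2, xbar)
    info <- info + crossprod(xc * wr, xc) / sum(wr)
  }
  inv <- tryCatch(solve(info), error = function(e) {
    stop("singular information matrix in scaled_schoenfeld")
  })
  scaled <- d * res %*% inv + matrix(beta, d, p, byrow = TRUE)
  out <- data.frame(time = tt[ev_idx], scaled, check.names = FALSE)
  names(out) <- c("time", model$schema)
  out
}

#' Hazard-ratio table of a fitted linear model
#'
#' Nonzero coefficients as hazard ratios, sorted by effect magnitude —
#' the tabular form behind a forest-style predictor plot.
#'
#' @param model A `cox_hazard_model`.
#' @return Data frame: `covariate`, `coef`, `hazard_ratio`, sorted by
#'   `abs(coef)` decreasing.
#' @export
hazard_ratio_table <- function(model) {
  beta <- model$beta[model$beta != 0]
  out <- data.frame(covariate = names(beta), coef = unname(beta),
                    hazard_ratio = exp(unname(beta)),
                    stringsAsFactors = FALSE)
  out[order(abs(out$coef), decreasing = TRUE), , drop = FALSE]
}
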