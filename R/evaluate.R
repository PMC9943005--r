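#' Harrell's concordance index
#'
#' Probability that, among comparable subject pairs, the higher risk score
#' belongs to the subject with the earlier event. A pair (i, j) is comparable
#' when `t_i < t_j` and subject i had the event; tied risk scores count 1/2.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param risk_scores Per-subject risk scores (higher = higher risk).
#' @return Concordance in \[0, 1\].
#' @export
harrell_cindex <- function(times, events, risk_scores) {
  n <- length(times)
  if (length(events) != n || length(risk_scores) != n) {
    stop("times, events and risk_scores must have equal length")
  }
  conc <- 0; ties <- 0; comp <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    comp <- comp + sum(later)
    conc <- conc + sum(risk_scores[later] < risk_scores[i])
    ties <- ties + sum(risk_scores[later] == risk_scores[i])
  }
  if (comp == 0) stop("no comparable pairs")
  (conc + 0.5 * ties) / comp
}

#' Cross-validated concordance with standard error
#'
#' k-fold cross-validation with event-stratified folds: the model factory is
#' fitted on each training complement and scored on the held-out fold; the
#' reported mean and standard error (`sd / sqrt(k)`) summarize the
#' out-of-fold Harrell c-indices. A fold without comparable pairs triggers
#' refolding with a derived seed (logged via a message).
#'
#' @param model_factory `function(train_cohort, seed)` returning an object
#'   with a [predict_log_hazard()] method.
#' @param cohort Full evaluation cohort (complete covariates).
#' @param k Number of folds.
#' @param seed Integer seed; the fold assignment and any factory randomness
#'   derive from it.
#' @return List with `mean`, `se` and the per-fold c-indices.
#' @export
cv_cindex <- function(model_factory, cohort, k = 10, seed = 1L) {
  validate_cohort(cohort)
  if (k < 2) stop("k must be >= 2")
  if (sum(cohort$event) < k) stop("need at least k events")
  foldid <- event_stratified_folds(cohort$event, k, seed)
  for (attempt in 1:10) {
    ok <- all(tapply(cohort$event, foldid, sum) >= 1)
    if (ok) break
    message("cv_cindex: fold without events; refolding")
    foldid <- event_stratified_folds(cohort$event, k, seed + attempt)
  }
  cidx <- numeric(k)
  for (f in seq_len(k)) {
    train <- cohort[foldid != f, , drop = FALSE]
    test <- cohort[foldid == f, , drop = FALSE]
    model <- model_factory(train, seed = stage_seed(seed, paste0("fold", f)))
    scores <- predict_log_hazard(model, test)
    cidx[f] <- harrell_cindex(test$time, test$event, scores)
  }
  list(mean = mean(cidx), se = stats::sd(cidx) / sqrt(k), folds = cidx)
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t),
# evaluated left-continuously (at t-) when minus = TRUE.
censoring_km_at <- function(times, events, at, minus = FALSE) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  eval_at <- if (minus) at - sqrt(.Machine$double.eps) * pmax(at, 1) else at
  idx <- findInterval(eval_at, fit$time)
  c(1, fit$surv)[idx + 1L]
}

# Weighted cumulative-dynamic AUC core: cases are events by the horizon,
# controls are still at risk after it; IPCW weights remove the censoring
# bias. O(n log n) via sorted cumulative control weights.
ipcw_auc_core <- function(times, events, scores, horizon, g_case, g_ctrl) {
  case <- times <= horizon & events == 1
  ctrl <- times > horizon
  if (!any(case)) stop("no cases by the horizon")
  if (!any(ctrl)) stop("no controls at the horizon")
  w_case <- 1 / g_case[case]
  w_ctrl <- rep(1 / g_ctrl, sum(ctrl))
  s_case <- scores[case]
  s_ctrl <- scores[ctrl]
  ord <- order(s_ctrl)
  s_sorted <- s_ctrl[ord]
  cw <- cumsum(w_ctrl[ord])
  n_lt <- findInterval(s_case, s_sorted, left.open = TRUE)
  n_le <- findInterval(s_case, s_sorted)
  w_lt <- c(0, cw)[n_lt + 1L]
  w_le <- c(0, cw)[n_le + 1L]
  sum(w_case * (w_lt + 0.5 * (w_le - w_lt))) / (sum(w_case) * sum(w_ctrl))
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-cases / dynamic-controls AUC at a fixed horizon. Cases are
#' subjects with an event by the horizon, controls those still event-free
#' beyond it; each case is weighted by `1/G(T_i-)` and each control by
#' `1/G(horizon)`, with `G` the Kaplan-Meier estimate of the censoring
#' distribution. The confidence interval is a seeded percentile bootstrap.
#'
#' @param times,events Follow-up and event indicators.
#' @param risk_scores Per-subject risk scores.
#' @param horizon Horizon in months within the observed follow-up.
#' @param n_boot Bootstrap resamples for the CI (0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level CI level.
#' @return List with `auc`, `ci` (lower, upper) and `n_boot`.
#' @export
time_dependent_auc <- function(times, events, risk_scores, horizon,
                               n_boot = 500, seed = 1L, conf_level = 0.95) {
  if (horizon <= 0 || horizon >= max(times)) {
    stop("horizon must lie within the observed follow-up")
  }
  g_case <- censoring_km_at(times, events, times, minus = TRUE)
  g_ctrl <- censoring_km_at(times, events, horizon)
  auc <- ipcw_auc_core(times, events, risk_scores, horizon, g_case, g_ctrl)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(times)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch({
        gc_b <- censoring_km_at(times[idx], events[idx], times[idx], minus = TRUE)
        g0_b <- censoring_km_at(times[idx], events[idx], horizon)
        ipcw_auc_core(times[idx], events[idx], risk_scores[idx], horizon,
                      gc_b, g0_b)
      }, error = function(e) NA_real_)
    }, numeric(1))
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE))
  }
  list(auc = auc, ci = ci, n_boot = n_boot)
}

#' Paired bootstrap comparison of two time-dependent AUCs
#'
#' Resamples subjects with replacement, recomputes both models' IPCW AUCs on
#' each resample, and tests `delta AUC = 0` with a normal approximation using
#' the bootstrap standard error of the paired difference.
#'
#' @param scores_a,scores_b Risk scores of the two models on the same rows.
#' @param times,events Shared outcomes.
#' @param horizon Horizon in months.
#' @param n_boot Bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return List with `delta` (AUC_a - AUC_b), `p_value`, `se` and the
#'   per-model AUCs.
#' @export
compare_auc <- function(scores_a, scores_b, times, events, horizon,
                        n_boot = 500, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100 for a stable comparison")
  if (length(scores_a) != length(scores_b)) {
    stop("both models must be scored on the same rows")
  }
  g_case <- censoring_km_at(times, events, times, minus = TRUE)
  g_ctrl <- censoring_km_at(times, events, horizon)
  auc_a <- ipcw_auc_core(times, events, scores_a, horizon, g_case, g_ctrl)
  auc_b <- ipcw_auc_core(times, events, scores_b, horizon, g_case, g_ctrl)
  delta <- auc_a - auc_b
  set.seed(seed)
  n <- length(times)
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch({
      gc_b <- censoring_km_at(times[idx], events[idx], times[idx], minus = TRUE)
      g0_b <- censoring_km_at(times[idx], events[idx], horizon)
      ipcw_auc_core(times[idx], events[idx], scores_a[idx], horizon, gc_b, g0_b) -
        ipcw_auc_core(times[idx], events[idx], scores_b[idx], horizon, gc_b, g0_b)
    }, error = function(e) NA_real_)
  }, numeric(1))
  se <- stats::sd(deltas, na.rm = TRUE)
  p <- if (!is.finite(se) || se == 0) 1 else 2 * stats::pnorm(-abs(delta) / se)
  list(delta = delta, p_value = p, se = se, auc_a = auc_a, auc_b = auc_b)
}

km_survival_at <- function(times, events, horizon) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  idx <- findInterval(horizon, fit$time)
  c(1, fit$surv)[idx + 1L]
}

#' Decile calibration table
#'
#' Splits subjects into near-equal groups by predicted risk and compares the
#' mean predicted risk with the observed risk (one minus the within-group
#' Kaplan-Meier survival at the horizon), which remains valid for subjects
#' censored before the horizon under independent censoring.
#'
#' @param predicted_risk Predicted event probabilities at the horizon, in
#'   \[0, 1\].
#' @param times,events Outcomes.
#' @param horizon Horizon in months.
#' @param groups Number of groups (default 10 = deciles).
#' @return Data frame: `group`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_deciles <- function(predicted_risk, times, events, horizon,
                                groups = 10) {
  if (any(predicted_risk < 0 | predicted_risk > 1)) {
    stop("predicted_risk must be in [0, 1]")
  }
  n <- length(predicted_risk)
  if (length(unique(predicted_risk)) < 2) {
    warning("all predictions identical; using a single calibration group",
            call. = FALSE)
    groups <- 1
  }
  g <- ceiling(rank(predicted_risk, ties.method = "first") * groups / n)
  out <- do.call(rbind, lapply(seq_len(groups), function(k) {
    in_g <- g == k
    data.frame(group = k, n = sum(in_g),
               mean_predicted = mean(predicted_risk[in_g]),
               observed = 1 - km_survival_at(times[in_g], events[in_g], horizon))
  }))
  out
}

#' Integrated calibration index
#'
#' Density-weighted mean absolute difference between predicted and observed
#' risks at a horizon. Observed risks are smoothed by regressing the hazard
#' on a natural cubic spline of the complementary log-log of the predicted
#' risk, then converting back to an event probability through the model's
#' Breslow baseline; taking the subject-wise mean of
#' `|smoothed observed - predicted|` realizes the weighting by the empirical
#' density of the predictions. If the spline hazard fit fails, a binned
#' Kaplan-Meier local-regression smoother is used instead (logged warning).
#'
#' @param predicted_risk Predicted event probabilities at the horizon.
#' @param times,events Outcomes.
#' @param horizon Horizon in months.
#' @param df Spline degrees of freedom.
#' @return The ICI (non-negative scalar).
#' @export
ici <- function(predicted_risk, times, events, horizon, df = 3) {
  p <- pmin(pmax(predicted_risk, 1e-10), 1 - 1e-10)
  if (stats::var(p) == 0) {
    # calibration-in-the-large only: observed risk is the overall KM risk
    obs <- 1 - km_survival_at(times, events, horizon)
    return(mean(abs(obs - p)))
  }
  cll <- log(-log(1 - p))
  obs <- tryCatch({
    basis <- splines::ns(cll, df = df)
    fit <- survival::coxph(survival::Surv(times, events) ~ basis,
                           ties = "breslow")
    lp <- drop(basis %*% stats::coef(fit))
    bl <- breslow_baseline(times, events, lp)
    1 - exp(-baseline_cumhaz_at(bl, horizon) * exp(lp))
  }, error = function(e) {
    warning("ici: spline hazard fit failed (", conditionMessage(e),
            "); using binned local-regression smoother", call. = FALSE)
    nb <- max(5L, min(20L, floor(length(p) / 50)))
    g <- ceiling(rank(p, ties.method = "first") * nb / length(p))
    bp <- vapply(seq_len(nb), function(k) mean(p[g == k]), numeric(1))
    bo <- vapply(seq_len(nb), function(k) {
      1 - km_survival_at(times[g == k], events[g == k], horizon)
    }, numeric(1))
    lo <- stats::lowess(bp, bo, f = 2 / 3)
    stats::approx(lo$x, lo$y, xout = p, rule = 2)$y
  })
  mean(abs(obs - p))
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times,events Outcomes (`times > 0`).
#' @return A `km_curve`: data frame of `time` and `surv` plus an evaluator
#'   `S(t)` (`fn`).
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("times must be non-negative")
  if (!length(times)) stop("empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 fn = stats::stepfun(fit$time, c(1, fit$surv))),
            class = "km_curve")
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Cumulative incidence of the event of interest with a competing event; with
#' zero competing events it equals one minus the Kaplan-Meier estimate
#' exactly.
#'
#' @param times Follow-up times.
#' @param events 0/1 indicator for the event of interest.
#' @param competing_events 0/1 indicator for the competing event (mutually
#'   exclusive with `events`).
#' @return A `cif_curve`: data frame of `time` and `cif` plus an evaluator.
#' @export
cumulative_incidence <- function(times, events, competing_events) {
  if (any(times < 0)) stop("times must be non-negative")
  if (any(events == 1 & competing_events == 1)) {
    stop("events and competing_events must be mutually exclusive")
  }
  status <- factor(ifelse(events == 1, 1, ifelse(competing_events == 1, 2, 0)),
                   levels = c(0, 1, 2))
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  state <- which(fit$states == "1")
  cif <- fit$pstate[, state]
  structure(list(time = fit$time, cif = cif,
                 fn = stats::stepfun(fit$time, c(0, cif))),
            class = "cif_curve")
}

#' Classification metrics at the Youden-index cut-off
#'
#' Reduces the horizon outcome to a binary status (cases: event by the
#' horizon; controls: event-free at the horizon; subjects censored before the
#' horizon are excluded with a message), scans all unique predicted values as
#' cut-offs, and reports sensitivity, specificity, PPV and NPV at the cut-off
#' maximizing Youden's index (sensitivity + specificity - 1).
#'
#' @param predicted_risk Predicted event probabilities at the horizon.
#' @param times,events Outcomes.
#' @param horizon Horizon in months.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden`, and the case/control counts used.
#' @export
threshold_metrics <- function(predicted_risk, times, events, horizon) {
  case <- events == 1 & times <= horizon
  ctrl <- times >= horizon & !case
  excluded <- !(case | ctrl)
  if (any(excluded)) {
    message("threshold_metrics: excluding ", sum(excluded),
            " subject(s) censored before the horizon")
  }
  p <- predicted_risk[case | ctrl]
  y <- case[case | ctrl]
  if (!any(y)) stop("no cases at the horizon")
  if (all(y)) stop("no controls at the horizon")
  cuts <- sort(unique(p))
  best <- list(youden = -Inf)
  for (cut in cuts) {
    pos <- p >= cut
    sens <- sum(pos & y) / sum(y)
    spec <- sum(!pos & !y) / sum(!y)
    j <- sens + spec - 1
    if (j > best$youden + 1e-12) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   ppv = if (any(pos)) sum(pos & y) / sum(pos) else NA_real_,
                   npv = if (any(!pos)) sum(!pos & !y) / sum(!pos) else NA_real_,
                   youden = j)
    }
  }
  best$n_cases <- sum(y)
  best$n_controls <- sum(!y)
  best
}

#' Full validation report for a fitted hazard model
#'
#' Computes the discrimination/calibration panel for one model on held-out
#' data: Harrell c-index, IPCW time-dependent AUC with bootstrap CI, ICI and
#' decile calibration at each horizon, and Youden threshold metrics.
#'
#' @param model A fitted hazard model (log-hazard + baseline contract).
#' @param test Held-out cohort (complete covariates).
#' @param horizons Horizons in months (default 24 and 60).
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param seed Integer seed.
#' @return A `validation_report` list.
#' @export
validation_report <- function(model, test, horizons = c(24, 60),
                              n_boot = 500, seed = 1L) {
  validate_cohort(test, require_complete = TRUE)
  scores <- predict_log_hazard(model, test)
  per_h <- lapply(horizons, function(h) {
    risk <- 1 - predict_survival(model, test, h)
    auc <- time_dependent_auc(test$time, test$event, scores, h,
                              n_boot = n_boot, seed = stage_seed(seed, paste0("auc", h)))
    list(horizon = h,
         auc = auc$auc, auc_ci = auc$ci,
         ici = ici(risk, test$time, test$event, h),
         deciles = calibration_deciles(risk, test$time, test$event, h),
         threshold = threshold_metrics(risk, test$time, test$event, h))
  })
  structure(list(cindex = harrell_cindex(test$time, test$event, scores),
                 horizons = per_h, n = nrow(test)),
            class = "validation_report")
}
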