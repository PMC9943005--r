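toy_cohort <- function(time, event, ...) {
  x <- list(...)
  data.frame(subject_id = sprintf("s%d", seq_along(time)),
             time = time, event = event, x, check.names = FALSE)
}

test_that("partial log-likelihood matches hand-counted risk sets", {
  # two subjects, both events, beta = 0: log(1/2) + log(1/1)
  co <- toy_cohort(c(1, 2), c(1, 1), x = c(0.3, -0.1))
  expect_equal(cox_partial_loglik(c(x = 0), co), log(1 / 2) + log(1),
               tolerance = 1e-12)
  # a single subject with an event: risk set of one
  co1 <- toy_cohort(3, 1, x = 1.7)
  expect_equal(cox_partial_loglik(c(x = 0.5), co1), 0, tolerance = 1e-12)
  expect_error(cox_partial_loglik(c(x = 0), toy_cohort(c(1, 2), c(0, 0), x = c(1, 2))),
               "event")
})

test_that("Breslow ties agree with the brute-force oracle and with coxph", {
  co <- toy_cohort(c(2, 2, 3, 5), c(1, 1, 0, 1), x = c(1, 0, -1, 0.5))
  beta <- c(x = 0.5)
  expect_equal(cox_partial_loglik(beta, co),
               bf_partial_loglik(0.5 * co$x, co$time, co$event),
               tolerance = 1e-10)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = co,
                         ties = "breslow", init = 0.5,
                         control = survival::coxph.control(iter.max = 0))
  expect_equal(cox_partial_loglik(beta, co), fit$loglik[2], tolerance = 1e-8)
})

test_that("neural loss equals the negative linear partial likelihood", {
  co <- toy_cohort(c(1, 2, 3, 4), c(1, 0, 1, 1), x = c(0.2, -0.3, 1.1, 0))
  scores <- c(1.0, 0.5, 0.0, -0.5)
  expect_equal(neural_partial_loss(scores, co),
               -bf_partial_loglik(scores, co$time, co$event),
               tolerance = 1e-10)
  # shift invariance and the all-equal = null-model identity
  expect_equal(neural_partial_loss(scores + 3.2, co),
               neural_partial_loss(scores, co), tolerance = 1e-9)
  expect_equal(neural_partial_loss(rep(2, 4), co),
               -cox_partial_loglik(c(x = 0), co), tolerance = 1e-10)
  expect_equal(neural_partial_loss(0.7 * co$x, co),
               -cox_partial_loglik(c(x = 0.7), co), tolerance = 1e-8)
})

test_that("penalized path shrinks to zero, recovers signal, and respects ridge symmetry", {
  fx <- linear_fixture()
  tr <- fx$train
  path <- fit_penalized_cox(tr, alpha = 0.5)
  b_max <- as.matrix(coef(path, s = path$fit$lambda[1]))
  expect_true(all(b_max == 0))  # strongest penalty: exact zeros
  nz <- colSums(as.matrix(coef(path)) != 0)
  expect_true(nz[1] <= nz[length(nz)])  # sparsity decreases along the path
  # near-unpenalized end of the path recovers the strong coefficient
  b_min <- as.matrix(coef(path, s = min(path$fit$lambda)))
  expect_lt(abs(b_min["x1", 1] - 0.8), 3 * fx$cox$se[["x1"]])
  # pure L2 with a duplicated covariate: coefficients split evenly
  tr2 <- tr
  tr2$x1_dup <- tr2$x1
  p2 <- fit_penalized_cox(tr2, covariates = c("x1", "x1_dup"), alpha = 0,
                          lambda = c(1, 0.1, 0.01), thresh = 1e-14)
  b2 <- as.matrix(coef(p2, s = 0.1))
  expect_lt(abs(b2["x1", 1] - b2["x1_dup", 1]), 1e-6)
})

test_that("the one-standard-error rule is the analytic maximum", {
  # SE identically zero collapses to the minimizer
  sel <- one_se_lambda(c(3, 2, 1), c(10, 9, 9.5), c(0, 0, 0))
  expect_equal(sel$lambda_1se, sel$lambda_min)
  # flat curve: the largest grid lambda wins
  sel <- one_se_lambda(c(3, 2, 1), c(5, 5, 5), c(1, 1, 1))
  expect_equal(sel$lambda_1se, 3)
  # hand-evaluated 3-point curve
  sel <- one_se_lambda(c(3, 2, 1), c(10, 9, 9.5), c(1, 1, 1))
  expect_equal(sel$lambda_1se, 3)
  expect_equal(sel$lambda_min, 2)
})

test_that("cross-validated selection is deterministic and respects lambda_1se >= lambda_min", {
  fx <- linear_fixture()
  tr <- fx$train
  path <- fit_penalized_cox(tr, alpha = 0.5)
  cv1 <- cv_select_lambda(path, tr, k = 5, seed = 3)
  cv2 <- cv_select_lambda(path, tr, k = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  expect_equal(cv1$lambda, cv1$lambda_1se)
})

test_that("the Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  bl <- breslow_baseline(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(bl$cumhaz[4], 1 / 4 + 1 / 3 + 1 / 2 + 1, tolerance = 1e-12)
  expect_equal(bl$cumhaz[2], bf_nelson_aalen_at(c(1, 2, 3, 4), rep(1, 4), 2),
               tolerance = 1e-12)
  m <- manual_cox_model(c(x = 0), baseline_time = bl$time,
                        baseline_cumhaz = bl$cumhaz, max_time = 4)
  expect_equal(predict_survival(m, data.frame(x = 1), 0), 1)
  s <- vapply(c(1, 2, 3, 4), function(t) {
    suppressMessages(predict_survival(m, data.frame(x = 1), t))
  }, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("survival predictions preserve risk ordering and average calibration", {
  fx <- linear_fixture()
  m <- fx$cox
  te <- fx$test
  sc <- predict_log_hazard(m, te)
  s24 <- predict_survival(m, te, 24)
  expect_true(all(s24 > 0 & s24 <= 1))
  # higher score => lower survival at every horizon
  ord <- order(sc)
  expect_true(all(diff(s24[ord]) <= 1e-12))
  # calibration-in-the-large at 2 years
  mean_risk <- mean(1 - s24)
  km <- kaplan_meier(te$time, te$event)
  obs <- 1 - km$fn(24)
  se <- sqrt(obs * (1 - obs) / nrow(te))
  expect_lt(abs(mean_risk - obs), 3 * se + 0.02)
})

test_that("scaled Schoenfeld residuals match the brute-force definition", {
  co <- toy_cohort(c(1, 2, 3), c(1, 1, 0), x = c(0.5, -0.2, 0.9))
  beta <- c(x = 0.4)
  m <- manual_cox_model(beta)
  sr <- scaled_schoenfeld(m, co)
  # brute force: r_i = x_i - weighted mean over risk set; scale by d * I^-1 + beta
  w <- exp(0.4 * co$x)
  r1 <- co$x[1] - sum(co$x * w) / sum(w)
  r2 <- co$x[2] - sum(co$x[2:3] * w[2:3]) / sum(w[2:3])
  v1 <- sum(w * (co$x - sum(co$x * w) / sum(w))^2) / sum(w)
  v2 <- sum(w[2:3] * (co$x[2:3] - sum(co$x[2:3] * w[2:3]) / sum(w[2:3]))^2) / sum(w[2:3])
  expected <- 2 * c(r1, r2) / (v1 + v2) + 0.4
  expect_equal(sr$x, expected, tolerance = 1e-8)
})

test_that("Schoenfeld diagnostics separate proportional from time-varying hazards", {
  flagged_ph <- 0
  positive_tv <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    g <- generate_cohort(sim_config(2000, std_covariates(2),
      list(effect_spec("x1", "linear", coef = 0.6)),
      baseline = list(shape = 1.2, scale = 80),
      censoring = list(max_followup = 100, entry_window = 50), seed = 100 + r))
    m <- fit_cox_mle(g$cohort)
    sr <- scaled_schoenfeld(m, g$cohort)
    rho <- vapply(c("x1", "x2"), function(v) stats::cor(sr$time, sr[[v]]),
                  numeric(1))
    if (any(abs(rho) >= 0.1)) flagged_ph <- flagged_ph + 1

    # time-interacting coefficient beta(t) = t / 50 on x1
    set.seed(200 + r)
    n <- 1000
    x1 <- rnorm(n); x2 <- rnorm(n)
    tgrid <- seq(0.5, 100, by = 0.5)
    base_inc <- diff(c(0, (tgrid / 80)^1.2))
    hc <- t(vapply(x1, function(x) cumsum(base_inc * exp((tgrid / 50) * x)),
                   numeric(length(tgrid))))
    e <- rexp(n)
    hit <- hc - e > 0
    t_ev <- apply(hit, 1, function(z) if (any(z)) tgrid[which(z)[1]] else Inf)
    cens <- runif(n, 40, 100)
    co <- data.frame(subject_id = as.character(seq_len(n)),
                     time = pmin(t_ev, cens), event = as.numeric(t_ev <= cens),
                     x1 = x1, x2 = x2)
    m2 <- fit_cox_mle(co)
    sr2 <- scaled_schoenfeld(m2, co)
    if (stats::cor(sr2$time, sr2$x1) > 0) positive_tv <- positive_tv + 1
  }
  expect_gte(n_rep - flagged_ph, 0.9 * n_rep)
  expect_gte(positive_tv, 0.9 * n_rep)
})

test_that("the fitted model is a local maximum of the partial likelihood", {
  fx <- linear_fixture()
  tr <- fx$train
  beta_hat <- fx$cox$beta
  ll_hat <- cox_partial_loglik(beta_hat, tr)
  set.seed(42)
  for (i in 1:10) {
    expect_gte(ll_hat, cox_partial_loglik(beta_hat + rnorm(5, 0, 0.05), tr))
  }
})

test_that("the hazard-ratio table reports nonzero coefficients by magnitude", {
  m <- manual_cox_model(c(a = 0.2, b = -0.9, c = 0))
  tab <- hazard_ratio_table(m)
  expect_identical(tab$covariate, c("b", "a"))
  expect_equal(tab$hazard_ratio, exp(c(-0.9, 0.2)))
})
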