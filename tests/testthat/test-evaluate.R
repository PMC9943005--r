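test_that("Harrell c-index matches hand counts and pair enumeration", {
  expect_equal(harrell_cindex(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1.0)
  expect_equal(harrell_cindex(c(1, 2, 3), c(1, 1, 1), c(5, 5, 5)), 0.5)
  set.seed(2)
  times <- c(2, 5, 3, 8, 4, 9)
  events <- c(1, 1, 0, 0, 1, 1)
  scores <- c(1.2, 0.4, 0.4, -0.3, 2.0, -1.0)
  expect_identical(harrell_cindex(times, events, scores),
                   bf_cindex(times, events, scores))
  expect_error(harrell_cindex(3, 0, 1), "comparable")
})

test_that("cross-validated c-index is stratified, deterministic and unbiased", {
  fx <- linear_fixture()
  co <- fx$cohort
  # the generator's truth is linear, so the oracle scorer is a fixed
  # linear model carrying the true coefficients
  oracle_factory <- function(train, seed) {
    manual_cox_model(c(x1 = 0.8, x2 = -0.5, x3 = 0.3, x4 = 0, x5 = 0))
  }
  cv1 <- cv_cindex(oracle_factory, co, k = 5, seed = 2)
  cv2 <- cv_cindex(oracle_factory, co, k = 5, seed = 2)
  expect_identical(cv1, cv2)
  full <- harrell_cindex(co$time, co$event,
                         fx$truth$f_star(co[covariate_names(co)]))
  expect_lt(abs(cv1$mean - full), 0.02)

  noise_factory <- function(train, seed) {
    manual_cox_model(c(x1 = 0, x2 = 0, x3 = 0, x4 = 0, x5 = 1e-12))
  }
  cvn <- cv_cindex(noise_factory, co, k = 5, seed = 3)
  expect_lt(abs(cvn$mean - 0.5), 2 * max(cvn$se, 0.01) + 0.02)
})

test_that("IPCW time-dependent AUC matches the plain AUC without censoring", {
  set.seed(4)
  n <- 300
  time <- rexp(n, 0.05) + 0.1
  event <- rep(1, n)                       # no censoring at all
  score <- -time + rnorm(n, 0, 5)
  horizon <- stats::median(time)
  got <- time_dependent_auc(time, event, score, horizon, n_boot = 0)
  y <- time <= horizon
  # plain Mann-Whitney AUC of the binary horizon status
  plain <- mean(outer(score[y], score[!y], ">") + 0.5 * outer(score[y], score[!y], "=="))
  expect_equal(got$auc, plain, tolerance = 1e-12)
  # perfect separation
  expect_equal(time_dependent_auc(time, event, -time, horizon, n_boot = 0)$auc, 1)
})

test_that("IPCW weighting matches the brute-force pair sum under censoring", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 0, 1, 0, 1, 0)
  score <- c(2.0, 1.5, 1.8, 0.3, 0.9, 0.1, 1.1, -0.4)
  horizon <- 5.5
  got <- time_dependent_auc(time, event, score, horizon, n_boot = 0)
  expect_equal(got$auc, bf_ipcw_auc(time, event, score, horizon),
               tolerance = 1e-10)
  # bootstrap CI is seeded and ordered
  a1 <- time_dependent_auc(time, event, score, horizon, n_boot = 200, seed = 5)
  a2 <- time_dependent_auc(time, event, score, horizon, n_boot = 200, seed = 5)
  expect_identical(a1, a2)
  expect_lte(a1$ci[1], a1$auc + 1e-12)
})

test_that("paired AUC comparison is symmetric, null-safe and powered", {
  fx <- linear_fixture()
  te <- fx$test
  s_model <- predict_log_hazard(fx$cox, te)
  expect_equal(
    compare_auc(s_model, s_model, te$time, te$event, 24, n_boot = 100,
                seed = 1)$p_value, 1)
  set.seed(3)
  s_noise <- rnorm(nrow(te))
  ab <- compare_auc(s_model, s_noise, te$time, te$event, 24, n_boot = 200, seed = 2)
  ba <- compare_auc(s_noise, s_model, te$time, te$event, 24, n_boot = 200, seed = 2)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
  expect_error(compare_auc(s_model, s_noise, te$time, te$event, 24, n_boot = 50),
               "n_boot")
  # power: a strong model beats noise nearly always
  rejections <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    g <- sim_linear_cohort(2000, seed = 500 + r, betas = c(1.0, 0.5))
    co <- g$cohort
    strong <- g$truth$f_star(co[covariate_names(co)])
    set.seed(600 + r)
    noise <- rnorm(nrow(co))
    p <- compare_auc(strong, noise, co$time, co$event, 24, n_boot = 120,
                     seed = 700 + r)$p_value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_gte(rejections, 0.95 * n_rep)
})

test_that("decile calibration recovers oracle risks and partitions the data", {
  fx <- ehr_complete_fixture()
  co <- fx$cohort
  tab <- calibration_deciles(fx$risk24, co$time, co$event, 24)
  expect_identical(sum(tab$n), nrow(co))
  expect_lte(max(tab$n) - min(tab$n), 1)
  expect_lt(max(abs(tab$observed - tab$mean_predicted)), 0.03)
  # no events, all-zero predictions (single group: every value ties)
  tab0 <- suppressWarnings(calibration_deciles(rep(0, 40), rexp(40) + 1,
                                               rep(0, 40), 2))
  expect_true(all(tab0$observed == 0))
  expect_warning(calibration_deciles(rep(0.3, 30), rexp(30) + 1,
                                     rbinom(30, 1, 0.4), 1), "identical")
})

test_that("the integrated calibration index detects miscalibration monotonically", {
  fx <- ehr_complete_fixture()
  co <- fx$cohort
  base <- ici(fx$risk24, co$time, co$event, 24)
  expect_lt(base, 0.01)
  shifted <- pmin(pmax(fx$risk24 + 0.10, 1e-6), 1 - 1e-6)
  i_shift <- ici(shifted, co$time, co$event, 24)
  expect_gte(i_shift, 0.07)
  expect_lte(i_shift, 0.12)
  small_shift <- pmin(pmax(fx$risk24 + 0.05, 1e-6), 1 - 1e-6)
  expect_lt(base, ici(small_shift, co$time, co$event, 24))
  expect_lt(ici(small_shift, co$time, co$event, 24), i_shift)
})

test_that("a constant prediction equal to the event fraction is calibrated in the large", {
  set.seed(9)
  n <- 5000
  time <- rexp(n, 0.2) + 0.01
  event <- rep(1, n)                       # no censoring
  horizon <- stats::quantile(time, 0.6)
  p <- rep(mean(time <= horizon), n)
  expect_lt(ici(p, time, event, horizon), 0.01)
})

test_that("Kaplan-Meier and cumulative incidence match hand-computed step functions", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$fn(c(1, 2, 3, 4)), c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  km_c <- kaplan_meier(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(km_c$fn(c(1, 5, 10)) == 1))
  # interleaved censoring, hand product-limit
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 0, 1, 0, 1, 0)
  km2 <- kaplan_meier(times, events)
  expect_equal(km2$fn(5), bf_km_at(times, events, 5), tolerance = 1e-10)
  expect_equal(km2$fn(5), (1 - 1/6) * (1 - 1/4) * (1 - 1/2), tolerance = 1e-10)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")

  # Aalen-Johansen with no competing events equals 1 - KM exactly
  cif <- cumulative_incidence(times, events, rep(0, 6))
  expect_equal(cif$fn(c(1, 3, 5)), 1 - km2$fn(c(1, 3, 5)), tolerance = 1e-12)
  # with competing events the CIF is below 1 - KM of the naive estimate
  comp <- c(0, 1, 0, 1, 0, 0)
  cif2 <- cumulative_incidence(times, events, comp)
  expect_true(all(diff(cif2$cif) >= -1e-12))
  expect_lte(max(cif2$cif), 1)
})

test_that("Youden threshold metrics match exhaustive enumeration", {
  p <- c(0.9, 0.8, 0.7, 0.65, 0.5, 0.4, 0.35, 0.2, 0.15, 0.1)
  times <- c(1, 2, 1.5, 9, 3, 10, 11, 12, 13, 2.5)
  events <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  horizon <- 8
  got <- threshold_metrics(p, times, events, horizon)
  y <- events == 1 & times <= horizon
  keep <- y | times >= horizon
  want <- bf_threshold(p[keep], y[keep])
  for (f in c("cutoff", "sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
  # perfectly separating predictor
  sep <- threshold_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 2, 9, 9), c(1, 1, 0, 0), 5)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # constant predictor has Youden index 0
  cst <- threshold_metrics(rep(0.4, 6), c(1, 2, 3, 9, 9, 9), c(1, 1, 1, 0, 0, 0), 5)
  expect_equal(cst$youden, 0)
  expect_message(threshold_metrics(c(0.5, 0.4, 0.6), c(1, 2, 9), c(1, 0, 0), 5),
                 "censored before")
})

test_that("AUC and c-index agree when censoring cannot distort either", {
  # all censoring happens after the horizon, every event precedes it, and
  # the event fraction is low so case-case pairs barely dilute the c-index
  set.seed(12)
  n <- 3000
  x <- rnorm(n)
  t_ev <- rexp(n, 0.002 * exp(0.9 * x))
  cens <- 60
  keep <- t_ev <= 50 | t_ev > cens       # drop events in (50, 60] so the
  x <- x[keep]; t_ev <- t_ev[keep]       # horizon clears all event times
  time <- pmin(t_ev, cens)
  event <- as.numeric(t_ev <= cens)
  horizon <- 55
  auc <- time_dependent_auc(time, event, x, horizon, n_boot = 0)$auc
  ci <- harrell_cindex(time, event, x)
  expect_lt(abs(auc - ci), 0.02)
})

test_that("validation reports carry the full panel shape", {
  fx <- ushape_fixture()
  rep <- validation_report(fx$nn, fx$test_nn, horizons = c(24, 60),
                           n_boot = 50, seed = 1)
  expect_s3_class(rep, "validation_report")
  expect_true(rep$cindex > 0.5)
  expect_length(rep$horizons, 2)
  h1 <- rep$horizons[[1]]
  expect_true(h1$auc >= 0 && h1$auc <= 1)
  expect_gte(h1$ici, 0)
  expect_identical(sum(h1$deciles$n), nrow(fx$test_nn))
})
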