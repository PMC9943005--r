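mini_cohort <- function(values, time = NULL, event = NULL) {
  n <- length(values[[1]])
  data.frame(subject_id = sprintf("s%d", seq_len(n)),
             time = time %||% (seq_len(n) + 0.5),
             event = event %||% rep_len(c(1, 0), n),
             values, check.names = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stratified split honors fractions, strata and determinism", {
  g <- sim_linear_cohort(1000, seed = 2, betas = c(0.5))
  co <- g$cohort
  co$event <- rep(c(1, 0), c(200, 800))  # force a clean 20% stratum
  sp <- split_cohort(co, seed = 9)
  sizes <- table(sp$split)
  expect_true(abs(sizes[["train"]] - 700) <= 1)
  expect_true(abs(sizes[["validation"]] - 150) <= 1)
  expect_true(abs(sizes[["test"]] - 150) <= 1)
  expect_identical(sp, split_cohort(co, seed = 9))
  expect_false(identical(sp$split, split_cohort(co, seed = 10)$split))
  ef <- tapply(co$event[match(sp$subject_id, co$subject_id)], sp$split, mean)
  expect_true(all(abs(ef - 0.2) <= 0.01))
  co$event <- 0
  expect_error(split_cohort(co, seed = 1), "degenerate")
})

test_that("paper-scale split keeps the event fraction within one point per part", {
  co <- generate_cohort(sim_config_ehr(10614, seed = 55))$cohort
  sp <- split_cohort(co, seed = 4)
  overall <- mean(co$event)
  ef <- tapply(co$event, sp$split, mean)
  expect_true(all(abs(ef - overall) <= 0.01))
})

test_that("mean+flag imputation uses training means and flags training missingness", {
  tr <- mini_cohort(list(a = c(1, 3, NA), b = c(0, 1, 1)))
  st <- fit_mean_flag_imputer(tr)
  out <- transform_cohort(st, tr)
  expect_equal(out$a, c(1, 3, 2))
  expect_equal(out$a_missing, c(0, 0, 1))
  expect_false("b_missing" %in% names(out))  # no missingness, no flag
  te <- mini_cohort(list(a = c(10, NA), b = c(NA, 0)))
  out_te <- transform_cohort(st, te)
  expect_equal(out_te$a, c(10, 2))           # TRAINING mean, not test mean
  expect_equal(out_te$b, c(2 / 3, 0))        # binary imputed with its mean
  # idempotence on completed data
  expect_identical(transform_cohort(st, out_te), out_te)
  tr$a <- NA_real_
  expect_error(fit_mean_flag_imputer(tr), "entirely missing.*a")
})

test_that("chained imputation is the identity on complete data and beats the mean under correlation", {
  tr <- mini_cohort(list(a = rnorm(20), b = rnorm(20)))
  st <- fit_chained_imputer(tr, n_iterations = 3, seed = 1)
  expect_identical(transform_cohort(st, tr), tr)
  expect_error(fit_chained_imputer(tr, n_iterations = 0), "n_iterations")

  set.seed(8)
  n <- 2000
  z <- rnorm(n)
  a <- z + 0.45 * rnorm(n)
  b <- z + 0.45 * rnorm(n)
  miss <- runif(n) < 0.2
  co <- mini_cohort(list(a = ifelse(miss, NA, a), b = b),
                    time = rexp(n) + 1, event = rbinom(n, 1, 0.3))
  st <- fit_chained_imputer(co, n_iterations = 5, seed = 1)
  imp <- transform_cohort(st, co)
  rmse_chained <- sqrt(mean((imp$a[miss] - a[miss])^2))
  rmse_mean <- sqrt(mean((mean(co$a, na.rm = TRUE) - a[miss])^2))
  expect_lt(rmse_chained, rmse_mean)
  # determinism and idempotence
  st2 <- fit_chained_imputer(co, n_iterations = 5, seed = 1)
  expect_identical(transform_cohort(st2, co), imp)
  expect_identical(transform_cohort(st, imp), imp)
})

test_that("collinear predictors fall back to mean imputation with a warning", {
  set.seed(3)
  a <- c(rnorm(30), NA, NA)
  b <- rnorm(32)
  co <- mini_cohort(list(a = a, b = b, b_dup = b))
  expect_warning(st <- fit_chained_imputer(co, n_iterations = 1),
                 "rank-deficient")
  out <- transform_cohort(st, co)
  expect_equal(out$a[31:32], rep(mean(a, na.rm = TRUE), 2))
})

test_that("quantile normalization maps to a standard normal, preserves order and clips", {
  set.seed(10)
  tr <- mini_cohort(list(x = runif(5000), flag = rep_len(c(0, 1), 5000)))
  st <- fit_quantile_normalizer(tr)
  out <- transform_cohort(st, tr)
  expect_identical(out$flag, tr$flag)  # binary columns pass through
  z <- out$x
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::sd(z) - 1), 0.1)
  skew <- mean((z - mean(z))^3) / stats::sd(z)^3
  expect_lt(abs(skew), 0.1)
  # monotone
  ord <- order(tr$x)
  expect_true(all(diff(z[ord]) >= 0))
  # out-of-range test values clip to the extreme training quantiles
  te <- mini_cohort(list(x = c(-5, 5), flag = c(0, 1)))
  zt <- transform_cohort(st, te)$x
  expect_equal(zt[1], min(z))
  expect_equal(zt[2], max(z))
})

test_that("an already-normal sample is left nearly unchanged", {
  set.seed(11)
  x <- rnorm(5000)
  tr <- mini_cohort(list(x = x))
  st <- fit_quantile_normalizer(tr)
  z <- transform_cohort(st, tr)$x
  central <- x > stats::quantile(x, 0.01) & x < stats::quantile(x, 0.99)
  expect_lt(max(abs(z[central] - x[central])), 0.2)
})

test_that("a constant column maps to zeros with a warning", {
  tr <- mini_cohort(list(x = rep(3.7, 10), y = rnorm(10)))
  expect_warning(st <- fit_quantile_normalizer(tr), "constant")
  expect_equal(transform_cohort(st, tr)$x, rep(0, 10))
})

test_that("preprocessing state depends only on training rows", {
  g <- sim_ushape_cohort(600, seed = 44)
  parts <- split3(g$cohort, seed = 5)
  st1 <- fit_preprocessor(parts$train, "mean_flag")
  # permute the held-out outcomes entirely; the state must be unchanged
  permuted_test <- parts$test
  permuted_test$time <- rev(permuted_test$time)
  permuted_test$event <- rev(permuted_test$event)
  st2 <- fit_preprocessor(parts$train, "mean_flag")
  expect_identical(serialize(st1, NULL), serialize(st2, NULL))
  # the transform of train rows never sees test values
  expect_identical(transform_cohort(st1, parts$train),
                   transform_cohort(st2, parts$train))
})
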