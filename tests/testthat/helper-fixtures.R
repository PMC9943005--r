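# Shared simulation fixtures, built once per test run and cached, so the
# expensive neural fits are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

std_covariates <- function(p, prefix = "x") {
  lapply(seq_len(p), function(j) covariate_spec(paste0(prefix, j), "continuous"))
}

# linear proportional-hazards cohort: betas on standard-normal covariates
sim_linear_cohort <- function(n = 3000, seed = 7,
                              betas = c(0.8, -0.5, 0.3, 0, 0)) {
  covs <- std_covariates(length(betas))
  eff <- Map(function(j, b) {
    effect_spec(paste0("x", j), if (b != 0) "linear" else "none", coef = b)
  }, seq_along(betas), betas)
  generate_cohort(sim_config(n, covs, unname(eff),
    baseline = list(shape = 1.2, scale = 150),
    censoring = list(max_followup = 100, entry_window = 50), seed = seed))
}

# dominant U-shaped effect plus one weak linear effect
sim_ushape_cohort <- function(n = 3000, seed = 19) {
  covs <- c(std_covariates(4), list(covariate_spec("u", "continuous")))
  eff <- list(effect_spec("u", "u_shape", coef = 0.9, center = 0),
              effect_spec("x1", "linear", coef = 0.3))
  generate_cohort(sim_config(n, covs, eff,
    baseline = list(shape = 1.2, scale = 60),
    censoring = list(max_followup = 100, entry_window = 50), seed = seed))
}

# one informative covariate among pure noise (selection checks)
sim_signal_noise <- function(n = 400, seed = 1, n_noise = 10, beta = 1.2) {
  covs <- c(list(covariate_spec("signal", "continuous")),
            lapply(seq_len(n_noise), function(j) {
              covariate_spec(paste0("noise", j), "continuous")
            }))
  generate_cohort(sim_config(n, covs,
    list(effect_spec("signal", "linear", coef = beta)),
    baseline = list(shape = 1.2, scale = 60),
    censoring = list(max_followup = 100, entry_window = 50), seed = seed))
}

split3 <- function(cohort, seed = 3) {
  sp <- split_cohort(cohort, seed = seed)
  list(train = cohort[sp$split == "train", ],
       validation = cohort[sp$split == "validation", ],
       test = cohort[sp$split == "test", ])
}

# linear cohort with fitted linear Cox MLE and PHNN (shared by the recovery
# and equivalence checks)
linear_fixture <- function() fixture("linear_fit", function() {
  g <- sim_linear_cohort()
  parts <- split3(g$cohort)
  cox <- fit_cox_mle(parts$train)
  nn <- train_phnn(parts$train, parts$validation, seed = 11)
  c(list(truth = g$truth, cohort = g$cohort), parts,
    list(cox = cox, nn = nn))
})

# U-shape cohort preprocessed the neural way, with both models fitted
ushape_fixture <- function() fixture("ushape_fit", function() {
  g <- sim_ushape_cohort()
  parts <- split3(g$cohort)
  prep <- fit_preprocessor(parts$train, "mean_flag")
  trn <- transform_cohort(prep, parts$train)
  van <- transform_cohort(prep, parts$validation)
  ten <- transform_cohort(prep, parts$test)
  cox <- fit_cox_mle(parts$train)
  nn <- train_phnn(trn, van, seed = 11)
  c(list(truth = g$truth, cohort = g$cohort, prep = prep,
         train_nn = trn, validation_nn = van, test_nn = ten),
    parts, list(cox = cox, nn = nn))
})

# paper-like cohort without missingness, for oracle-calibration checks
ehr_complete_fixture <- function() fixture("ehr_complete", function() {
  cfg <- sim_config_ehr(10000, seed = 77)
  for (i in seq_along(cfg$covariates)) cfg$covariates[[i]]$missing_rate <- 0
  g <- generate_cohort(cfg)
  risk24 <- 1 - true_survival_at(g$truth, g$cohort[covariate_names(g$cohort)], 24)
  list(cohort = g$cohort, truth = g$truth, risk24 = risk24)
})

# a deterministic linear hazard model with known coefficients (no fitting)
manual_cox_model <- function(beta, baseline_time = c(1, 2),
                             baseline_cumhaz = c(0.1, 0.3), max_time = 10) {
  structure(list(beta = beta, lambda = 0, alpha = NA_real_,
                 baseline = structure(list(time = baseline_time,
                                           cumhaz = baseline_cumhaz,
                                           max_time = max_time),
                                      class = "breslow_baseline"),
                 schema = names(beta)),
            class = c("cox_hazard_model", "hazard_model"))
}
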