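#' Configuration for the end-to-end two-model pipeline
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL` with `cohort`
#'   supplied for real-cohort mode.
#' @param cohort Optional pre-built cohort data frame (real-cohort mode).
#' @param fractions Train/validation/test fractions.
#' @param horizons Evaluation horizons in months (default 2 and 5 years).
#' @param selection `NULL` to skip forward selection, or a list with
#'   `candidates` (default: all covariates), `stop_rule` (see
#'   [forward_select()]) and `arch`/`hyper` for the reduced selection models.
#' @param cox List of penalized-model settings (`alpha`, `k`, `rule`).
#' @param phnn List with `arch` and `hyper` for the final neural model.
#' @param n_boot Bootstrap resamples for AUC confidence intervals.
#' @param cv_folds Folds for the cross-validated c-index (0 skips it).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, cohort = NULL,
                       fractions = c(0.70, 0.15, 0.15),
                       horizons = c(24, 60), selection = NULL,
                       cox = list(alpha = 0.5, k = 10, rule = "one_se"),
                       phnn = list(arch = phnn_arch(), hyper = list()),
                       n_boot = 200, cv_folds = 0, seed = 1L) {
  if (is.null(sim) && is.null(cohort)) stop("provide either 'sim' or 'cohort'")
  if (any(horizons <= 0)) stop("horizons must be positive")
  if (!is.null(selection) && !is.null(selection$candidates) &&
      !is.null(cohort) &&
      !all(selection$candidates %in% covariate_names(cohort))) {
    stop("selection candidates include unknown covariate(s)")
  }
  structure(list(sim = sim, cohort = cohort, fractions = fractions,
                 horizons = horizons, selection = selection, cox = cox,
                 phnn = phnn, n_boot = n_boot, cv_folds = cv_folds,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full two-model prognostic pipeline
#'
#' simulate (or ingest) -> stratified split -> per-family preprocessing
#' (chained-equation imputation for the penalized linear model; mean+flag
#' imputation plus quantile normalization for the neural model) -> optional
#' forward feature selection on train/validation -> fit penalized Cox and
#' PHNN -> partial-dependence curves -> side-by-side validation reports on
#' the held-out test set. The test rows are touched exactly once, at
#' evaluation; the `audit` log records which stage accessed which partition.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report artifacts are
#'   written there as CSV/JSON-like text files.
#' @return A `run_report` list: `selection` trace (or `NULL`),
#'   `cox_model`, `phnn_model`, `hazard_ratios`, `pdp` curves,
#'   `report_cox`, `report_phnn`, `comparison` (per-horizon AUC
#'   comparisons), the `split`, and the `audit` log.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  audit <- character(0)
  note <- function(...) audit <<- c(audit, paste0(...))

  if (!is.null(config$sim)) {
    gen <- generate_cohort(config$sim)
    cohort <- gen$cohort
    truth <- gen$truth
    note("simulate: generated ", nrow(cohort), " subjects")
  } else {
    cohort <- config$cohort
    truth <- NULL
    validate_cohort(cohort)
    note("ingest: read ", nrow(cohort), " subjects")
  }
  if (!is.null(config$selection) && !is.null(config$selection$candidates) &&
      !all(config$selection$candidates %in% covariate_names(cohort))) {
    stop("selection candidates include unknown covariate(s): ",
         paste(setdiff(config$selection$candidates, covariate_names(cohort)),
               collapse = ", "))
  }

  split <- split_cohort(cohort, config$fractions,
                        seed = stage_seed(config$seed, "split"))
  part <- function(which) cohort[split$split == which, , drop = FALSE]
  train <- part("train"); val <- part("validation"); test <- part("test")
  note("split: train/validation/test = ", nrow(train), "/", nrow(val), "/",
       nrow(test))

  # linear-model preprocessing: chained-equation imputation, natural scale
  prep_cox <- fit_preprocessor(train, "chained",
                               seed = stage_seed(config$seed, "prep_cox"))
  train_cox <- transform_cohort(prep_cox, train)
  test_cox <- transform_cohort(prep_cox, test)
  # neural-model preprocessing: mean+flag imputation, quantile normalization
  prep_nn <- fit_preprocessor(train, "mean_flag")
  train_nn <- transform_cohort(prep_nn, train)
  val_nn <- transform_cohort(prep_nn, val)
  test_nn <- transform_cohort(prep_nn, test)
  note("preprocess: states fitted on training rows only")

  selection <- NULL
  nn_features <- covariate_names(train_nn)
  if (!is.null(config$selection)) {
    sel_cfg <- config$selection
    candidates <- sel_cfg$candidates %||%
      grep("_missing$", covariate_names(train_nn), value = TRUE, invert = TRUE)
    factory <- phnn_factory(arch = sel_cfg$arch %||% phnn_arch(c(16L, 8L), 0.2),
                            hyper = sel_cfg$hyper %||% list(max_epochs = 60L,
                                                            patience = 10L),
                            validation = val_nn)
    selection <- forward_select(candidates, train_nn, val_nn, factory,
                                stop_rule = sel_cfg$stop_rule %||% list(),
                                seed = stage_seed(config$seed, "select"))
    flags <- paste0(selection$selected, "_missing")
    nn_features <- c(selection$selected,
                     intersect(flags, covariate_names(train_nn)))
    note("select: ", length(selection$selected), " features (",
         selection$stopping_reason, ")")
  }

  cox_model <- fit_linear_cox(train_cox,
                              alpha = config$cox$alpha %||% 0.5,
                              k = config$cox$k %||% 10,
                              rule = config$cox$rule %||% "one_se",
                              seed = stage_seed(config$seed, "cox"))
  note("fit-cox: lambda = ", signif(cox_model$lambda, 4), ", ",
       sum(cox_model$beta != 0), " nonzero coefficients")

  phnn_model <- train_phnn(train_nn, val_nn,
                           arch = config$phnn$arch %||% phnn_arch(),
                           hyper = config$phnn$hyper %||% list(),
                           covariates = nn_features,
                           seed = stage_seed(config$seed, "phnn"))
  note("fit-phnn: best epoch ", phnn_model$best_epoch,
       ", validation loss ", signif(phnn_model$best_val_loss, 6))

  pdp <- partial_dependence_all(phnn_model, train_nn)
  note("explain: PDP curves for ",
       length(unique(pdp$covariate)), " covariates (training rows)")

  report_cox <- validation_report(cox_model, test_cox,
                                  horizons = config$horizons,
                                  n_boot = config$n_boot,
                                  seed = stage_seed(config$seed, "eval_cox"))
  report_phnn <- validation_report(phnn_model, test_nn,
                                   horizons = config$horizons,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(config$seed, "eval_phnn"))
  comparison <- lapply(config$horizons, function(h) {
    cmp <- compare_auc(predict_log_hazard(phnn_model, test_nn),
                       predict_log_hazard(cox_model, test_cox),
                       test$time, test$event, h,
                       n_boot = max(100, config$n_boot),
                       seed = stage_seed(config$seed, paste0("cmp", h)))
    c(horizon = h, cmp)
  })
  note("evaluate: test rows scored once per model")

  cv <- NULL
  if (config$cv_folds >= 2) {
    cv <- list(
      cox = cv_cindex(function(tr, seed) {
        p <- fit_preprocessor(tr, "chained", seed = seed)
        fit_linear_cox(transform_cohort(p, tr), seed = seed,
                       alpha = config$cox$alpha %||% 0.5,
                       k = config$cox$k %||% 10)
      }, cohort_complete_for_cv(cohort, prep_cox),
      k = config$cv_folds, seed = stage_seed(config$seed, "cv_cox")))
    note("cv: ", config$cv_folds, "-fold c-index for the linear model")
  }

  report <- structure(list(selection = selection, cox_model = cox_model,
                           phnn_model = phnn_model,
                           hazard_ratios = hazard_ratio_table(cox_model),
                           pdp = pdp, report_cox = report_cox,
                           report_phnn = report_phnn, comparison = comparison,
                           cv = cv, split = split, truth = truth,
                           audit = audit),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

cohort_complete_for_cv <- function(cohort, prep) {
  transform_cohort(prep, cohort)
}

report_table <- function(report) {
  row <- function(name, rep) {
    h <- rep$horizons
    data.frame(model = name, cindex = rep$cindex,
               auc_2y = h[[1]]$auc, ici_2y = h[[1]]$ici,
               auc_5y = if (length(h) > 1) h[[2]]$auc else NA_real_,
               ici_5y = if (length(h) > 1) h[[2]]$ici else NA_real_)
  }
  rbind(row("COX", report$report_cox), row("PHNN", report$report_phnn))
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$hazard_ratios,
                   file.path(out_dir, "cox_hazard_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pdp, file.path(out_dir, "phnn_pdp.csv"),
                   row.names = FALSE)
  if (!is.null(report$selection)) {
    utils::write.csv(report$selection$table,
                     file.path(out_dir, "selection_trace.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report_table(report),
                   file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  for (nm in c("report_cox", "report_phnn")) {
    rep <- report[[nm]]
    for (hh in rep$horizons) {
      utils::write.csv(hh$deciles,
                       file.path(out_dir, paste0(nm, "_calibration_",
                                                 hh$horizon, "mo.csv")),
                       row.names = FALSE)
    }
  }
  writeLines(report$audit, file.path(out_dir, "audit.log"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Two-model prognostic pipeline report\n")
  cat("------------------------------------\n")
  print(report_table(x), row.names = FALSE, digits = 3)
  if (!is.null(x$selection)) {
    cat("\nSelected features (", length(x$selection$selected), "): ",
        paste(x$selection$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
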