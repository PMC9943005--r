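#' Event-stratified train/validation/test split
#'
#' Randomly partitions subjects into train/validation/test sets separately
#' within events and non-events so that every part carries approximately the
#' overall event fraction. Counts per part are fixed by largest-remainder
#' apportionment within each stratum, so part sizes deviate from the exact
#' fractions by at most one subject per stratum.
#'
#' @param cohort A cohort data frame.
#' @param fractions Numeric vector of three positive fractions summing to 1,
#'   in the order train, validation, test.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A data frame `subject_id`, `split` (factor with levels `train`,
#'   `validation`, `test`), with the fractions and seed stored as attributes.
#' @export
split_cohort <- function(cohort, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  validate_cohort(cohort)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive values summing to 1")
  }
  ne <- sum(cohort$event == 1)
  if (ne == 0L || ne == nrow(cohort)) {
    stop("degenerate cohort: all subjects are ", if (ne) "events" else "censored")
  }
  labels <- c("train", "validation", "test")
  assign <- character(nrow(cohort))
  set.seed(seed)
  for (ev in c(1, 0)) {
    idx <- which(cohort$event == ev)
    idx <- sample(idx)
    n_s <- length(idx)
    counts <- floor(n_s * fractions)
    rem <- n_s * fractions - counts
    short <- n_s - sum(counts)
    if (short > 0) {
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
    }
    assign[idx] <- rep(labels, counts)
  }
  out <- data.frame(subject_id = cohort$subject_id,
                    split = factor(assign, levels = labels),
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Mean imputation with missingness flag columns
#'
#' Fits the imputation strategy used for the neural hazard model: every
#' covariate's missing values are replaced by its training-sample mean
#' (binary covariates included, giving a value in \[0, 1\]), and for each
#' covariate with any training missingness a binary `<name>_missing` flag
#' column records which values were originally absent.
#'
#' @param train Training cohort (fit uses training rows only).
#' @return A `mean_flag_imputer` preprocessing state for [transform_cohort()].
#' @export
fit_mean_flag_imputer <- function(train) {
  validate_cohort(train)
  cv <- covariate_names(train)
  means <- vapply(cv, function(nm) mean(train[[nm]], na.rm = TRUE), numeric(1))
  all_missing <- cv[!is.finite(means)]
  if (length(all_missing)) {
    stop("covariate(s) entirely missing in training data: ",
         paste(all_missing, collapse = ", "))
  }
  flag_for <- cv[vapply(cv, function(nm) anyNA(train[[nm]]), logical(1))]
  structure(list(means = means, flag_for = flag_for, covariates = cv),
            class = c("mean_flag_imputer", "preprocess_state"))
}

#' Apply a fitted preprocessing state to a cohort
#'
#' Transforms are deterministic given the fitted state, use only training
#' statistics, and are idempotent for the imputers (re-applying to already
#' completed data is a no-op). The quantile normalizer is a one-shot
#' coordinate change and is applied once per pipeline.
#'
#' @param state A fitted preprocessing state.
#' @param cohort Cohort data frame to transform.
#' @param ... Unused.
#' @return The transformed cohort.
#' @export
transform_cohort <- function(state, cohort, ...) UseMethod("transform_cohort")

#' @rdname transform_cohort
#' @export
transform_cohort.mean_flag_imputer <- function(state, cohort, ...) {
  validate_cohort(cohort)
  for (nm in state$flag_for) {
    flag <- paste0(nm, "_missing")
    if (!flag %in% names(cohort)) cohort[[flag]] <- as.numeric(is.na(cohort[[nm]]))
  }
  for (nm in state$covariates) {
    miss <- is.na(cohort[[nm]])
    if (any(miss)) cohort[[nm]][miss] <- state$means[[nm]]
  }
  cohort
}

#' Chained-equation imputation
#'
#' Iterative per-covariate regression imputation in the style of chained
#' equations: starting from mean initialization, each covariate with training
#' missingness is regressed on all other covariates over its observed
#' training rows (linear regression for continuous covariates, logistic
#' regression for binary ones) and its missing entries are replaced by the
#' conditional-mean prediction; the cycle repeats `n_iterations` times. A
#' single completed dataset is produced (no multiple-imputation pooling).
#' Perfectly collinear predictors make the regression rank deficient; the
#' affected covariate then falls back to mean imputation with a warning.
#'
#' @param train Training cohort.
#' @param n_iterations Number of full cycles, `>= 1`.
#' @param seed Integer seed (the conditional-mean variant is deterministic;
#'   the seed is recorded in the state).
#' @return A `chained_imputer` preprocessing state for [transform_cohort()].
#' @export
fit_chained_imputer <- function(train, n_iterations = 10, seed = 1L) {
  validate_cohort(train)
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("n_iterations must be >= 1")
  }
  cv <- covariate_names(train)
  if (length(cv) < 2L) stop("chained imputation requires >= 2 covariates")
  means <- vapply(cv, function(nm) mean(train[[nm]], na.rm = TRUE), numeric(1))
  all_missing <- cv[!is.finite(means)]
  if (length(all_missing)) {
    stop("covariate(s) entirely missing in training data: ",
         paste(all_missing, collapse = ", "))
  }
  binary <- vapply(cv, function(nm) is_binary_column(train[[nm]]), logical(1))
  has_na <- vapply(cv, function(nm) anyNA(train[[nm]]), logical(1))

  x <- as.matrix(train[cv])
  miss_mask <- is.na(x)
  for (nm in cv) x[miss_mask[, nm], nm] <- means[[nm]]

  models <- stats::setNames(vector("list", length(cv)), cv)
  for (iter in seq_len(n_iterations)) {
    for (nm in cv[has_na]) {
      obs <- !miss_mask[, nm]
      preds <- setdiff(cv, nm)
      df <- as.data.frame(x[, preds, drop = FALSE])
      df$.y <- x[, nm]
      fit <- tryCatch({
        if (binary[[nm]]) {
          suppressWarnings(stats::glm(.y ~ ., data = df[obs, , drop = FALSE],
                                      family = stats::binomial()))
        } else {
          stats::lm(.y ~ ., data = df[obs, , drop = FALSE])
        }
      }, error = function(e) NULL)
      co <- if (is.null(fit)) NULL else stats::coef(fit)
      if (is.null(co) || anyNA(co)) {
        warning("chained imputer: rank-deficient model for '", nm,
                "'; falling back to mean imputation", call. = FALSE)
        models[[nm]] <- list(type = "mean", mean = means[[nm]])
        x[miss_mask[, nm], nm] <- means[[nm]]
      } else {
        type <- if (binary[[nm]]) "logistic" else "linear"
        models[[nm]] <- list(type = type, coef = co, predictors = preds)
        if (any(miss_mask[, nm])) {
          eta <- co[1] + x[miss_mask[, nm], preds, drop = FALSE] %*% co[-1]
          x[miss_mask[, nm], nm] <- if (binary[[nm]]) stats::plogis(eta) else eta
        }
      }
    }
  }
  structure(list(means = means, models = models, covariates = cv,
                 binary = binary, has_na = has_na,
                 n_iterations = n_iterations, seed = seed),
            class = c("chained_imputer", "preprocess_state"))
}

#' @rdname transform_cohort
#' @export
transform_cohort.chained_imputer <- function(state, cohort, ...) {
  validate_cohort(cohort)
  cv <- state$covariates
  missing_cols <- setdiff(cv, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks covariate(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(cohort[cv])
  miss_mask <- is.na(x)
  if (!any(miss_mask)) return(cohort)
  for (nm in cv) x[miss_mask[, nm], nm] <- state$means[[nm]]
  for (iter in seq_len(state$n_iterations)) {
    for (nm in cv[state$has_na]) {
      m <- state$models[[nm]]
      if (is.null(m) || !any(miss_mask[, nm])) next
      if (m$type == "mean") {
        x[miss_mask[, nm], nm] <- m$mean
      } else {
        eta <- m$coef[1] + x[miss_mask[, nm], m$predictors, drop = FALSE] %*% m$coef[-1]
        x[miss_mask[, nm], nm] <- if (m$type == "logistic") stats::plogis(eta) else eta
      }
    }
  }
  cohort[cv] <- as.data.frame(x)
  cohort
}

#' Quantile normalization to a standard normal
#'
#' Fits a rank-preserving monotone map per continuous covariate: the
#' training empirical quantile function (1000 probability points, linear
#' interpolation) composed with the standard-normal quantile function.
#' Binary covariates and missingness-flag columns pass through unchanged.
#' Out-of-range values clip to the extreme training quantiles; a constant
#' training column maps to all zeros with a warning.
#'
#' @param train Training cohort with complete continuous covariates
#'   (impute first).
#' @param n_quantiles Number of empirical quantile knots.
#' @return A `quantile_normalizer` preprocessing state for [transform_cohort()].
#' @export
fit_quantile_normalizer <- function(train, n_quantiles = 1000) {
  validate_cohort(train)
  cv <- covariate_names(train)
  cont <- cv[!vapply(cv, function(nm) is_binary_column(train[[nm]]), logical(1))]
  probs <- seq(0, 1, length.out = n_quantiles)
  maps <- list()
  for (nm in cont) {
    x <- train[[nm]]
    if (anyNA(x)) stop("quantile normalizer requires complete training data; '",
                       nm, "' has missing values (impute first)")
    qs <- unname(stats::quantile(x, probs, type = 7))
    if (max(qs) - min(qs) < .Machine$double.eps) {
      warning("quantile normalizer: constant column '", nm,
              "' mapped to zeros", call. = FALSE)
      maps[[nm]] <- list(constant = TRUE)
    } else {
      maps[[nm]] <- list(constant = FALSE, quantiles = qs, probs = probs)
    }
  }
  structure(list(maps = maps, continuous = cont, covariates = cv),
            class = c("quantile_normalizer", "preprocess_state"))
}

#' @rdname transform_cohort
#' @export
transform_cohort.quantile_normalizer <- function(state, cohort, ...) {
  validate_cohort(cohort)
  p_clip <- c(5e-4, 1 - 5e-4)
  for (nm in names(state$maps)) {
    if (!nm %in% names(cohort)) next
    m <- state$maps[[nm]]
    if (m$constant) {
      cohort[[nm]] <- rep(0, nrow(cohort))
    } else {
      p <- stats::approx(m$quantiles, m$probs, xout = cohort[[nm]],
                         rule = 2, ties = "ordered")$y
      cohort[[nm]] <- stats::qnorm(pmin(pmax(p, p_clip[1]), p_clip[2]))
    }
  }
  cohort
}

#' Fit a model-family preprocessing pipeline
#'
#' Convenience composition of the per-family strategies: `"mean_flag"`
#' (mean imputation + missingness flags + quantile normalization of the
#' continuous covariates — the neural-model recipe) or `"chained"`
#' (chained-equation imputation, covariates left on their natural scale —
#' the penalized linear-model recipe, which standardizes internally).
#'
#' @param train Training cohort; all states are fitted on it alone.
#' @param strategy `"mean_flag"` or `"chained"`.
#' @param normalize Whether to quantile-normalize continuous covariates
#'   (default `TRUE` for `"mean_flag"`, `FALSE` for `"chained"`).
#' @param n_iterations,seed Passed to [fit_chained_imputer()].
#' @return A `preprocessor` state for [transform_cohort()].
#' @export
fit_preprocessor <- function(train, strategy = c("mean_flag", "chained"),
                             normalize = NULL, n_iterations = 10, seed = 1L) {
  strategy <- match.arg(strategy)
  normalize <- normalize %||% (strategy == "mean_flag")
  imputer <- switch(strategy,
    mean_flag = fit_mean_flag_imputer(train),
    chained = fit_chained_imputer(train, n_iterations = n_iterations, seed = seed))
  completed <- transform_cohort(imputer, train)
  normalizer <- if (normalize) fit_quantile_normalizer(completed) else NULL
  structure(list(imputer = imputer, normalizer = normalizer, strategy = strategy),
            class = c("preprocessor", "preprocess_state"))
}

#' @rdname transform_cohort
#' @export
transform_cohort.preprocessor <- function(state, cohort, ...) {
  out <- transform_cohort(state$imputer, cohort)
  if (!is.null(state$normalizer)) out <- transform_cohort(state$normalizer, out)
  out
}
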