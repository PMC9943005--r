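#' Greedy forward feature selection by validation concordance
#'
#' At each step, every remaining candidate is added in turn to the selected
#' set, a model is fitted on the training set via `model_factory`, and the
#' Harrell c-index on the validation set is recorded; the candidate with the
#' highest validation c-index is kept (ties broken by alphabetical candidate
#' name). Selection stops when the best achievable gain over the running
#' best c-index stays below `min_gain` for `patience_steps` consecutive
#' steps, when `max_features` is reached, or when no candidates remain. The
#' test set is never consulted.
#'
#' @param candidates Candidate covariate names.
#' @param train,validation Disjoint cohorts with complete covariates.
#' @param model_factory `function(train_cohort, features, seed)` returning an
#'   object with a [predict_log_hazard()] method. A factory error on one
#'   candidate skips that candidate with a warning.
#' @param stop_rule List of `min_gain` (default 0.002), `patience_steps`
#'   (default 2) and `max_features` (default 25).
#' @param initial Covariates treated as already selected before the first
#'   step; if the candidates offer nothing beyond them, the trace stops
#'   immediately with reason `"no candidates"`.
#' @param seed Integer seed; step k uses the derived seed `seed + k` for
#'   every candidate, so any selected subset can be re-fitted reproducibly.
#' @return A `selection_trace`: `selected` (ordered names), `best_cindex`
#'   per step, the full per-step per-candidate c-index `table`, and
#'   `stopping_reason`.
#' @export
forward_select <- function(candidates, train, validation, model_factory,
                           stop_rule = list(), initial = character(0),
                           seed = 1L) {
  stop_rule <- utils::modifyList(list(min_gain = 0.002, patience_steps = 2,
                                      max_features = 25), stop_rule)
  if (!length(candidates)) stop("at least one candidate is required")
  if (any(duplicated(candidates))) stop("candidates must be unique")
  shared <- intersect(train$subject_id, validation$subject_id)
  if (length(shared)) stop("train and validation sets must be disjoint")

  selected <- initial
  best_overall <- -Inf
  best_cindex <- numeric(0)
  trace_rows <- list()
  low_gain_streak <- 0
  stopping_reason <- NULL
  step <- 0L

  repeat {
    remaining <- sort(setdiff(candidates, selected))
    if (!length(remaining)) {
      stopping_reason <- if (step == 0L) "no candidates" else "candidates exhausted"
      break
    }
    if (length(selected) >= stop_rule$max_features) {
      stopping_reason <- "max_features reached"
      break
    }
    step <- step + 1L
    step_seed <- seed + step
    cidx <- rep(NA_real_, length(remaining))
    for (j in seq_along(remaining)) {
      feats <- c(selected, remaining[j])
      cidx[j] <- tryCatch({
        model <- model_factory(train, feats, seed = step_seed)
        harrell_cindex(validation$time, validation$event,
                       predict_log_hazard(model, validation))
      }, error = function(e) {
        warning("forward_select: skipping candidate '", remaining[j],
                "' (", conditionMessage(e), ")", call. = FALSE)
        NA_real_
      })
    }
    trace_rows[[step]] <- data.frame(step = step, candidate = remaining,
                                     cindex = cidx, stringsAsFactors = FALSE)
    if (all(is.na(cidx))) {
      stopping_reason <- "all candidates failed"
      break
    }
    pick <- which.max(cidx)   # remaining is alphabetically sorted: ties
    step_best <- cidx[pick]   # resolve to the first name
    gain <- step_best - best_overall
    selected <- c(selected, remaining[pick])
    best_cindex <- c(best_cindex, step_best)
    if (is.finite(best_overall) && gain < stop_rule$min_gain) {
      low_gain_streak <- low_gain_streak + 1
      if (low_gain_streak >= stop_rule$patience_steps) {
        stopping_reason <- "no substantial improvement"
        break
      }
    } else {
      low_gain_streak <- 0
    }
    best_overall <- max(best_overall, step_best)
  }

  structure(list(selected = setdiff(selected, initial),
                 initial = initial, best_cindex = best_cindex,
                 table = if (length(trace_rows)) do.call(rbind, trace_rows)
                         else data.frame(step = integer(), candidate = character(),
                                         cindex = numeric()),
                 stopping_reason = stopping_reason, seed = seed,
                 stop_rule = stop_rule),
            class = "selection_trace")
}

#' Model factories for forward selection and cross-validation
#'
#' `cox_factory()` builds unpenalized proportional-hazards fits;
#' `phnn_factory()` builds (optionally reduced-epoch) neural hazard models —
#' during selection only the candidate ranking matters, so a shorter
#' training schedule can be used and the final model refitted fully.
#'
#' @param arch A [phnn_arch()] for the neural factory.
#' @param hyper Training hyperparameters for the neural factory.
#' @param validation Validation cohort used for early stopping inside the
#'   neural factory.
#' @return A `function(train, features = NULL, seed)` returning a fitted
#'   hazard model.
#' @export
cox_factory <- function() {
  function(train, features = NULL, seed = 1L) {
    fit_cox_mle(train, covariates = features %||% covariate_names(train))
  }
}

#' @rdname cox_factory
#' @export
phnn_factory <- function(arch = phnn_arch(), hyper = list(), validation) {
  force(validation)
  function(train, features = NULL, seed = 1L) {
    train_phnn(train, validation, arch = arch, hyper = hyper,
               covariates = features %||% covariate_names(train), seed = seed)
  }
}
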