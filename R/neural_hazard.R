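#' Feed-forward architecture of the proportional-hazards network
#'
#' The network parametrizes the log-relative-hazard `f(X)`; the relative
#' hazard is `r(X) = exp(f(X))`. Defaults follow the reference architecture:
#' four hidden layers of 128, 64, 32 and 15 rectified-linear units with
#' activation dropout 0.5 after every hidden layer (never on the input), and
#' a single linear output unit.
#'
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives a
#'   purely linear score (the Cox special case).
#' @param dropout Dropout rate in \[0, 1) applied after each hidden
#'   activation during training; disabled at inference.
#' @return A `phnn_arch` list.
#' @export
phnn_arch <- function(hidden = c(128L, 64L, 32L, 15L), dropout = 0.5) {
  if (length(hidden) && (any(hidden < 1) || any(hidden != round(hidden)))) {
    stop("hidden widths must be positive integers")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(hidden = as.integer(hidden), dropout = dropout),
            class = "phnn_arch")
}

# He-style initialization; consumes the current RNG stream.
phnn_init <- function(p, hidden) {
  widths <- c(p, hidden, 1L)
  params <- list(W = list(), b = list())
  for (l in seq_len(length(widths) - 1L)) {
    fan_in <- widths[l]
    params$W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L],
                                         sd = sqrt(2 / fan_in)),
                            fan_in, widths[l + 1L])
    params$b[[l]] <- rep(0, widths[l + 1L])
  }
  params
}

# Forward pass. masks = NULL for inference (dropout off); for training a
# list of inverted-dropout masks per hidden layer. Returns the score vector
# and the cached pre/post activations for backprop.
phnn_forward <- function(params, x, masks = NULL, keep = 1) {
  n_layer <- length(params$W)
  a <- x
  cache <- list(a = vector("list", n_layer), z = vector("list", n_layer))
  for (l in seq_len(n_layer)) {
    cache$a[[l]] <- a
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
    if (l < n_layer) {
      cache$z[[l]] <- z
      a <- pmax(z, 0)
      if (!is.null(masks)) a <- a * masks[[l]] / keep
    } else {
      a <- z
    }
  }
  list(score = drop(a), cache = cache)
}

# Gradient of the event-averaged negative Breslow partial likelihood with
# respect to the score vector. `rs_groups` is the precomputed tie-group
# structure of the (already sorted) training outcomes.
phnn_loss_grad <- function(scores, rs_groups) {
  s <- scores - mean(scores)
  es <- exp(s)
  tail_sum <- rev(cumsum(rev(es)))
  s0 <- tail_sum[rs_groups$first_idx]          # risk-set sums per tie group
  d <- rs_groups$d
  keep <- d > 0
  d_tot <- sum(d)
  nll <- -(sum(s * rs_groups$event) - sum(d[keep] * log(s0[keep]))) / d_tot
  # cumulative hazard increments up to and including each subject's group
  inc <- ifelse(keep, d / s0, 0)
  a_cum <- cumsum(inc)[rs_groups$group]
  grad <- (es * a_cum - rs_groups$event) / d_tot
  list(nll = nll, grad = grad)
}

phnn_group_structure <- function(time, event) {
  grp <- cumsum(!duplicated(time))
  first_idx <- which(!duplicated(time))
  d <- as.numeric(tapply(event, grp, sum))
  list(group = grp, first_idx = first_idx, d = d, event = event)
}

phnn_backward <- function(params, cache, masks, keep, dscore) {
  n_layer <- length(params$W)
  grads <- list(W = vector("list", n_layer), b = vector("list", n_layer))
  delta <- matrix(dscore, ncol = 1)
  for (l in rev(seq_len(n_layer))) {
    grads$W[[l]] <- crossprod(cache$a[[l]], delta)
    grads$b[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(masks)) delta <- delta * masks[[l - 1L]] / keep
      delta <- delta * (cache$z[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(m) m * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the proportional-hazards neural network
#'
#' Full-batch minimization of the event-averaged negative Breslow partial
#' likelihood by Adam, with inverted dropout during training and early
#' stopping on the validation partial likelihood (dropout disabled for
#' validation). The returned model carries the weights of the epoch with the
#' best validation loss and a Breslow baseline cumulative hazard computed
#' from the training scores under those weights. Training rows are put in a
#' canonical order internally, so the result is invariant to the row order
#' of the input.
#'
#' @param train,validation Preprocessed cohorts (complete covariates; the
#'   validation set must contain at least one event).
#' @param arch A [phnn_arch()].
#' @param hyper List of `lr` (learning rate, default 0.02 — in the
#'   full-batch regime each epoch is a single Adam step, so the rate is
#'   larger and the epoch budget longer than minibatch conventions),
#'   `max_epochs` (default 1000) and `patience` (non-improving epochs
#'   tolerated before stopping, default 100).
#' @param covariates Covariate subset (default: all covariate columns of
#'   `train`).
#' @param seed Integer seed for weight initialization and dropout; fixed
#'   seed gives a reproducible fit.
#' @return A `phnn_model`: weights, architecture, covariate `schema`,
#'   training `log` (epoch, train and validation loss), `best_epoch`, and
#'   the Breslow `baseline`.
#' @export
train_phnn <- function(train, validation, arch = phnn_arch(),
                       hyper = list(), covariates = NULL, seed = 1L) {
  validate_cohort(train, require_complete = TRUE)
  validate_cohort(validation, require_complete = TRUE)
  if (sum(validation$event) < 1) stop("validation set must contain >= 1 event")
  hyper <- utils::modifyList(list(lr = 0.02, max_epochs = 1000L, patience = 100L),
                             hyper)
  covariates <- covariates %||% covariate_names(train)
  x <- covariate_matrix(train, covariates)
  # canonical row order: outcomes then covariates, so that permuting input
  # rows cannot change the fit
  ord <- do.call(order, c(list(train$time, train$event),
                          as.data.frame(x)))
  x <- x[ord, , drop = FALSE]
  tt <- train$time[ord]; ev <- train$event[ord]
  rs <- phnn_group_structure(tt, ev)
  xv <- covariate_matrix(validation, covariates)
  vt <- validation$time; ve <- validation$event

  keep <- 1 - arch$dropout
  n <- nrow(x)
  set.seed(seed)
  params <- phnn_init(ncol(x), arch$hidden)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())

  for (epoch in seq_len(hyper$max_epochs)) {
    masks <- NULL
    if (arch$dropout > 0 && length(arch$hidden)) {
      masks <- lapply(arch$hidden, function(w) {
        matrix(stats::runif(n * w) >= arch$dropout, n, w)
      })
    }
    fw <- phnn_forward(params, x, masks, keep)
    lg <- phnn_loss_grad(fw$score, rs)
    if (!is.finite(lg$nll)) {
      stop("PHNN training diverged (loss is not finite); lower the learning rate")
    }
    grads <- phnn_backward(params, fw$cache, masks, keep, lg$grad)
    upd <- adam_step(params, grads, opt, hyper$lr)
    params <- upd$params; opt <- upd$state

    val_score <- phnn_forward(params, xv)$score
    if (any(!is.finite(val_score))) {
      stop("PHNN training diverged (loss is not finite); lower the learning rate")
    }
    val_loss <- -partial_loglik_scores(val_score, vt, ve) / sum(ve)
    if (!is.finite(val_loss)) {
      stop("PHNN training diverged (loss is not finite); lower the learning rate")
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = lg$nll,
                                 val_loss = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
    } else if (epoch - best$epoch > hyper$patience) {
      break
    }
  }

  train_scores <- phnn_forward(best$params, x)$score
  structure(list(params = best$params, arch = arch, schema = covariates,
                 log = log, best_epoch = best$epoch,
                 best_val_loss = best$loss, hyper = hyper, seed = seed,
                 baseline = breslow_baseline(tt, ev, train_scores)),
            class = c("phnn_model", "hazard_model"))
}

#' @rdname predict_log_hazard
#' @export
predict_log_hazard.phnn_model <- function(model, newdata, ...) {
  newdata <- as.data.frame(newdata)
  have <- intersect(model$schema, names(newdata))
  missing_cols <- setdiff(model$schema, names(newdata))
  if (length(missing_cols)) {
    stop("schema mismatch; missing covariate(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- covariate_matrix(newdata, model$schema)
  if (anyNA(x)) stop("newdata covariates must be complete")
  phnn_forward(model$params, x)$score
}
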