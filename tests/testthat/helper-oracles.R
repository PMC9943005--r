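# Independent brute-force oracles. These deliberately share no code with the
# package: pair enumeration, explicit risk sets, hand-rolled product-limit.

bf_cindex <- function(times, events, scores) {
  n <- length(times)
  conc <- 0; ties <- 0; comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (events[i] == 1 && times[i] < times[j]) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        if (scores[i] == scores[j]) ties <- ties + 1
      }
    }
  }
  (conc + 0.5 * ties) / comp
}

bf_partial_loglik <- function(scores, time, event) {
  ll <- 0
  for (et in sort(unique(time[event == 1]))) {
    risk <- which(time >= et)
    dead <- which(time == et & event == 1)
    ll <- ll + sum(scores[dead]) - length(dead) * log(sum(exp(scores[risk])))
  }
  ll
}

# product-limit estimate evaluated at time t
bf_km_at <- function(times, events, t) {
  s <- 1
  for (et in sort(unique(times[events == 1]))) {
    if (et > t) break
    n_risk <- sum(times >= et)
    d <- sum(times == et & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Nelson-Aalen cumulative hazard at time t
bf_nelson_aalen_at <- function(times, events, t) {
  h <- 0
  for (et in sort(unique(times[events == 1]))) {
    if (et > t) break
    h <- h + sum(times == et & events == 1) / sum(times >= et)
  }
  h
}

# IPCW cumulative/dynamic AUC by explicit pair summation; censoring survival
# G computed with the hand product-limit on the censoring indicator
bf_ipcw_auc <- function(times, events, scores, horizon) {
  eps <- 1e-9
  g_at <- function(t) bf_km_at(times, 1 - events, t)
  case <- which(times <= horizon & events == 1)
  ctrl <- which(times > horizon)
  num <- 0; den <- 0
  for (i in case) {
    wi <- 1 / g_at(times[i] - eps)
    for (j in ctrl) {
      wj <- 1 / g_at(horizon)
      num <- num + wi * wj * ((scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j]))
      den <- den + wi * wj
    }
  }
  num / den
}

# Youden-optimal threshold metrics from an explicit confusion table scan
bf_threshold <- function(p, y) {
  best <- NULL
  for (cut in sort(unique(p))) {
    tp <- sum(p >= cut & y); fn <- sum(p < cut & y)
    tn <- sum(p < cut & !y); fp <- sum(p >= cut & !y)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    if (is.null(best) || sens + spec - 1 > best$youden + 1e-12) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                   youden = sens + spec - 1)
    }
  }
  best
}
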