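# Brute-force reference implementations used as independent oracles.
# Each one enumerates the definition directly (explicit risk sets,
# exhaustive pair loops, hand product-limits); none shares code with the
# package implementations.

oracle_coxnll <- function(h, time, event) {
  ev <- which(event == 1)
  total <- 0
  for (i in ev) {
    rs <- which(time >= time[i])          # explicit risk set
    total <- total + (h[i] - log(sum(exp(h[rs]))))
  }
  -total / length(ev)
}

oracle_breslow <- function(h, time, event) {
  ut <- sort(unique(time[event == 1]))
  inc <- vapply(ut, function(t) {
    d <- sum(event == 1 & time == t)
    d / sum(exp(h[time >= t]))
  }, 1)
  list(event_times = ut, cumulative_hazard = cumsum(inc))
}

oracle_cindex <- function(time, event, pred) {
  num <- 0
  npairs <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        npairs <- npairs + 1
        if (pred[i] < pred[j]) num <- num + 1
        else if (pred[i] == pred[j]) num <- num + 0.5
      }
    }
  }
  if (npairs == 0) return(list(c_index = NA_real_, n_pairs = 0L))
  list(c_index = num / npairs, n_pairs = npairs)
}

oracle_mae <- function(time, event, pred) {
  keep <- event == 1
  if (!any(keep)) return(NA_real_)
  mean(abs(pred[keep] - time[keep]))
}

oracle_horizon_acc <- function(time, event, pred, horizon) {
  correct <- 0
  n_eval <- 0
  for (i in seq_along(time)) {
    truth <- if (time[i] >= horizon) "alive"
      else if (event[i] == 1) "dead"
      else NA               # censored before the horizon: unknowable
    if (is.na(truth)) next
    n_eval <- n_eval + 1
    predicted <- if (pred[i] >= horizon) "alive" else "dead"
    if (truth == predicted) correct <- correct + 1
  }
  if (n_eval == 0) return(list(accuracy = NA_real_, n = 0L))
  list(accuracy = correct / n_eval, n = n_eval)
}

oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = c(0, ut), survival = c(1, surv))
}

# Two-group log-rank from the O-E/V contingency table at each distinct
# event time.
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n_at <- sum(time >= t)
    n1_at <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1_at / n_at
    if (n_at > 1) {
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) /
        (n_at - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq,
       p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

oracle_mip <- function(arr) {
  d <- dim(arr)
  out <- matrix(-Inf, d[1], d[3])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        out[i, k] <- max(out[i, k], arr[i, j, k])
  out
}

# Random censored survival instance (with ties when tie_grid is small).
random_instance <- function(n, seed, tie_grid = NULL) {
  set.seed(seed)
  time <- if (is.null(tie_grid)) rexp(n, 1 / 100) + 1 else
    sample(tie_grid, n, replace = TRUE)
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  list(records = surv_records(seq_len(n), time, event),
       time = time, event = event,
       h = rnorm(n), pred = rexp(n, 1 / 300))
}
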