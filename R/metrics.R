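#' Harrell's concordance index over predicted survival times
#'
#' Fraction of comparable subject pairs whose predicted survival times are
#' ordered like their observed times.  A pair (i, j) is comparable when
#' `T_i < T_j` and subject i died (`E_i = 1`); pairs tied on observed time
#' are not comparable.  Tied predictions score 0.5.  Predictions are
#' oriented as survival times: larger prediction = longer predicted
#' survival (negate risk scores before calling).
#'
#' @param records a [surv_records] data frame.
#' @param predicted_times numeric predictions aligned with `records`.
#' @return List with `c_index` (NA with a message when no pair is
#'   comparable) and `n_pairs`.
#' @export
concordance_index <- function(records, predicted_times) {
  assert_aligned(records, predicted_times, "predicted times")
  tt <- records$time
  ee <- records$event
  pp <- predicted_times
  n <- length(tt)
  comp <- outer(tt, tt, "<") & matrix(ee == 1, n, n)
  n_pairs <- sum(comp)
  if (n_pairs == 0) {
    return(list(c_index = NA_real_, n_pairs = 0L))
  }
  dlt <- outer(pp, pp, "-")       # p_i - p_j
  score <- sum((dlt[comp] < 0) + 0.5 * (dlt[comp] == 0))
  list(c_index = score / n_pairs, n_pairs = as.integer(n_pairs))
}

#' Mean absolute error on uncensored subjects
#'
#' Mean of |predicted - observed| survival time over subjects whose death
#' was observed; censored subjects are excluded because their recorded
#' time underestimates the true survival time.
#'
#' @inheritParams concordance_index
#' @return List with `mae_days` (NA when no subject is uncensored) and
#'   `n_uncensored`.
#' @export
mae_uncensored <- function(records, predicted_times) {
  assert_aligned(records, predicted_times, "predicted times")
  ev <- records$event == 1
  if (!any(ev)) {
    return(list(mae_days = NA_real_, n_uncensored = 0L))
  }
  list(mae_days = mean(abs(predicted_times[ev] - records$time[ev])),
       n_uncensored = as.integer(sum(ev)))
}

#' Classification accuracy of survival status at a horizon
#'
#' A subject's true status at the horizon is "alive" when `T >= horizon`
#' (regardless of the event flag) and "dead" when the death was observed
#' before the horizon; subjects censored before the horizon have unknown
#' status and are excluded from the denominator.  The predicted status is
#' `predicted_time >= horizon`.
#'
#' @inheritParams concordance_index
#' @param horizon_days evaluation horizon in days (730 for 2-year, 1825
#'   for 5-year status).
#' @return List with `accuracy` (NA when no subject is evaluable) and
#'   `n_evaluable`.
#' @export
horizon_status_accuracy <- function(records, predicted_times,
                                    horizon_days = 730) {
  assert_aligned(records, predicted_times, "predicted times")
  stopifnot(horizon_days > 0)
  tt <- records$time
  ee <- records$event
  evaluable <- tt >= horizon_days | ee == 1
  if (!any(evaluable)) {
    return(list(accuracy = NA_real_, n_evaluable = 0L))
  }
  true_alive <- tt[evaluable] >= horizon_days
  pred_alive <- predicted_times[evaluable] >= horizon_days
  list(accuracy = mean(true_alive == pred_alive),
       n_evaluable = as.integer(sum(evaluable)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function under right
#' censoring, as a step curve over the distinct observed event times
#' (computed via [survival::survfit()]).
#'
#' @param records a [surv_records] data frame.
#' @return A `survival_curve` data frame with `time` and `survival`,
#'   starting at (0, 1).
#' @export
kaplan_meier <- function(records) {
  assert_records(records)
  if (nrow(records) == 0) stop("no records")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = records[, c("time", "event")])
  keep <- sf$n.event > 0
  out <- data.frame(time = c(0, sf$time[keep]),
                    survival = c(1, sf$surv[keep]))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival distributions: at each
#' distinct event time the observed minus hypergeometrically expected
#' events in group A are accumulated, and the statistic
#' \eqn{(\sum O - E)^2 / \sum V} is referred to a chi-square with 1 df
#' (computed via [survival::survdiff()]).
#'
#' @param group_a,group_b [surv_records] data frames.
#' @return List with `statistic` and `p_value`; both NA (with a message)
#'   when no event occurs in either group.
#' @export
log_rank_test <- function(group_a, group_b) {
  assert_records(group_a)
  assert_records(group_b)
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must be nonempty")
  }
  if (sum(group_a$event) + sum(group_b$event) == 0) {
    message("log-rank undefined: no events in either group")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  df <- data.frame(
    time = c(group_a$time, group_b$time),
    event = c(group_a$event, group_b$event),
    grp = rep(c("a", "b"), c(nrow(group_a), nrow(group_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Full evaluation bundle for one set of predictions
#'
#' Computes the four reporting metrics at once: C-index, MAE on
#' uncensored subjects, and the 2- and 5-year survival-status accuracies,
#' with the per-metric evaluable counts.
#'
#' @inheritParams concordance_index
#' @param horizons 2- and 5-year horizons in days.
#' @return Object of class `metric_bundle`: list with `c_index`,
#'   `mae_days`, `acc_2yr`, `acc_5yr` and an `n_eval` vector
#'   (`pairs`, `uncensored`, `evaluable_2yr`, `evaluable_5yr`).
#' @export
metric_bundle <- function(records, predicted_times,
                          horizons = c(730, 1825)) {
  ci <- concordance_index(records, predicted_times)
  mae <- mae_uncensored(records, predicted_times)
  a2 <- horizon_status_accuracy(records, predicted_times, horizons[1])
  a5 <- horizon_status_accuracy(records, predicted_times, horizons[2])
  out <- list(c_index = ci$c_index, mae_days = mae$mae_days,
              acc_2yr = a2$accuracy, acc_5yr = a5$accuracy,
              n_eval = c(pairs = ci$n_pairs,
                         uncensored = mae$n_uncensored,
                         evaluable_2yr = a2$n_evaluable,
                         evaluable_5yr = a5$n_evaluable))
  class(out) <- "metric_bundle"
  out
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf(
    "<metric_bundle> C-index %.3f | MAE %.0f days | acc 2yr %.3f | acc 5yr %.3f\n",
    x$c_index, x$mae_days, x$acc_2yr, x$acc_5yr))
  cat(sprintf("  n: %s\n",
              paste(names(x$n_eval), x$n_eval, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Serialize per-fold metric bundles as a delimited table
#'
#' One row per fold plus a `mean` and `sd` footer, mirroring the layout
#' of cross-validated performance tables.
#'
#' @param bundles list of [metric_bundle()] objects.
#' @param path optional file path; when given the table is written as
#'   tab-delimited text.
#' @return The table as a data frame, invisibly when written.
#' @export
metric_table <- function(bundles, path = NULL) {
  stopifnot(length(bundles) > 0)
  rows <- do.call(rbind, lapply(bundles, function(b) {
    data.frame(c_index = b$c_index, mae_days = b$mae_days,
               acc_2yr = b$acc_2yr, acc_5yr = b$acc_5yr)
  }))
  rows$fold <- seq_len(nrow(rows))
  footer <- data.frame(
    c_index = c(mean(rows$c_index), sd(rows$c_index)),
    mae_days = c(mean(rows$mae_days), sd(rows$mae_days)),
    acc_2yr = c(mean(rows$acc_2yr), sd(rows$acc_2yr)),
    acc_5yr = c(mean(rows$acc_5yr), sd(rows$acc_5yr)),
    fold = c("mean", "sd"))
  out <- rbind(rows, footer)[, c("fold", "c_index", "mae_days",
                                 "acc_2yr", "acc_5yr")]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}
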