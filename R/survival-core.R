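#' Negative log partial likelihood (Cox / DeepSurv loss)
#'
#' The training loss shared by every risk model: the negative log partial
#' likelihood of the Cox proportional-hazards model, averaged over events,
#' plus an optional L2 penalty supplied by the caller as the squared
#' parameter norm.  Tied event times are handled with the Breslow
#' convention: subjects tied at an event time share the full risk set
#' \eqn{R(t) = \{j : T_j \ge t\}}.
#'
#' @param risks numeric vector of log relative hazards \eqn{h_i}, aligned
#'   with `records`.
#' @param records a [surv_records] data frame (or any data frame with
#'   `time` and `event` columns) aligned with `risks`.
#' @param l2_weight nonnegative penalty weight.
#' @param param_norm_sq squared L2 norm of the model parameters being
#'   penalized (0 when unused).
#' @return Scalar loss
#'   \deqn{-\frac{1}{D}\sum_{i: E_i=1}\Big[h_i - \log\!\!\sum_{j: T_j \ge T_i}
#'   e^{h_j}\Big] + \lambda\,\|\theta\|^2,}
#'   where \eqn{D} is the number of events in the batch.
#' @seealso [coxnll_grad()] for the analytic gradient.
#' @export
coxnll <- function(risks, records, l2_weight = 0, param_norm_sq = 0) {
  assert_aligned(records, risks)
  stopifnot(l2_weight >= 0, param_norm_sq >= 0)
  if (any(!is.finite(risks))) stop("risk scores must be finite")
  d <- sum(records$event)
  if (d == 0) stop("degenerate batch: no events; resample or skip")
  parts <- coxnll_parts(risks, records$time, records$event)
  -sum(parts$h_event - parts$log_denom) / d + l2_weight * param_norm_sq
}

#' Gradient of the Cox loss with respect to the risk scores
#'
#' Analytic gradient of [coxnll()] (at `l2_weight = 0`) with respect to
#' each log relative hazard; this is what flows into network
#' backpropagation.
#'
#' @inheritParams coxnll
#' @return Numeric vector, same length as `risks`.
#' @export
coxnll_grad <- function(risks, records) {
  assert_aligned(records, risks)
  d <- sum(records$event)
  if (d == 0) stop("degenerate batch: no events; resample or skip")
  time <- records$time
  event <- records$event
  o <- order(time, decreasing = TRUE)
  ts <- time[o]; hs <- risks[o]; es <- event[o]
  m <- max(hs)
  w <- exp(hs - m)
  cw <- cumsum(w)
  grp <- cumsum(!duplicated(ts))
  last <- stats::ave(seq_along(ts), grp, FUN = max)
  first <- stats::ave(seq_along(ts), grp, FUN = min)
  s_tilde <- cw[last]                 # risk-set sums in exp(-m) units
  b <- ifelse(es == 1, 1 / s_tilde, 0)
  a <- rev(cumsum(rev(b)))[first]     # sum over events with T_i <= T_q
  g_sorted <- -(es - w * a) / d
  g <- numeric(length(risks))
  g[o] <- g_sorted
  g
}

# Shared pieces of the partial likelihood, computed with a max-subtracted
# log-sum-exp over cumulative risk sets.
coxnll_parts <- function(h, time, event) {
  o <- order(time, decreasing = TRUE)
  ts <- time[o]; hs <- h[o]; es <- event[o]
  m <- max(hs)
  cw <- cumsum(exp(hs - m))
  grp <- cumsum(!duplicated(ts))
  last <- stats::ave(seq_along(ts), grp, FUN = max)
  ev <- es == 1
  list(h_event = hs[ev], log_denom = log(cw[last][ev]) + m)
}

#' Fit a multivariate Cox proportional-hazards model
#'
#' Standard tabular CPH fit (Efron tie correction) on an encoded design
#' matrix, via Newton--Raphson maximization of the partial likelihood.
#' Backed by [survival::coxph()]; this function adds design-matrix
#' validation, a rank check that names the offending column, and a
#' uniform return type.
#'
#' @param design numeric design matrix, rows aligned with `records`
#'   (see [encode_design()]).
#' @param records a [surv_records] data frame aligned with `design`.
#' @param tol convergence tolerance passed to the fitter.
#' @param max_iter maximum Newton--Raphson iterations.
#' @return An object of class `cox_fit`: list with `coefficients`,
#'   `standard_errors` (Wald, from the inverse observed information),
#'   `log_likelihood`, `converged`, `n`, `n_events`.
#' @export
fit_cph <- function(design, records, tol = 1e-9, max_iter = 25) {
  design <- as.matrix(design)
  assert_records(records)
  if (nrow(design) != nrow(records)) {
    stop("design rows not aligned with records")
  }
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  zero_col <- which(apply(design, 2, function(z) all(z == 0)))
  if (length(zero_col)) {
    stop(sprintf("design column '%s' is constant zero",
                 colnames(design)[zero_col[1]]))
  }
  qrd <- qr(cbind(1, design))
  if (qrd$rank < ncol(design) + 1) {
    dep <- setdiff(seq_len(ncol(design) + 1), qrd$pivot[seq_len(qrd$rank)])
    bad <- colnames(design)[min(dep) - 1]
    stop(sprintf(
      "singular information matrix: column '%s' is linearly dependent", bad))
  }
  df <- as.data.frame(design)
  names(df) <- make.names(colnames(design))
  df$.time <- records$time
  df$.event <- records$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(names(df)[seq_len(ncol(design))], collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = tol,
                                                      iter.max = max_iter)),
    warning = function(w) {
      if (grepl("Ran out of iterations|did not converge",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (fit$iter > max_iter) converged <- FALSE
  beta <- unname(fit$coefficients)
  if (anyNA(beta)) {
    bad <- colnames(design)[which(is.na(beta))[1]]
    stop(sprintf(
      "singular information matrix: column '%s' dropped by the fitter", bad))
  }
  out <- list(coefficients = stats::setNames(beta, colnames(design)),
              standard_errors = stats::setNames(
                sqrt(diag(fit$var)), colnames(design)),
              log_likelihood = fit$loglik[2L],
              converged = converged,
              n = nrow(design),
              n_events = sum(records$event))
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, loglik = %.3f, converged = %s\n",
              x$n, x$n_events, x$log_likelihood, x$converged))
  z <- x$coefficients / x$standard_errors
  print(data.frame(coef = x$coefficients, se = x$standard_errors,
                   z = z, p = 2 * pnorm(-abs(z))))
  invisible(x)
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Given fitted log relative hazards on a training cohort, estimates the
#' cumulative baseline hazard \eqn{H_0(t)} with increments
#' \eqn{d(t) / \sum_{j: T_j \ge t} e^{h_j}} at each distinct observed
#' event time, where \eqn{d(t)} is the number of deaths at \eqn{t}.
#' Risk scores are clipped to \eqn{\pm 50} before exponentiation.
#'
#' @inheritParams coxnll
#' @return An object of class `baseline_hazard`: list with `event_times`
#'   (strictly increasing) and `cumulative_hazard` (nondecreasing).
#' @export
breslow_baseline <- function(risks, records) {
  assert_aligned(records, risks)
  if (sum(records$event) == 0) stop("no events: baseline hazard undefined")
  h <- pmin(pmax(risks, -50), 50)
  time <- records$time
  event <- records$event
  o <- order(time, decreasing = TRUE)
  ts <- time[o]; ws <- exp(h[o]); es <- event[o]
  grp <- cumsum(!duplicated(ts))
  last <- stats::ave(seq_along(ts), grp, FUN = max)
  cw <- cumsum(ws)
  gfirst <- !duplicated(ts)
  d_by_grp <- tapply(es, grp, sum)
  s_by_grp <- cw[last][gfirst]
  t_by_grp <- ts[gfirst]
  keep <- d_by_grp > 0
  inc <- (d_by_grp / s_by_grp)[keep]
  tt <- t_by_grp[keep]
  o2 <- order(tt)
  out <- list(event_times = unname(tt[o2]),
              cumulative_hazard = unname(cumsum(inc[o2])))
  class(out) <- "baseline_hazard"
  out
}

#' Per-subject survival curve from a baseline hazard and a risk score
#'
#' \eqn{S(t \mid x) = \exp(-H_0(t)\, e^{h})}, evaluated at the baseline's
#' event times and prepended with \eqn{S(0) = 1}.
#'
#' @param baseline a [breslow_baseline()] object.
#' @param risk scalar log relative hazard for the subject.
#' @return Object of class `survival_curve`: data frame with `time` and
#'   `survival` columns.
#' @export
survival_curve <- function(baseline, risk) {
  stopifnot(inherits(baseline, "baseline_hazard"), length(risk) == 1,
            is.finite(risk))
  s <- exp(-baseline$cumulative_hazard * exp(min(max(risk, -50), 50)))
  out <- data.frame(time = c(0, baseline$event_times),
                    survival = c(1, s))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median residual life from a survival curve
#'
#' The predicted absolute survival time: the first time at which the
#' subject's survival function crosses 0.5, linearly interpolated between
#' the bracketing curve points.  If the curve never reaches 0.5 over its
#' observed range, an exponential tail with rate
#' \eqn{-\log S(t_{last}) / t_{last}} is fitted to the last observed
#' survival value, the median is read off that tail, capped at `horizon`,
#' and the result is flagged as extrapolated.
#'
#' @param curve a [survival_curve()] object (or data frame with `time`,
#'   `survival`).
#' @param horizon cap for extrapolated predictions, in days
#'   (default 10 years).
#' @return List with `time` (days) and `extrapolated` (logical).
#' @export
median_survival_time <- function(curve, horizon = 3650) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0, horizon > 0)
  tt <- curve$time
  ss <- curve$survival
  j <- which(ss <= 0.5)[1]
  if (!is.na(j)) {
    if (j == 1L) return(list(time = tt[1], extrapolated = FALSE))
    t_star <- tt[j - 1] + (ss[j - 1] - 0.5) / (ss[j - 1] - ss[j]) *
      (tt[j] - tt[j - 1])
    return(list(time = t_star, extrapolated = FALSE))
  }
  s_last <- ss[length(ss)]
  t_last <- tt[length(tt)]
  rate <- if (t_last > 0) -log(s_last) / t_last else 0
  t_med <- if (rate > 0) log(2) / rate else Inf
  list(time = min(t_med, horizon), extrapolated = TRUE)
}

#' Predicted median survival times for a vector of risk scores
#'
#' Vectorized bridge from model risk scores to absolute times: builds the
#' per-subject survival curve against a training-fold Breslow baseline and
#' extracts the median residual life for each subject.
#'
#' @param baseline a [breslow_baseline()] object fitted on training data.
#' @param risks numeric vector of log relative hazards.
#' @inheritParams median_survival_time
#' @return Data frame with columns `time` and `extrapolated`.
#' @export
predict_median_times <- function(baseline, risks, horizon = 3650) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  h0 <- baseline$cumulative_hazard
  tt <- c(0, baseline$event_times)
  res <- vapply(risks, function(h) {
    s <- c(1, exp(-h0 * exp(min(max(h, -50), 50))))
    m <- median_survival_time(data.frame(time = tt, survival = s),
                              horizon = horizon)
    c(m$time, as.numeric(m$extrapolated))
  }, numeric(2))
  data.frame(time = res[1, ], extrapolated = res[2, ] > 0)
}

#' Write / read a survival curve as two-column delimited text
#'
#' @param curve a [survival_curve()] object.
#' @param path file path.
#' @return `write_survival_curve` returns `path` invisibly;
#'   `read_survival_curve` returns a `survival_curve`.
#' @export
write_survival_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  utils::write.table(curve[, c("time", "survival")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_curve
#' @export
read_survival_curve <- function(path) {
  out <- utils::read.delim(path)
  stopifnot(all(c("time", "survival") %in% names(out)))
  class(out) <- c("survival_curve", "data.frame")
  out
}
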