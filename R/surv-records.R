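#' Follow-up records
#'
#' Container for right-censored overall-survival follow-up: one row per
#' subject with the observed time (days from diagnosis to death or last
#' follow-up) and the event indicator (1 = death observed, 0 = censored).
#'
#' @param subject_id identifiers, any atomic type; coerced to character.
#' @param time positive follow-up times in days.
#' @param event event indicators, 0/1 (or logical).
#' @return A `data.frame` of class `surv_records` with columns
#'   `subject_id`, `time`, `event`.
#' @examples
#' surv_records(c("a", "b"), c(120, 430), c(1, 0))
#' @export
surv_records <- function(subject_id, time, event) {
  if (length(time) != length(event) ||
      length(subject_id) != length(time)) {
    stop("subject_id, time and event must have equal length")
  }
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("follow-up times must be finite and > 0")
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicators must be 0 or 1")
  }
  out <- data.frame(subject_id = as.character(subject_id),
                    time = time, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("surv_records", "data.frame")
  out
}

#' @export
print.surv_records <- function(x, n = 6, ...) {
  cat(sprintf("<surv_records> %d subjects, %d events (%.1f%% censored)\n",
              nrow(x), sum(x$event), 100 * mean(x$event == 0)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("# ... with %d more rows\n", nrow(x) - n))
  invisible(x)
}

assert_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  invisible(records)
}

assert_aligned <- function(records, values, what = "risk scores") {
  assert_records(records)
  if (nrow(records) != length(values)) {
    stop(sprintf("%s (%d) not aligned with records (%d)",
                 what, length(values), nrow(records)))
  }
  invisible(NULL)
}
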