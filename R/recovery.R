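# Scoring detection output against a generator's ground truth.

# Greedy one-to-one matching of detected to true times within `tol_s`.
match_times <- function(detected, truth, tol_s) {
  used <- logical(length(detected))
  err <- rep(NA_real_, length(truth))
  for (i in seq_along(truth)) {
    if (length(detected) == 0) break
    d <- abs(detected - truth[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      err[i] <- detected[j] - truth[i]
    }
  }
  list(err = err, matched_detected = used)
}

#' Score instability-event recovery against ground truth
#'
#' Matches detected zero-crossing times one-to-one to the injected event
#' zero-crossings within `tol_s` and reports recall, the matched timing
#' errors, and the false-event rate (unmatched detections per second of
#' recording).
#'
#' @param events data frame from [detect_instability_events()].
#' @param truth a `ground_truth` (from a synthetic `subject_recording`).
#' @param duration_s recording duration used for the false rate.
#' @param tol_s matching tolerance in seconds (default 0.05).
#' @return A list: `recall`, `n_true`, `n_detected`, `false_rate_hz`,
#'   `errors_s` (matched signed errors).
#' @export
score_event_recovery <- function(events, truth, duration_s, tol_s = 0.05) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- match_times(events$zero_crossing_time_s, truth$event_zero_crossings, tol_s)
  n_true <- length(truth$event_zero_crossings)
  list(
    recall = if (n_true == 0) NA_real_ else mean(!is.na(m$err)),
    n_true = n_true,
    n_detected = nrow(events),
    false_rate_hz = sum(!m$matched_detected) / duration_s,
    errors_s = m$err[!is.na(m$err)]
  )
}

#' Score N1 recovery against ground truth
#'
#' @param n1 data frame from [detect_n1()].
#' @param truth a `ground_truth`.
#' @param tol_s matching tolerance on trough times (default 0.025).
#' @return A list: `recall`, `n_true`, `n_detected`, `errors_s`.
#' @export
score_n1_recovery <- function(n1, truth, tol_s = 0.025) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- match_times(n1$time_s, truth$n1_times, tol_s)
  n_true <- length(truth$n1_times)
  list(
    recall = if (n_true == 0) NA_real_ else mean(!is.na(m$err)),
    n_true = n_true,
    n_detected = nrow(n1),
    errors_s = m$err[!is.na(m$err)]
  )
}
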