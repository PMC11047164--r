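# N1 and control trough detection on the cleaned fronto-central IC trace.

#' Baseline-correct an IC trace against its pre-task segment
#'
#' Subtracts the mean of the pre-task window (default -5..0 s before task
#' onset) from the whole trace and reports the window mean and SD. The SD is
#' the yardstick for the "at least 2 SD below baseline" trough criterion.
#'
#' @param ic IC `time_series` (arbitrary microvolt-scale units) that starts at
#'   or before the baseline window.
#' @param window length-2 numeric, baseline window in seconds (default
#'   `c(-5, 0)`).
#' @return A list with `ic` (the corrected `time_series`) and `stats` (class
#'   `baseline_stats`: `mean`, `sd`, `window`).
#' @export
baseline_correct <- function(ic, window = c(-5, 0)) {
  stopifnot(inherits(ic, "time_series"))
  idx <- ts_window_idx(ic, window[1], window[2])
  if (length(idx) < 2L) stop("baseline window is empty or degenerate", call. = FALSE)
  m <- mean(ic$values[idx])
  s <- stats::sd(ic$values[idx])
  corrected <- time_series(ic$values - m, fs = ic$fs, t0 = ic$t0, units = ic$units)
  stats <- structure(list(mean = m, sd = s, window = window), class = "baseline_stats")
  list(ic = corrected, stats = stats)
}

# Indices of local minima (strictly below the previous sample, no higher than
# the next; a plateau reports its first sample). Endpoints excluded.
local_min_idx <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] < v[i - 1] & v[i] <= v[i + 1]]
}

#' Detect N1 troughs time-locked before corrective zero-crossings
#'
#' For each instability event, searches the baseline-corrected IC trace in a
#' window before the COPv zero-crossing (default -250..-100 ms) for local
#' minima at least `k_sd` baseline SDs below the baseline mean, and selects
#' the most negative one (ties broken towards the earlier trough). Events
#' with no qualifying trough contribute no N1 and are dropped from the
#' instability set; events whose search window leaves the recording are
#' skipped with a warning.
#'
#' @param ic_corrected baseline-corrected IC `time_series`.
#' @param stats `baseline_stats` from [baseline_correct()].
#' @param events data frame from [detect_instability_events()].
#' @param search_window_ms length-2 numeric, window relative to each
#'   zero-crossing in ms (default `c(-250, -100)`).
#' @param k_sd depth criterion in baseline SDs (default 2).
#' @return A data frame with columns `time_s`, `amplitude`, `latency_ms`,
#'   `zero_crossing_time_s`, `peak_time_s`, one row per detected N1.
#' @export
detect_n1 <- function(ic_corrected, stats, events,
                      search_window_ms = c(-250, -100), k_sd = 2) {
  stopifnot(inherits(ic_corrected, "time_series"),
            inherits(stats, "baseline_stats"))
  if (diff(search_window_ms) <= 0 || any(search_window_ms >= 0)) {
    stop("`search_window_ms` must be an increasing interval before the zero-crossing",
         call. = FALSE)
  }
  v <- ic_corrected$values
  tt <- ts_times(ic_corrected)
  mins <- local_min_idx(v)
  depth_ok <- mins[v[mins] <= -k_sd * stats$sd]
  out <- list()
  if (nrow(events) > 0) {
    for (r in seq_len(nrow(events))) {
      zc <- events$zero_crossing_time_s[r]
      lo <- zc + search_window_ms[1] / 1000
      hi <- zc + search_window_ms[2] / 1000
      if (lo < ic_corrected$t0 - .t_eps || hi > ts_end(ic_corrected) + .t_eps) {
        warning(sprintf("N1 search window for event at %.3f s leaves the recording; skipped", zc))
        next
      }
      in_win <- depth_ok[tt[depth_ok] >= lo - .t_eps & tt[depth_ok] <= hi + .t_eps]
      if (length(in_win) == 0L) next
      best <- in_win[order(v[in_win], tt[in_win])][1]
      out[[length(out) + 1L]] <- data.frame(
        time_s = tt[best],
        amplitude = v[best],
        latency_ms = (zc - tt[best]) * 1000,
        zero_crossing_time_s = zc,
        peak_time_s = events$peak_time_s[r]
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(time_s = numeric(0), amplitude = numeric(0),
                      latency_ms = numeric(0), zero_crossing_time_s = numeric(0),
                      peak_time_s = numeric(0)))
  }
  do.call(rbind, out)
}

#' Harvest control troughs away from detected N1s
#'
#' All other local minima of the corrected IC trace that are at least `k_sd`
#' baseline SDs deep qualify as control-class centers, after excluding any
#' trough within `exclusion_ms` of a detected N1, thinning troughs closer
#' than `min_sep_ms` to each other (the deeper trough is kept), and dropping
#' troughs whose -300..+100 ms epoch would leave `epoch_bounds`.
#'
#' @param ic_corrected baseline-corrected IC `time_series`.
#' @param stats `baseline_stats`.
#' @param n1_times numeric vector of detected N1 times (s).
#' @param k_sd depth criterion in baseline SDs (default 2).
#' @param exclusion_ms half-width of the exclusion zone around each N1
#'   (default 300).
#' @param min_sep_ms minimum pairwise separation between kept controls
#'   (default 400).
#' @param search_bounds length-2 numeric: only troughs in this interval are
#'   considered (defaults to the task period, i.e. from 0 s to the end of the
#'   trace).
#' @param epoch_window_ms epoch extent used for the bounds check (default
#'   `c(-300, 100)`).
#' @param epoch_bounds length-2 numeric: interval the whole epoch must fit in
#'   (defaults to `search_bounds`).
#' @return A data frame with columns `time_s`, `amplitude`, sorted by time.
#' @export
detect_control_troughs <- function(ic_corrected, stats, n1_times, k_sd = 2,
                                   exclusion_ms = 300, min_sep_ms = 400,
                                   search_bounds = NULL,
                                   epoch_window_ms = c(-300, 100),
                                   epoch_bounds = NULL) {
  stopifnot(inherits(ic_corrected, "time_series"),
            inherits(stats, "baseline_stats"))
  if (is.null(search_bounds)) search_bounds <- c(0, ts_end(ic_corrected))
  if (is.null(epoch_bounds)) epoch_bounds <- search_bounds
  v <- ic_corrected$values
  tt <- ts_times(ic_corrected)
  cand <- local_min_idx(v)
  cand <- cand[v[cand] <= -k_sd * stats$sd]
  cand <- cand[tt[cand] >= search_bounds[1] - .t_eps &
                 tt[cand] <= search_bounds[2] + .t_eps]
  if (length(n1_times) > 0 && length(cand) > 0) {
    near_n1 <- vapply(tt[cand], function(t0) {
      any(abs(t0 - n1_times) <= exclusion_ms / 1000 + .t_eps)
    }, logical(1))
    cand <- cand[!near_n1]
  }
  # epoch must fit in bounds
  if (length(cand) > 0) {
    lo <- tt[cand] + epoch_window_ms[1] / 1000
    hi <- tt[cand] + epoch_window_ms[2] / 1000
    cand <- cand[lo >= epoch_bounds[1] - .t_eps & hi <= epoch_bounds[2] + .t_eps]
  }
  # thin by depth: deepest first, keep if far enough from everything kept
  kept <- integer(0)
  for (i in cand[order(v[cand], tt[cand])]) {
    if (length(kept) == 0L || all(abs(tt[i] - tt[kept]) >= min_sep_ms / 1000 - .t_eps)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  data.frame(time_s = tt[kept], amplitude = v[kept])
}

#' Extract labeled multichannel epochs around class centers
#'
#' Clips every channel (COPv, shear, head acceleration, TTB, corrected IC) to
#' the closed window `center + epoch_window_ms`. Channels keep their native
#' sampling rates (a 100 Hz channel contributes 41 samples to a -300..+100 ms
#' epoch). Centers whose window is not fully covered by every channel are
#' dropped.
#'
#' @param recording a `subject_recording`.
#' @param derived a `biomech_derived` from [derive_biomech()].
#' @param centers data frame with columns `time_s` and `label` (1 =
#'   instability, 0 = control).
#' @param ic_corrected baseline-corrected IC `time_series`.
#' @param epoch_window_ms length-2 numeric window in ms (default
#'   `c(-300, 100)`).
#' @return A list of `labeled_epoch` objects, each with `subject_id`,
#'   `center_time_s`, `label` and `traces` (named list of clipped
#'   `time_series`: `copv`, `sh`, `ha`, `ttb`, `ic`).
#' @export
extract_epochs <- function(recording, derived, centers, ic_corrected,
                           epoch_window_ms = c(-300, 100)) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(derived, "biomech_derived"))
  channels <- list(copv = derived$copv, sh = recording$shear_ap,
                   ha = recording$head_acc_ap, ttb = derived$ttb,
                   ic = ic_corrected)
  out <- list()
  if (nrow(centers) > 0) {
    ord <- order(centers$time_s)
    centers <- centers[ord, , drop = FALSE]
    for (r in seq_len(nrow(centers))) {
      ctr <- centers$time_s[r]
      lo <- ctr + epoch_window_ms[1] / 1000
      hi <- ctr + epoch_window_ms[2] / 1000
      ok <- all(vapply(channels, function(ch) {
        lo >= ch$t0 - .t_eps && hi <= ts_end(ch) + .t_eps
      }, logical(1)))
      if (!ok) next
      traces <- lapply(channels, ts_clip, from = lo, to = hi)
      out[[length(out) + 1L]] <- structure(
        list(subject_id = recording$subject_id, center_time_s = ctr,
             label = as.integer(centers$label[r]), traces = traces),
        class = "labeled_epoch"
      )
    }
  }
  out
}
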