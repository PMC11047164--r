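#' Rectangular anterior-posterior stability zone
#'
#' Anatomical foot limits along the AP axis, anterior positive, with the
#' origin at the subject's initial COP reference. The zone is fixed per
#' subject.
#'
#' @param anterior_limit_cm anterior boundary (> 0), cm.
#' @param posterior_limit_cm posterior boundary (< 0), cm.
#' @export
stability_zone <- function(anterior_limit_cm, posterior_limit_cm) {
  stopifnot_scalar(anterior_limit_cm)
  stopifnot_scalar(posterior_limit_cm)
  if (!(anterior_limit_cm > 0 && posterior_limit_cm < 0)) {
    stop("stability zone requires anterior limit > 0 > posterior limit",
         call. = FALSE)
  }
  structure(list(anterior_limit_cm = anterior_limit_cm,
                 posterior_limit_cm = posterior_limit_cm),
            class = "stability_zone")
}

#' COP velocity by three-point central difference
#'
#' Interior sample `i` receives `(x[i+1] - x[i-1]) * fs / 2`; the two
#' endpoints receive one-sided first differences so the series keeps its
#' length. The central difference introduces no time shift and is exact for
#' quadratic trajectories.
#'
#' @param cop a `time_series` of AP COP position (cm).
#' @return A `time_series` of COP velocity (cm/s) on the same time grid.
#' @export
compute_copv <- function(cop) {
  stopifnot(inherits(cop, "time_series"))
  x <- cop$values
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * cop$fs / 2
  v[1] <- (x[2] - x[1]) * cop$fs
  v[n] <- (x[n] - x[n - 1]) * cop$fs
  time_series(v, fs = cop$fs, t0 = cop$t0, units = "cm/s")
}

#' Subject-specific instability threshold from quiet stance
#'
#' Returns `k` times the sample standard deviation of COP velocity over the
#' quiet-stance reference window (by default the first 20 s of the task,
#' i.e. the first zero-gain trial).
#'
#' @param copv COP velocity `time_series` (cm/s).
#' @param quiet_window length-2 numeric, window in seconds; defaults to the
#'   first 20 s of the series.
#' @param k SD multiplier (default 3).
#' @return Threshold in cm/s.
#' @export
estimate_copv_threshold <- function(copv, quiet_window = NULL, k = 3) {
  stopifnot(inherits(copv, "time_series"))
  stopifnot_scalar(k)
  if (is.null(quiet_window)) quiet_window <- c(copv$t0, copv$t0 + 20)
  idx <- ts_window_idx(copv, quiet_window[1], quiet_window[2])
  if (length(idx) < 2L) stop("quiet window contains fewer than 2 samples", call. = FALSE)
  s <- stats::sd(copv$values[idx])
  thr <- k * s
  if (thr == 0) warning("degenerate quiet window: COPv SD is zero, threshold is 0")
  thr
}

#' Distance to the stability boundary in the direction of COP motion
#'
#' For each sample the distance from COP to the boundary the COP is currently
#' moving towards: `anterior - cop` when COPv > 0, `cop - posterior` when
#' COPv < 0, and the distance to the nearer boundary when COPv is exactly
#' zero. Samples outside the zone are clamped to 0 with a warning.
#'
#' @param cop COP position `time_series` (cm).
#' @param copv COP velocity `time_series`, aligned sample-for-sample.
#' @param zone a [stability_zone()].
#' @return A `time_series` of DTB (cm), non-negative.
#' @export
compute_dtb <- function(cop, copv, zone) {
  stopifnot(inherits(cop, "time_series"), inherits(copv, "time_series"),
            inherits(zone, "stability_zone"))
  if (length(cop) != length(copv) || abs(cop$t0 - copv$t0) > .t_eps ||
      cop$fs != copv$fs) {
    stop("`cop` and `copv` must share the same time grid", call. = FALSE)
  }
  x <- cop$values
  v <- copv$values
  to_ant <- zone$anterior_limit_cm - x
  to_post <- x - zone$posterior_limit_cm
  d <- ifelse(v > 0, to_ant, ifelse(v < 0, to_post, pmin(to_ant, to_post)))
  n_out <- sum(d < 0)
  if (n_out > 0) {
    warning(sprintf("COP outside stability zone at %d samples; DTB clamped to 0", n_out))
    d <- pmax(d, 0)
  }
  time_series(d, fs = cop$fs, t0 = cop$t0, units = "cm")
}

#' Time to the stability boundary
#'
#' `TTB = DTB / |COPv|`, with a velocity floor `eps_cm_s` guarding the
#' division and a cap `cap_s` bounding the result (a stationary COP would
#' otherwise yield infinite time to boundary).
#'
#' @param dtb DTB `time_series` (cm), non-negative.
#' @param copv aligned COP velocity `time_series` (cm/s).
#' @param cap_s upper bound on TTB in seconds (default 10).
#' @param eps_cm_s velocity floor in cm/s (default 0.1).
#' @return A `time_series` of TTB (s), in `(0, cap_s]`.
#' @export
compute_ttb <- function(dtb, copv, cap_s = 10, eps_cm_s = 0.1) {
  stopifnot(inherits(dtb, "time_series"), inherits(copv, "time_series"))
  stopifnot_scalar(cap_s); stopifnot_scalar(eps_cm_s)
  if (cap_s <= 0 || eps_cm_s <= 0) stop("`cap_s` and `eps_cm_s` must be positive", call. = FALSE)
  if (any(dtb$values < 0)) stop("DTB must be non-negative", call. = FALSE)
  if (length(dtb) != length(copv)) stop("`dtb` and `copv` must be aligned", call. = FALSE)
  ttb <- pmin(dtb$values / pmax(abs(copv$values), eps_cm_s), cap_s)
  time_series(ttb, fs = dtb$fs, t0 = dtb$t0, units = "s")
}

# Indices of local extrema of |v| (strictly greater in magnitude than the
# previous sample, at least as great as the next; a plateau reports its first
# sample). Endpoints are excluded.
local_peak_idx <- function(v) {
  m <- abs(v)
  n <- length(m)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[m[i] > m[i - 1] & m[i] >= m[i + 1]]
}

#' Detect instability events in COP velocity
#'
#' Finds large-amplitude local extrema of |COPv| above the subject threshold
#' and, for each, the first subsequent zero-crossing of COPv — the early
#' biomechanical sign of a corrective balance response. The zero-crossing is
#' localised at the first sample of opposite (or zero) sign, without
#' sub-sample interpolation. Peaks within `refractory_s` of a previously
#' accepted peak are dropped (one excursion, one event), as are peaks with no
#' subsequent zero-crossing before the end of the recording.
#'
#' @param copv COP velocity `time_series` (cm/s).
#' @param threshold positive threshold in cm/s (see
#'   [estimate_copv_threshold()]).
#' @param refractory_s minimum separation between accepted peaks in seconds.
#' @return A data frame with columns `peak_time_s`, `peak_copv_cm_s`,
#'   `zero_crossing_time_s`, one row per event, ordered by time.
#' @export
detect_instability_events <- function(copv, threshold, refractory_s = 1.0) {
  stopifnot(inherits(copv, "time_series"))
  stopifnot_scalar(threshold); stopifnot_scalar(refractory_s)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  v <- copv$values
  tt <- ts_times(copv)
  cand <- local_peak_idx(v)
  cand <- cand[abs(v[cand]) > threshold]
  out <- list()
  last_t <- -Inf
  for (i in cand) {
    if (tt[i] - last_t <= refractory_s) next
    s <- sign(v[i])
    after <- which(sign(v[(i + 1):length(v)]) != s)
    if (length(after) == 0L) next
    j <- i + after[1]
    last_t <- tt[i]
    out[[length(out) + 1L]] <- data.frame(
      peak_time_s = tt[i],
      peak_copv_cm_s = v[i],
      zero_crossing_time_s = tt[j]
    )
  }
  if (length(out) == 0L) {
    return(data.frame(peak_time_s = numeric(0), peak_copv_cm_s = numeric(0),
                      zero_crossing_time_s = numeric(0)))
  }
  do.call(rbind, out)
}

#' Derive all biomechanical series for one subject
#'
#' Convenience wrapper: COPv via central difference, the quiet-stance 3SD
#' threshold, DTB against the subject's stability zone, and capped TTB.
#'
#' @param recording a `subject_recording` (see [generate_subject()]).
#' @param k_sd threshold SD multiplier (default 3).
#' @param cap_s,eps_cm_s TTB cap and velocity floor (see [compute_ttb()]).
#' @param refractory_s event refractory period in seconds.
#' @param threshold optional override of the estimated threshold (cm/s).
#' @return A list of class `biomech_derived` with elements `copv`, `dtb`,
#'   `ttb` (all `time_series`), `threshold` (cm/s) and `events` (data frame
#'   from [detect_instability_events()]).
#' @export
derive_biomech <- function(recording, k_sd = 3, cap_s = 10, eps_cm_s = 0.1,
                           refractory_s = 1.0, threshold = NULL) {
  stopifnot(inherits(recording, "subject_recording"))
  copv <- compute_copv(recording$cop_ap)
  if (is.null(threshold)) {
    threshold <- estimate_copv_threshold(copv, k = k_sd)
  }
  zone <- stability_zone(recording$stability_limits_cm[["anterior"]],
                         recording$stability_limits_cm[["posterior"]])
  dtb <- compute_dtb(recording$cop_ap, copv, zone)
  ttb <- compute_ttb(dtb, copv, cap_s = cap_s, eps_cm_s = eps_cm_s)
  events <- detect_instability_events(copv, threshold, refractory_s = refractory_s)
  structure(list(copv = copv, dtb = dtb, ttb = ttb, threshold = threshold,
                 events = events),
            class = "biomech_derived")
}
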