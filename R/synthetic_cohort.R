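# Seeded synthetic standing-balance cohort generator.
#
# Emulates a continuous 180 s balance task of nine 20 s trials under
# sway-referenced support gains: bounded mean-reverting AP sway whose
# low-frequency amplitude scales with |gain|, sporadic instability events
# (a large COPv excursion followed by a corrective reversal), an N1 trough
# injected 100-250 ms before each corrective zero-crossing in a 1/f
# EEG-like independent-component trace, distractor troughs of comparable
# depth, and shear / head-acceleration channels that are noisy linear
# functions of COP velocity.

#' Surface-gain schedule of the balance task
#'
#' @param gains ordered gains, one per trial (dimensionless; positive gains
#'   amplify sway-referenced surface motion, negative gains reverse it).
#' @param trial_duration_s seconds per trial.
#' @return An object of class `gain_schedule`.
#' @export
gain_schedule <- function(gains = c(0, 0.4, 2.0, 0, 0.6, -0.4, 0, 1.0, -1.0),
                          trial_duration_s = 20) {
  stopifnot(is.numeric(gains), length(gains) >= 1, all(is.finite(gains)))
  stopifnot_scalar(trial_duration_s)
  if (trial_duration_s <= 0) stop("`trial_duration_s` must be positive", call. = FALSE)
  structure(list(gains = as.numeric(gains), trial_duration_s = trial_duration_s),
            class = "gain_schedule")
}

# Gain in force at each time point (vectorised; times past the schedule end
# reuse the last trial's gain).
schedule_gain_at <- function(schedule, t) {
  idx <- pmin(length(schedule$gains),
              pmax(1L, floor(t / schedule$trial_duration_s) + 1L))
  schedule$gains[idx]
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline is designed for: ten
#' subjects, nine 20 s trials with the standard gain order, a 5 s pre-task
#' EEG baseline, quiet-stance COPv variability giving a ~6 cm/s event
#' threshold, N1 latency ~165 +/- 10 ms before the corrective zero-crossing,
#' and a control:instability epoch ratio near 2:1.
#'
#' @param n_subjects number of subjects (>= 2 for leave-one-subject-out).
#' @param schedule a [gain_schedule()].
#' @param pre_task_s length of the pre-task EEG baseline segment (s).
#' @param fs_cop,fs_low,fs_ha_raw sampling rates: COP and IC (100 Hz),
#'   downsampled shear/head-acceleration rate (10 Hz), raw head-acceleration
#'   rate before decimation (80 Hz).
#' @param event_rate_hz mean instability events per second of task (before
#'   minimum-separation thinning). Events are injected only after the first
#'   (reference, zero-gain) trial.
#' @param event_pulse list: `peak_cm_s` mean peak COP velocity of the
#'   destabilizing excursion, `duration_s` the full excursion period
#'   (destabilizing lobe then corrective lobe), `peak_jitter` relative
#'   uniform jitter of the peak per event.
#' @param min_event_sep_s minimum separation between event zero-crossings.
#' @param n1_params list: `amplitude_sd` trough depth in baseline SDs
#'   (positive number, applied negatively), `latency_mean_ms` and
#'   `latency_sd_ms` of the N1-to-zero-crossing latency, `width_fwhm_ms` of
#'   the Gaussian trough.
#' @param distractor_rate_hz rate of injected control troughs per second.
#' @param distractor_depth_sd length-2 range of distractor depth (baseline
#'   SDs).
#' @param channel_coupling list: `sh_gain` (N per cm/s^2) couples shear to
#'   the AP COM acceleration proxy (second derivative of COP) with white
#'   noise `sh_noise_sd` (N) at 10 Hz; `ha_gain` (m/s^2 per cm/s) and
#'   `ha_noise_sd` (m/s^2) couple head acceleration to COP velocity at the
#'   raw 80 Hz rate (the noise is partly removed again by the 10 Hz
#'   anti-alias decimation, as for a real inertial sensor).
#' @param sway_params list describing the sway model. The fast,
#'   gain-independent component is a colored (Ornstein-Uhlenbeck,
#'   correlation time `vel_tau_s`) COP velocity of SD `copv_sd_cm_s`,
#'   soft-saturated at `vel_sat_cm_s` (physiological sway speeds are
#'   bounded), leakily integrated to COP position with reversion time
#'   `pos_tau_s`. The slow component is an overdamped oscillator
#'   (`omega_slow_hz`, `zeta_slow`) of position SD `slow_sd_cm`, scaled per
#'   trial by `1 + gain_coef * |gain|` — sway-referencing inflates slow
#'   postural drift while leaving fast sway speed largely unchanged.
#' @param ic_band_hz length-2 band (Hz) of the 1/f IC background.
#' @param stability_limits_cm named vector `c(anterior = , posterior = )` in
#'   cm (anterior > 0 > posterior), jittered per subject by up to
#'   `limit_jitter_cm`.
#' @param limit_jitter_cm uniform per-subject jitter of each limit (cm).
#' @param seed master integer seed of the cohort.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 10,
                          schedule = gain_schedule(),
                          pre_task_s = 5,
                          fs_cop = 100, fs_low = 10, fs_ha_raw = 80,
                          event_rate_hz = 0.36,
                          event_pulse = list(peak_cm_s = 12, duration_s = 0.8,
                                             peak_jitter = 0.15),
                          min_event_sep_s = 1.5,
                          n1_params = list(amplitude_sd = 4.5,
                                           latency_mean_ms = 165,
                                           latency_sd_ms = 10,
                                           width_fwhm_ms = 80),
                          distractor_rate_hz = 0.02,
                          distractor_depth_sd = c(2.8, 5.2),
                          channel_coupling = list(sh_gain = 0.11, sh_noise_sd = 2.4,
                                                  ha_gain = 0.055, ha_noise_sd = 0.9),
                          sway_params = list(vel_tau_s = 0.3, copv_sd_cm_s = 2.0,
                                             vel_sat_cm_s = 5.5, pos_tau_s = 8,
                                             omega_slow_hz = 0.03, zeta_slow = 1.0,
                                             slow_sd_cm = 1.6, gain_coef = 0.5),
                          ic_band_hz = c(0.1, 15),
                          stability_limits_cm = c(anterior = 14, posterior = -11),
                          limit_jitter_cm = 2.0,
                          seed = 42) {
  stopifnot(inherits(schedule, "gain_schedule"))
  for (r in c(fs_cop, fs_low, fs_ha_raw)) {
    stopifnot_scalar(r)
    if (r <= 0) stop("sampling rates must be positive", call. = FALSE)
  }
  if (event_rate_hz < 0 || distractor_rate_hz < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  lat_lo <- n1_params$latency_mean_ms - 4 * n1_params$latency_sd_ms
  lat_hi <- n1_params$latency_mean_ms + 4 * n1_params$latency_sd_ms
  if (n1_params$latency_mean_ms < 100 || n1_params$latency_mean_ms > 250) {
    stop("N1 latency mean must lie within 100-250 ms", call. = FALSE)
  }
  if (lat_lo <= 0 || lat_hi >= 300) {
    stop("N1 latency window must stay inside (0, 300) ms", call. = FALSE)
  }
  if (!(stability_limits_cm[["anterior"]] > 0 &&
          stability_limits_cm[["posterior"]] < 0)) {
    stop("anterior limit must be > 0 > posterior limit", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, schedule = schedule, pre_task_s = pre_task_s,
         fs_cop = fs_cop, fs_low = fs_low, fs_ha_raw = fs_ha_raw,
         event_rate_hz = event_rate_hz, event_pulse = event_pulse,
         min_event_sep_s = min_event_sep_s, n1_params = n1_params,
         distractor_rate_hz = distractor_rate_hz,
         distractor_depth_sd = distractor_depth_sd,
         channel_coupling = channel_coupling, sway_params = sway_params,
         ic_band_hz = ic_band_hz,
         stability_limits_cm = stability_limits_cm,
         limit_jitter_cm = limit_jitter_cm, seed = seed),
    class = "cohort_params"
  )
}

# Simulate a damped stochastic oscillator x'' = -2*zeta*omega*x' - omega^2*x
# + input, Euler-discretised at dt, with `input` a pre-generated forcing
# vector. Returns the position trace.
sim_oscillator <- function(input, dt, omega, zeta) {
  n <- length(input)
  x <- numeric(n)
  v <- 0
  xi <- 0
  for (i in seq_len(n)) {
    a <- -2 * zeta * omega * v - omega^2 * xi + input[i]
    v <- v + a * dt
    xi <- xi + v * dt
    x[i] <- xi
  }
  x
}

# Band-limited 1/f ("pink") noise of length n at rate fs, unit variance
# target, band [f_lo, f_hi] Hz. Deterministic given the RNG state.
pink_noise <- function(n, fs, f_lo = 0.1, f_hi = 40) {
  nfft <- n
  f <- (0:(nfft %/% 2)) * fs / nfft
  amp <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(pmax(f, f_lo)), 0)
  phase <- stats::runif(length(f), 0, 2 * pi)
  half <- amp * exp(1i * phase)
  half[1] <- 0
  if (nfft %% 2 == 0) half[length(half)] <- Re(half[length(half)])
  spec <- c(half, Conj(rev(half[2:(length(half) - (1 - nfft %% 2))])))
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n]
  x / stats::sd(x)
}

# Poisson event times in [lo, hi] at `rate`, sorted, thinned to a minimum
# separation (the later of a close pair is dropped).
poisson_times <- function(rate, lo, hi, min_sep = 0) {
  if (rate <= 0 || hi <= lo) return(numeric(0))
  n <- stats::rpois(1, rate * (hi - lo))
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, lo, hi))
  if (min_sep > 0 && length(tt) > 1) {
    kept <- tt[1]
    for (t0 in tt[-1]) if (t0 - kept[length(kept)] >= min_sep) kept <- c(kept, t0)
    tt <- kept
  }
  tt
}

#' Generate one synthetic subject recording
#'
#' Deterministic given `(params$seed, subject_index)`. See [cohort_params()]
#' for the generative model. The returned ground truth records the injected
#' event zero-crossings, N1 trough centers and distractor trough centers.
#'
#' @param params a [cohort_params()].
#' @param subject_index 1-based subject index (`<= params$n_subjects`).
#' @return An object of class `subject_recording` with elements
#'   `subject_id`, `cop_ap` (cm, 100 Hz), `shear_ap` (N, 10 Hz),
#'   `head_acc_ap` (m/s^2, 10 Hz, generated at 80 Hz then decimated),
#'   `ic_trace` (a.u., 100 Hz, starting 5 s before task onset),
#'   `stability_limits_cm`, `gain_schedule`, and `truth` (class
#'   `ground_truth`).
#' @export
generate_subject <- function(params, subject_index) {
  stopifnot(inherits(params, "cohort_params"))
  if (subject_index < 1 || subject_index > params$n_subjects) {
    stop("`subject_index` out of range", call. = FALSE)
  }
  sp <- params$sway_params
  ep <- params$event_pulse
  np <- params$n1_params
  cc <- params$channel_coupling
  sched <- params$schedule
  task_s <- length(sched$gains) * sched$trial_duration_s
  fs <- params$fs_cop
  dt <- 1 / fs
  n_task <- as.integer(round(task_s * fs)) + 1L
  t_task <- (0:(n_task - 1L)) / fs

  seed_s <- hash_seed(params$seed, subject_index)
  with_seed(seed_s, {
    # --- per-subject stability limits ---
    ant <- params$stability_limits_cm[["anterior"]] +
      stats::runif(1, -1, 1) * params$limit_jitter_cm
    post <- params$stability_limits_cm[["posterior"]] +
      stats::runif(1, -1, 1) * params$limit_jitter_cm

    # --- sway: fast gain-independent component ---
    # Colored velocity (OU), soft-saturated, leakily integrated to position.
    warm <- as.integer(10 * fs)
    n_sim <- n_task + warm
    u <- numeric(n_sim)
    rho <- exp(-dt / sp$vel_tau_s)
    innov <- stats::rnorm(n_sim) * sqrt(1 - rho^2)
    for (i in 2:n_sim) u[i] <- rho * u[i - 1] + innov[i]
    v_fast <- u * sp$copv_sd_cm_s / stats::sd(u)
    v_fast <- sp$vel_sat_cm_s * tanh(v_fast / sp$vel_sat_cm_s)
    v_fast <- v_fast * sp$copv_sd_cm_s / stats::sd(v_fast)
    x_fast <- numeric(n_sim)
    xi <- 0
    for (i in seq_len(n_sim)) {
      xi <- xi + (v_fast[i] - xi / sp$pos_tau_s) * dt
      x_fast[i] <- xi
    }
    x_fast <- x_fast[(warm + 1L):n_sim]

    # --- sway: slow gain-scaled component ---
    om_s <- 2 * pi * sp$omega_slow_hz
    c_unit <- sqrt(4 * sp$zeta_slow * om_s^3)   # unit stationary position SD
    g_t <- schedule_gain_at(sched, c(rev(-(1:warm)) * dt, t_task))
    g_t[seq_len(warm)] <- sched$gains[1]
    scale_t <- sp$slow_sd_cm * (1 + sp$gain_coef * abs(g_t))
    w <- stats::rnorm(n_sim) / sqrt(dt) * c_unit * scale_t
    x_slow <- sim_oscillator(w, dt, om_s, sp$zeta_slow)[(warm + 1L):n_sim]

    # --- instability events: full-cycle velocity excursions ---
    # Event times are lean-weighted: a loss of balance is far more likely
    # while the COP is displaced from center (and hence under destabilizing
    # surface gains, where slow sway is larger), which is what couples low
    # time-to-boundary to the instability class.
    half <- ep$duration_s / 2
    x_sway <- x_fast + x_slow
    lo_t <- sched$trial_duration_s + half
    hi_t <- task_s - half
    n_target <- stats::rpois(1, params$event_rate_hz * task_s)
    cand <- sort(stats::runif(4 * max(n_target, 1), lo_t, hi_t))
    lean <- abs(x_sway[pmin(n_task, pmax(1L, round(cand * fs) + 1L))])
    zc_times <- if (n_target == 0 || length(cand) == 0) numeric(0) else {
      sort(cand[sample.int(length(cand), min(n_target, length(cand)),
                           prob = (lean + 0.3)^3)])
    }
    if (length(zc_times) > 1) {
      kept <- zc_times[1]
      for (t0 in zc_times[-1]) {
        if (t0 - kept[length(kept)] >= params$min_event_sep_s) kept <- c(kept, t0)
      }
      zc_times <- kept
    }
    x_ev <- numeric(n_task)
    for (k in seq_along(zc_times)) {
      A <- ep$peak_cm_s * stats::runif(1, 1 - ep$peak_jitter, 1 + ep$peak_jitter)
      excursion <- A * ep$duration_s / pi   # peak COP displacement of the cycle
      # A loss of balance compounds the current postural lean: the
      # destabilizing lobe pushes in the lean direction, so the distance to
      # the approached boundary is small during the event. Near the boundary
      # (no safe room for the excursion) the pulse goes the other way.
      x_at <- x_sway[min(n_task, max(1L, round(zc_times[k] * fs) + 1L))]
      s_draw <- stats::runif(1)   # keeps sign stochastic when |lean| is tiny
      s <- if (abs(x_at) < 0.5) sign(s_draw - 0.5) else sign(x_at)
      room <- if (s > 0) (ant - 0.2) - x_at else x_at - (post + 0.2)
      if (room < excursion + 1.5) s <- -s
      t_start <- zc_times[k] - half
      idx <- which(t_task >= t_start & t_task <= t_start + ep$duration_s)
      ph <- 2 * pi * (t_task[idx] - t_start) / ep$duration_s
      x_ev[idx] <- x_ev[idx] + s * A * (ep$duration_s / (2 * pi)) * (1 - cos(ph))
    }

    cop_v <- x_sway + x_ev
    cop_v <- pmin(pmax(cop_v, post + 0.2), ant - 0.2)  # hard safety margin
    cop <- time_series(cop_v, fs = fs, t0 = 0, units = "cm")

    # --- shear: noisy linear function of the AP COM acceleration proxy ---
    copv <- compute_copv(cop)
    v10 <- downsample_signal(copv, params$fs_low)
    a10 <- compute_copv(v10)   # central difference of velocity = acceleration
    sh <- time_series(cc$sh_gain * a10$values +
                        stats::rnorm(length(a10)) * cc$sh_noise_sd,
                      fs = params$fs_low, t0 = 0, units = "N")

    # --- head acceleration: generated at 80 Hz, decimated to 10 Hz ---
    t80 <- seq(0, task_s, by = 1 / params$fs_ha_raw)
    cop80 <- stats::spline(t_task, cop_v, xout = t80)$y
    ha_raw <- compute_copv(time_series(cop80, fs = params$fs_ha_raw, t0 = 0))
    ha80 <- time_series(cc$ha_gain * ha_raw$values +
                          stats::rnorm(length(ha_raw)) * cc$ha_noise_sd,
                        fs = params$fs_ha_raw, t0 = 0, units = "m/s^2")
    ha <- downsample_signal(ha80, params$fs_low)

    # --- IC trace: band-limited 1/f background + injected troughs ---
    n_ic <- as.integer(round((task_s + params$pre_task_s) * fs)) + 1L
    t_ic <- -params$pre_task_s + (0:(n_ic - 1L)) / fs
    ic_v <- pink_noise(n_ic, fs, params$ic_band_hz[1], params$ic_band_hz[2])
    sd_base <- stats::sd(ic_v[t_ic >= -params$pre_task_s - .t_eps & t_ic <= .t_eps])
    sig_g <- (np$width_fwhm_ms / 1000) / (2 * sqrt(2 * log(2)))

    lat <- stats::rnorm(length(zc_times), np$latency_mean_ms, np$latency_sd_ms)
    lat <- pmin(pmax(lat, np$latency_mean_ms - 4 * np$latency_sd_ms + 1e-6),
                np$latency_mean_ms + 4 * np$latency_sd_ms - 1e-6) / 1000
    n1_times <- zc_times - lat
    for (c0 in n1_times) {
      ic_v <- ic_v - np$amplitude_sd * sd_base * exp(-(t_ic - c0)^2 / (2 * sig_g^2))
    }

    distract <- poisson_times(params$distractor_rate_hz, 1, task_s - 1,
                              min_sep = 0.5)
    if (length(distract) > 0 && length(n1_times) > 0) {
      keep <- vapply(distract, function(t0) {
        all(abs(t0 - n1_times) > 0.7) && all(abs(t0 - zc_times) > 0.7)
      }, logical(1))
      distract <- distract[keep]
    }
    for (c0 in distract) {
      depth <- stats::runif(1, params$distractor_depth_sd[1],
                            params$distractor_depth_sd[2])
      ic_v <- ic_v - depth * sd_base * exp(-(t_ic - c0)^2 / (2 * sig_g^2))
    }
    ic <- time_series(ic_v, fs = fs, t0 = -params$pre_task_s, units = "a.u.")

    truth <- structure(
      list(event_zero_crossings = sort(zc_times),
           n1_times = sort(n1_times),
           control_trough_times = sort(distract)),
      class = "ground_truth"
    )

    structure(
      list(subject_id = sprintf("S%02d", subject_index),
           cop_ap = cop, shear_ap = sh, head_acc_ap = ha, ic_trace = ic,
           stability_limits_cm = c(anterior = ant, posterior = post),
           gain_schedule = sched, truth = truth),
      class = "subject_recording"
    )
  })
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s: COP %d samples @ %g Hz, %d injected events\n",
              x$subject_id, length(x$cop_ap), x$cop_ap$fs,
              length(x$truth$event_zero_crossings)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param params a [cohort_params()]; `n_subjects` must be at least 2
#'   (leave-one-subject-out evaluation needs >= 2 subjects).
#' @return An object of class `cohort`: a list with `subjects` (list of
#'   `subject_recording`) and `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_subjects < 2) {
    stop("`n_subjects` must be >= 2 (leave-one-subject-out needs >= 2 subjects)",
         call. = FALSE)
  }
  subjects <- lapply(seq_len(params$n_subjects), function(i) generate_subject(params, i))
  structure(list(subjects = subjects, params = params), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, seed %d\n", length(x$subjects), x$params$seed))
  invisible(x)
}

# ---- cohort disk layout -----------------------------------------------------

ts_to_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
}

csv_to_ts <- function(path, fs, units) {
  d <- utils::read.csv(path)
  time_series(d$value, fs = fs, t0 = d$time_s[1], units = units)
}

#' Write a cohort to a directory tree
#'
#' One directory per subject with two-column CSVs (`time_s,value`) for
#' `cop.csv`, `shear.csv`, `headacc.csv`, `ic.csv`, a `meta.json` (units,
#' rates, stability limits, gain schedule), a `truth.json`, and a top-level
#' `manifest.json` echoing the generator parameters.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj_dirs <- character(0)
  for (s in cohort$subjects) {
    sd_path <- file.path(dir, s$subject_id)
    dir.create(sd_path, showWarnings = FALSE)
    ts_to_csv(s$cop_ap, file.path(sd_path, "cop.csv"))
    ts_to_csv(s$shear_ap, file.path(sd_path, "shear.csv"))
    ts_to_csv(s$head_acc_ap, file.path(sd_path, "headacc.csv"))
    ts_to_csv(s$ic_trace, file.path(sd_path, "ic.csv"))
    meta <- list(
      subject_id = s$subject_id,
      rates_hz = list(cop = s$cop_ap$fs, shear = s$shear_ap$fs,
                      headacc = s$head_acc_ap$fs, ic = s$ic_trace$fs),
      units = list(cop = s$cop_ap$units, shear = s$shear_ap$units,
                   headacc = s$head_acc_ap$units, ic = s$ic_trace$units),
      stability_limits_cm = as.list(s$stability_limits_cm),
      gain_schedule = list(gains = s$gain_schedule$gains,
                           trial_duration_s = s$gain_schedule$trial_duration_s)
    )
    jsonlite::write_json(meta, file.path(sd_path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(s$truth), file.path(sd_path, "truth.json"),
                         digits = NA)
    subj_dirs <- c(subj_dirs, s$subject_id)
  }
  declass <- function(x) if (is.list(x)) lapply(unclass(x), declass) else x
  manifest <- list(subjects = subj_dirs, params = declass(cohort$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return A `cohort` (with `params` as the raw manifest echo).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(manifest$subjects, function(id) {
    sd_path <- file.path(dir, id)
    meta <- jsonlite::read_json(file.path(sd_path, "meta.json"),
                                simplifyVector = TRUE)
    truth_raw <- jsonlite::read_json(file.path(sd_path, "truth.json"),
                                     simplifyVector = TRUE)
    truth <- structure(lapply(truth_raw, as.numeric), class = "ground_truth")
    structure(
      list(subject_id = id,
           cop_ap = csv_to_ts(file.path(sd_path, "cop.csv"),
                              meta$rates_hz$cop, meta$units$cop),
           shear_ap = csv_to_ts(file.path(sd_path, "shear.csv"),
                                meta$rates_hz$shear, meta$units$shear),
           head_acc_ap = csv_to_ts(file.path(sd_path, "headacc.csv"),
                                   meta$rates_hz$headacc, meta$units$headacc),
           ic_trace = csv_to_ts(file.path(sd_path, "ic.csv"),
                                meta$rates_hz$ic, meta$units$ic),
           stability_limits_cm = c(anterior = meta$stability_limits_cm$anterior,
                                   posterior = meta$stability_limits_cm$posterior),
           gain_schedule = gain_schedule(meta$gain_schedule$gains,
                                         meta$gain_schedule$trial_duration_s),
           truth = truth),
      class = "subject_recording"
    )
  })
  structure(list(subjects = subjects, params = manifest$params), class = "cohort")
}
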