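#' Uniformly sampled scalar time series
#'
#' The backbone container for every channel in the pipeline: a numeric vector
#' sampled at a fixed rate, with a start time and a unit label. Sample `i`
#' (1-based) sits at time `t0 + (i - 1) / fs` seconds.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units free-text unit label (e.g. `"cm"`, `"cm/s"`, `"N"`).
#' @return An object of class `time_series`.
#' @examples
#' x <- time_series(sin(2 * pi * (0:99) / 100), fs = 100, units = "cm")
#' ts_times(x)[1:3]
#' @export
time_series <- function(values, fs, t0 = 0, units = "") {
  if (!is.numeric(values) || length(values) < 1L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  stopifnot_scalar(fs)
  stopifnot_scalar(t0)
  if (fs <= 0) stop("sampling rate `fs` must be positive", call. = FALSE)
  structure(
    list(values = as.numeric(values), fs = fs, t0 = t0, units = as.character(units)),
    class = "time_series"
  )
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a time series
#' @param x a `time_series`.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$fs

#' End time (time of the last sample) of a time series
#' @param x a `time_series`.
#' @export
ts_end <- function(x) x$t0 + (length(x$values) - 1) / x$fs

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %d samples @ %g Hz, t = [%.3f, %.3f] s%s\n",
    length(x$values), x$fs, x$t0, ts_end(x),
    if (nzchar(x$units)) paste0(", units: ", x$units) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = ts_times(x), value = x$values)
}

#' Clip a time series to a closed time interval
#'
#' Keeps every sample whose timestamp lies in `[from, to]` (with a small
#' floating-point tolerance so grid-aligned endpoints are included).
#'
#' @param x a `time_series`.
#' @param from,to interval bounds in seconds.
#' @return A `time_series` covering the requested interval, or `NULL` when no
#'   sample falls inside it.
#' @export
ts_clip <- function(x, from, to) {
  stopifnot_scalar(from); stopifnot_scalar(to)
  if (to < from) stop("`to` must be >= `from`", call. = FALSE)
  eps <- .t_eps * max(1, x$fs)
  i_lo <- max(1L, as.integer(ceiling((from - x$t0) * x$fs - eps)) + 1L)
  i_hi <- min(length(x$values), as.integer(floor((to - x$t0) * x$fs + eps)) + 1L)
  if (i_hi < i_lo) return(NULL)
  time_series(x$values[i_lo:i_hi], fs = x$fs, t0 = x$t0 + (i_lo - 1L) / x$fs,
              units = x$units)
}

# Indices of samples with time in the closed interval [from, to].
ts_window_idx <- function(x, from, to) {
  eps <- .t_eps * max(1, x$fs)
  i_lo <- max(1L, as.integer(ceiling((from - x$t0) * x$fs - eps)) + 1L)
  i_hi <- min(length(x$values), as.integer(floor((to - x$t0) * x$fs + eps)) + 1L)
  if (i_hi < i_lo) integer(0) else i_lo:i_hi
}

#' Anti-aliased downsampling to a lower rate
#'
#' Low-pass filters (4th-order Butterworth at 80% of the target Nyquist
#' frequency, applied forward-backward over a reflection-padded copy so the
#' result is zero-phase and free of edge transients) and then decimates by the
#' integer rate ratio. Timestamps stay on a uniform grid starting at the
#' original start time.
#'
#' @param x a `time_series`.
#' @param target_hz new sampling rate; must divide the source rate.
#' @return A `time_series` at `target_hz`.
#' @examples
#' x <- time_series(sin(2 * pi * 1 * (0:799) / 80), fs = 80)
#' y <- downsample_signal(x, 10)
#' @export
downsample_signal <- function(x, target_hz) {
  stopifnot(inherits(x, "time_series"))
  stopifnot_scalar(target_hz)
  if (target_hz <= 0) stop("`target_hz` must be positive", call. = FALSE)
  if (target_hz > x$fs + .t_eps) {
    stop("upsampling is not supported: `target_hz` exceeds the source rate",
         call. = FALSE)
  }
  q <- x$fs / target_hz
  if (abs(q - round(q)) > 1e-9) {
    stop("`target_hz` must divide the source rate by an integer factor",
         call. = FALSE)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  n <- length(x$values)
  if (n < 2L * q) stop("series too short to downsample at this ratio", call. = FALSE)
  pad <- min(n - 1L, 30L * q)
  v <- x$values
  padded <- c(2 * v[1] - rev(v[2:(pad + 1L)]),
              v,
              2 * v[n] - rev(v[(n - pad):(n - 1L)]))
  bf <- signal::butter(4, 0.8 / q)
  smoothed <- signal::filtfilt(bf, padded)[(pad + 1L):(pad + n)]
  keep <- seq(1L, n, by = q)
  time_series(smoothed[keep], fs = target_hz, t0 = x$t0, units = x$units)
}
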