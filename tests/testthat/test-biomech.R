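test_that("three-point central difference is exact on low-order polynomials", {
  fs <- 100
  t <- (0:499) / fs
  # constant -> zero velocity
  v0 <- compute_copv(time_series(rep(2, 500), fs = fs))
  expect_true(all(v0$values == 0))
  # linear ramp, slope 2 cm/s -> exactly 2 everywhere (one-sided ends too)
  v1 <- compute_copv(time_series(2 * t, fs = fs))
  expect_equal(v1$values, rep(2, 500), tolerance = 1e-10)
  # quadratic x = t^2 -> interior velocity exactly 2 t
  v2 <- compute_copv(time_series(t^2, fs = fs))
  expect_equal(v2$values[2:499], 2 * t[2:499], tolerance = 1e-10)
  expect_error(compute_copv(time_series(1:2, fs = fs)), "at least 3")
})

test_that("integrating computed COPv recovers COP on smooth inputs", {
  fs <- 100
  t <- (0:999) / fs
  x <- sin(2 * pi * 0.5 * t)
  v <- compute_copv(time_series(x, fs = fs))
  # trapezoidal integration of the central-difference velocity is
  # O(fs^-2)-accurate
  x_rec <- x[1] + c(0, cumsum((v$values[-1] + v$values[-1000]) / 2) / fs)
  expect_lt(max(abs(x_rec - x)), 1e-3)
})

test_that("instability threshold is k times the quiet-window COPv SD", {
  fs <- 100
  v <- time_series(rep(c(-2, 2), 1000), fs = fs)   # sample SD very near 2
  thr <- estimate_copv_threshold(v)
  expect_equal(thr, 3 * stats::sd(v$values[1:2000]))
  expect_equal(thr, 6, tolerance = 1e-3)
  expect_warning(estimate_copv_threshold(time_series(rep(0, 3000), fs = fs)),
                 "degenerate")
  # Monte-Carlo: N(0, 1.5) -> threshold ~ 4.5 within SD sampling error
  set.seed(8)
  vmc <- time_series(rnorm(2000, 0, 1.5), fs = fs)
  expect_equal(estimate_copv_threshold(vmc), 4.5, tolerance = 0.25)
})

test_that("DTB follows the direction-of-motion rule", {
  fs <- 100
  zone <- stability_zone(10, -8)
  cop <- time_series(c(0, 4, 1), fs = fs)
  copv <- time_series(c(1, -1, 0), fs = fs)
  dtb <- compute_dtb(cop, copv, zone)
  expect_equal(dtb$values[1], 10)       # moving anteriorly from 0
  expect_equal(dtb$values[2], 12)       # moving posteriorly from +4
  expect_equal(dtb$values[3], 9)        # zero velocity -> nearer boundary
  # exhaustive per-sample oracle on a random walk inside the zone
  set.seed(21)
  x <- cumsum(rnorm(500, sd = 0.3)); x <- pmin(pmax(x, -7), 9)
  v <- rnorm(500)
  got <- compute_dtb(time_series(x, fs = fs), time_series(v, fs = fs), zone)
  want <- vapply(seq_along(x), function(i) {
    if (v[i] > 0) 10 - x[i] else if (v[i] < 0) x[i] + 8 else min(10 - x[i], x[i] + 8)
  }, numeric(1))
  expect_equal(got$values, want)
  # outside the zone: clamped at zero with a warning
  expect_warning(
    out <- compute_dtb(time_series(c(11, 0), fs = fs),
                       time_series(c(1, 1), fs = fs), zone),
    "clamped"
  )
  expect_equal(out$values[1], 0)
})

test_that("TTB divides DTB by |COPv| with floor and cap", {
  fs <- 100
  dtb <- time_series(c(10, 5, 3), fs = fs)
  copv <- time_series(c(5, 0, -0.01), fs = fs)
  ttb <- compute_ttb(dtb, copv, cap_s = 10, eps_cm_s = 0.1)
  expect_equal(ttb$values[1], 2)        # 10 / 5
  expect_equal(ttb$values[2], 10)       # zero velocity -> cap
  expect_equal(ttb$values[3], 10)       # below the velocity floor -> cap
  expect_error(compute_ttb(time_series(c(-1, 0, 1), fs = fs), copv),
               "non-negative")
  # element-wise brute-force oracle on random data
  set.seed(9)
  d <- abs(rnorm(300, 8, 3)); v <- rnorm(300, 0, 3)
  got <- compute_ttb(time_series(d, fs = fs), time_series(v, fs = fs))
  want <- pmin(d / pmax(abs(v), 0.1), 10)
  expect_equal(got$values, want)
})

test_that("TTB is non-increasing in |COPv| at fixed COP", {
  speeds <- seq(0.05, 12, by = 0.05)
  ttb <- compute_ttb(time_series(rep(8, length(speeds)), fs = 10),
                     time_series(speeds, fs = 10))
  expect_true(all(diff(ttb$values) <= 1e-12))
})

test_that("event detection finds the constructed zero-crossing", {
  fs <- 100
  t <- (0:(20 * fs - 1)) / fs
  v <- numeric(length(t))
  # half-sine velocity pulse peaking 8 cm/s at t = 10.0 s, then a corrective
  # reversal crossing zero at t = 10.35 s
  up <- t >= 9.65 & t <= 10.35
  v[up] <- 8 * sin(pi * (t[up] - 9.65) / 0.7)
  down <- t > 10.35 & t <= 10.95
  v[down] <- -4 * sin(pi * (t[down] - 10.35) / 0.6)
  ev <- detect_instability_events(time_series(v, fs = fs), threshold = 6)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$zero_crossing_time_s, 10.35, tolerance = 0.011)
  expect_gt(abs(ev$peak_copv_cm_s), 6)
})

test_that("event detection honors threshold and refractory period", {
  fs <- 100
  quiet <- time_series(sin(2 * pi * (0:999) / fs) * 2, fs = fs)
  expect_equal(nrow(detect_instability_events(quiet, threshold = 6)), 0)
  # two supra-threshold peaks 200 ms apart -> one event under 500 ms refractory
  t <- (0:499) / fs
  v <- 8 * exp(-((t - 1.0) / 0.05)^2) + 8 * exp(-((t - 1.2) / 0.05)^2) -
    0.5 * (t > 1.4)
  ev <- detect_instability_events(time_series(v, fs = fs), threshold = 6,
                                  refractory_s = 0.5)
  expect_equal(nrow(ev), 1)
  expect_error(detect_instability_events(quiet, threshold = -1), "positive")
})
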