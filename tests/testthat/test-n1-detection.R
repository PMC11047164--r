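make_ic <- function(values, fs = 100, t0 = -5) time_series(values, fs = fs, t0 = t0)

test_that("baseline correction subtracts the pre-task mean and reports SD", {
  # constant trace: corrected to zero, mean reported
  bc <- baseline_correct(make_ic(rep(1.7, 2000)))
  expect_true(all(bc$ic$values == 0))
  expect_equal(bc$stats$mean, 1.7)
  # known pre-task moments survive the correction; the closed window [-5, 0]
  # covers the first 501 samples at 100 Hz
  set.seed(4)
  pre <- rnorm(501, mean = 1.7, sd = 0.5)
  task <- rnorm(1499)
  bc2 <- baseline_correct(make_ic(c(pre, task)))
  expect_equal(bc2$stats$mean, mean(pre))
  expect_equal(bc2$stats$sd, sd(pre))
  expect_lt(abs(mean(bc2$ic$values[1:501])), 1e-12)
  expect_error(baseline_correct(make_ic(rnorm(100), t0 = 0)), "empty")
})

test_that("N1 selection obeys the depth rule and the search window", {
  fs <- 100
  t <- seq(-5, 30, by = 1 / fs)
  events <- data.frame(peak_time_s = 9.8, peak_copv_cm_s = 8,
                       zero_crossing_time_s = 10)
  # flat corrected trace: nothing to find
  flat <- baseline_correct(make_ic(rep(0.7, length(t))))
  expect_equal(nrow(detect_n1(flat$ic, flat$stats, events)), 0)

  # pre-task noise sets the SD; the task segment carries only the trough
  set.seed(12)
  base <- ifelse(t <= 0, rnorm(length(t)), 0)
  sdb <- sd(base[t <= 0])
  trough <- -3 * sdb * exp(-((t - 9.84)^2) / (2 * 0.02^2))
  bc <- baseline_correct(make_ic(base + trough))
  n1 <- detect_n1(bc$ic, bc$stats, events)
  expect_equal(nrow(n1), 1)
  expect_equal(n1$time_s, 9.84, tolerance = 0.010)
  expect_equal(n1$latency_ms, 160, tolerance = 10)
  expect_lte(n1$amplitude, -2 * bc$stats$sd)

  # a trough only 60 ms before the crossing is outside -250..-100 ms
  trough2 <- -5 * sdb * exp(-((t - 9.94)^2) / (2 * 0.02^2))
  bc2 <- baseline_correct(make_ic(base + trough2))
  expect_equal(nrow(detect_n1(bc2$ic, bc2$stats, events)), 0)

  # an event whose window leaves the recording is skipped with a warning
  early <- data.frame(peak_time_s = -5.1, peak_copv_cm_s = 8,
                      zero_crossing_time_s = -4.9)
  expect_warning(out <- detect_n1(bc$ic, bc$stats, early), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("control troughs exclude N1 neighborhoods and thin by depth", {
  fs <- 100
  t <- seq(-5, 40, by = 1 / fs)
  g <- function(c0, depth, w = 0.02) -depth * exp(-((t - c0)^2) / (2 * w^2))
  # pre-task noise defines the SD; the task segment is quiet
  set.seed(2)
  pre <- t <= 0
  base <- ifelse(pre, rnorm(length(t)), 0)
  sdb <- sd(base[pre])
  # troughs: one near an N1 (excluded), two 100 ms apart (thinned to the
  # deeper), one isolated (kept)
  x <- base + g(10.0, 3 * sdb) + g(20.0, 2.5 * sdb) + g(20.1, 3.5 * sdb) +
    g(30.0, 4 * sdb)
  bc <- baseline_correct(make_ic(x))
  ctrl <- detect_control_troughs(bc$ic, bc$stats, n1_times = 10.0,
                                 min_sep_ms = 400,
                                 search_bounds = c(0, 40))
  expect_equal(nrow(ctrl), 2)
  expect_equal(ctrl$time_s, c(20.1, 30.0), tolerance = 0.01)
  # shallow trace: nothing qualifies
  quiet <- baseline_correct(make_ic(base))
  expect_equal(nrow(detect_control_troughs(quiet$ic, quiet$stats,
                                           n1_times = numeric(0),
                                           search_bounds = c(0, 40))), 0)
})

test_that("epochs have native-rate sample counts and in-bounds centers", {
  pr <- default_processed()
  ps <- pr$per_subject[[1]]
  rec <- pr$cohort$subjects[[1]]
  epochs <- ps$epochs
  expect_gt(length(epochs), 0)
  for (ep in epochs[seq_len(min(20, length(epochs)))]) {
    expect_length(ep$traces$copv, 41)  # 400 ms at 100 Hz, closed interval
    expect_length(ep$traces$ic, 41)
    expect_true(length(ep$traces$sh) %in% c(4, 5))  # 10 Hz channel
    expect_true(ep$center_time_s - 0.3 >= 0)
    expect_true(ep$center_time_s + 0.1 <= 180)
  }
  # a center too close to the recording start is dropped
  derived <- ps$derived
  bc <- baseline_correct(rec$ic_trace)
  got <- extract_epochs(rec, derived,
                        data.frame(time_s = 0.1, label = 0), bc$ic)
  expect_length(got, 0)
})

test_that("detected N1 centers coincide with injected troughs", {
  # The background 1/f activity shifts the apparent trough minimum by a few
  # samples, so agreement is statistical: at least 90% of label-1 centers
  # sit within two samples (20 ms) of an injected trough.
  pr <- default_processed()
  hits <- total <- 0
  for (i in seq_along(pr$per_subject)) {
    ps <- pr$per_subject[[i]]
    truth <- pr$cohort$subjects[[i]]$truth
    centers1 <- vapply(ps$epochs[vapply(ps$epochs, `[[`, integer(1), "label") == 1L],
                       `[[`, numeric(1), "center_time_s")
    total <- total + length(centers1)
    hits <- hits + sum(vapply(centers1, function(c0) {
      min(abs(truth$n1_times - c0)) < 0.020
    }, logical(1)))
  }
  expect_gte(hits / total, 0.9)
})

test_that("N1 amplitude/latency invariants hold and classes are disjoint", {
  pr <- default_processed()
  for (i in seq_along(pr$per_subject)) {
    ps <- pr$per_subject[[i]]
    if (nrow(ps$n1) > 0) {
      sdb <- ps$baseline$sd
      expect_true(all(ps$n1$amplitude <= -2 * sdb))
      expect_true(all(ps$n1$latency_ms >= 100 & ps$n1$latency_ms <= 250))
    }
    # no center appears in both classes
    expect_length(intersect(ps$n1$time_s, ps$controls$time_s), 0)
  }
})
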