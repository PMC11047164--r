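test_that("generator parameters are validated", {
  expect_error(cohort_params(event_rate_hz = -1), ">= 0")
  expect_error(cohort_params(n1_params = list(amplitude_sd = 4,
                                              latency_mean_ms = 80,
                                              latency_sd_ms = 10,
                                              width_fwhm_ms = 80)),
               "100-250")
  expect_error(cohort_params(n1_params = list(amplitude_sd = 4,
                                              latency_mean_ms = 240,
                                              latency_sd_ms = 20,
                                              width_fwhm_ms = 80)),
               "inside \\(0, 300\\)")
  expect_error(cohort_params(fs_cop = 0), "positive")
  expect_error(cohort_params(stability_limits_cm = c(anterior = -1,
                                                     posterior = -10)),
               "anterior")
  expect_error(generate_subject(cohort_params(), 11), "out of range")
  expect_error(generate_cohort(cohort_params(n_subjects = 1)), ">= 2")
})

test_that("a subject recording has the documented structure", {
  s <- generate_subject(cohort_params(n_subjects = 2, seed = 3), 1)
  expect_s3_class(s, "subject_recording")
  expect_equal(s$cop_ap$fs, 100)
  expect_equal(s$shear_ap$fs, 10)
  expect_equal(s$head_acc_ap$fs, 10)
  expect_equal(s$ic_trace$fs, 100)
  # 180 s task; IC starts 5 s before task onset
  expect_equal(ts_end(s$cop_ap), 180)
  expect_equal(s$ic_trace$t0, -5)
  expect_equal(ts_end(s$ic_trace), 180)
  # task channels share the task interval
  expect_equal(s$shear_ap$t0, 0)
  expect_equal(ts_end(s$shear_ap), 180)
  expect_gt(s$stability_limits_cm[["anterior"]], 0)
  expect_lt(s$stability_limits_cm[["posterior"]], 0)
})

test_that("generation is a pure function of (seed, subject index)", {
  p <- cohort_params(n_subjects = 2, seed = 17)
  a <- generate_subject(p, 1)
  b <- generate_subject(p, 1)
  expect_identical(a, b)
  c2 <- generate_subject(p, 2)
  expect_false(identical(a$cop_ap$values, c2$cop_ap$values))
  # cohorts too
  expect_identical(generate_cohort(p), generate_cohort(p))
})

test_that("a zero event rate yields an event-free recording", {
  p <- cohort_params(n_subjects = 2, event_rate_hz = 0, seed = 5)
  s <- generate_subject(p, 1)
  expect_length(s$truth$event_zero_crossings, 0)
  expect_length(s$truth$n1_times, 0)
})

test_that("injected N1s precede their zero-crossings by 100-250 ms", {
  pr <- default_processed()
  for (s in pr$cohort$subjects) {
    tr <- s$truth
    expect_equal(length(tr$n1_times), length(tr$event_zero_crossings))
    expect_false(is.unsorted(tr$event_zero_crossings))
    expect_false(is.unsorted(tr$n1_times))
    lat <- tr$event_zero_crossings - tr$n1_times
    expect_true(all(lat > 0.100 & lat < 0.250))
  }
})

test_that("COP never leaves the stability zone", {
  pr <- default_processed()
  for (s in pr$cohort$subjects) {
    expect_true(all(s$cop_ap$values < s$stability_limits_cm[["anterior"]]))
    expect_true(all(s$cop_ap$values > s$stability_limits_cm[["posterior"]]))
  }
})

test_that("the default cohort matches the study's epoch structure", {
  pr <- default_processed()
  f <- pr$features
  # instability share of all epochs brackets the reported 32%
  expect_gt(mean(f$label), 0.25)
  expect_lt(mean(f$label), 0.40)
  # control:instability ratio near 2:1
  ratio <- sum(f$label == 0) / sum(f$label == 1)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("feature correlations: five pairs below the 0.7 screen, and the
           structurally linked COPv-TTB pair is negative", {
  # TTB = DTB/|COPv| makes the COPv and TTB epoch medians hyperbolically
  # related, so with both features strongly class-separated their pooled
  # correlation is strong by construction; the remaining pairs must pass
  # the collinearity screen.
  pr <- default_processed()
  sc <- correlation_screen(pr$features)
  p <- sc$pearson
  linked <- (p$feature_1 == "COPv" & p$feature_2 == "TTB")
  expect_true(all(abs(p$r[!linked]) < 0.7))
  expect_lt(p$r[linked], 0)
  expect_false(any(p$strong[!linked]))
})

test_that("cohort round-trips through the on-disk layout", {
  p <- cohort_params(n_subjects = 2, seed = 23)
  cohort <- generate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "S01", "cop.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 2)
  s0 <- cohort$subjects[[1]]; s1 <- back$subjects[[1]]
  expect_equal(s1$cop_ap$values, s0$cop_ap$values)
  expect_equal(s1$cop_ap$fs, s0$cop_ap$fs)
  expect_equal(s1$ic_trace$t0, s0$ic_trace$t0)
  expect_equal(s1$truth$n1_times, s0$truth$n1_times)
  expect_equal(s1$stability_limits_cm, s0$stability_limits_cm)
  expect_equal(s1$gain_schedule$gains, s0$gain_schedule$gains)
})
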