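test_that("peaks are slope sign changes with flanking minima", {
  pk <- detect_peaks(c(0, 1, 0, 2, 0))
  expect_equal(pk$peak_index, c(2L, 4L))
  expect_equal(pk$min_before, c(1L, 3L))   # boundary fallback, then the dip
  expect_equal(pk$min_after, c(3L, 5L))
  expect_equal(nrow(detect_peaks(1:50)), 0)          # monotone ramp
  # 2 Hz sinusoid over 10 s at 100 Hz: one maximum per cycle
  t <- seq(0, 10 - 0.01, by = 0.01)
  expect_equal(nrow(detect_peaks(1.5 + sin(2 * pi * 2 * t), 100)), 20)
})

test_that("plateau peaks resolve to the first plateau sample", {
  pk <- detect_peaks(c(0, 2, 2, 2, 0, 1, 0))
  expect_equal(pk$peak_index, c(2L, 6L))
})

test_that("peak detection matches a brute-force scan on random signals", {
  set.seed(42)
  for (r in 1:1000) {
    x <- round(stats::rnorm(60), sample(0:2, 1))  # rounding induces plateaus
    expect_identical(detect_peaks(x)$peak_index, brute_force_peaks(x))
  }
})

test_that("peak normalization follows the flanking-minima ratio", {
  x <- c(1, 4, 3, 9, 0)                 # peak 4 with minima (1, 3)
  pk <- detect_peaks(x)
  mms <- normalize_peaks(x, pk)
  expect_equal(mms$value[1], 4 / (4 + 2), tolerance = 1e-7)
  # zero flanking minima give exactly 1
  x2 <- c(0, 2, 0)
  mms2 <- normalize_peaks(x2, detect_peaks(x2))
  expect_equal(mms2$value, 1)
  # non-positive peaks are skipped with a warning
  x3 <- c(-2, -1, -3, 1, 5, 1)
  expect_warning(m3 <- normalize_peaks(x3, detect_peaks(x3)), "non-positive")
  expect_equal(nrow(m3), 1)
})

test_that("MMS values are invariant under amplitude rescaling, exactly", {
  set.seed(7)
  for (r in 1:100) {
    x <- abs(stats::rnorm(400)) + 0.1
    ref <- mms_extract(x, 100)
    for (c0 in c(0.1, 1, 10, 100)) {
      scaled <- mms_extract(c0 * x, 100)
      expect_identical(scaled$value, ref$value)
      expect_identical(scaled$peak_index, ref$peak_index)
    }
  }
})

test_that("uncentered MMS amplitudes always lie in (0, 1]", {
  set.seed(8)
  for (r in 1:50) {
    x <- abs(stats::rnorm(300)) + 0.01
    v <- mms_extract(x, 100)$value
    expect_true(all(v > 0 & v <= 1))
    expect_true(all(diff(mms_extract(x, 100)$peak_time_s) > 0))
  }
})

test_that("gamma centering subtracts a consistent MLE mean", {
  set.seed(9)
  # build a signal whose planted MMS values are gamma draws
  v <- pmin(stats::rgamma(1e5, 4, scale = 0.1) + 0.5, 0.98)
  big <- new_mms_for_test(v)
  centered <- gamma_center(big)
  sh <- attr(centered, "gamma_shape"); sc <- attr(centered, "gamma_scale")
  expect_equal(centered$value_centered, v - sh * sc)
  # subtracted mean tracks the sample mean closely at this n
  expect_lt(abs(sh * sc - mean(v)) / mean(v), 0.01)
  expect_lt(abs(mean(centered$value_centered)), 3 * stats::sd(v) / sqrt(1e5))
})

test_that("gamma centering rejects constant and short series", {
  const <- new_mms_for_test(rep(0.7, 50))
  expect_error(gamma_center(const), "constant")
  short <- new_mms_for_test(stats::runif(10, 0.5, 0.9))
  expect_error(gamma_center(short), "at least 20")
})

test_that("inter-peak intervals and their summary are exact", {
  mms <- new_mms_for_test(c(0.6, 0.7, 0.8), times = c(0.0, 0.1, 0.3))
  ipi <- inter_peak_intervals(mms)
  expect_equal(ipi$intervals$interval_s, c(0.1, 0.2))
  expect_equal(ipi$mean_s, 0.15)
  expect_error(inter_peak_intervals(new_mms_for_test(0.5, times = 0)),
               "at least 2")
})

test_that("generator cadence is recovered from inter-peak intervals", {
  sim <- simulate_subject(gait_truth(cadence_hz = 1.1), duration_s = 120,
                          rate_hz = 100, seed = 3)
  mms <- mms_extract(sim$recording$pelvis, 100)
  ipi <- inter_peak_intervals(mms)
  expect_lt(abs(ipi$mean_s - 1 / 1.1) / (1 / 1.1), 0.02)
})
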