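test_that("a 3-minute walk at 1 Hz cadence yields ~180 peaks per node", {
  sim <- simulate_subject(gait_truth(), duration_s = 180, rate_hz = 100,
                          seed = 1)
  for (nd in c("pelvis", "foot_left")) {
    n_peaks <- nrow(detect_peaks(sim$recording[[nd]], 100))
    expect_gte(n_peaks, 170)
    expect_lte(n_peaks, 190)
  }
})

test_that("simulation is bit-identical under a fixed seed and distinct otherwise", {
  s1 <- simulate_subject(gait_truth(), duration_s = 30, rate_hz = 60, seed = 9)
  s2 <- simulate_subject(gait_truth(), duration_s = 30, rate_hz = 60, seed = 9)
  expect_identical(s1$recording$pelvis, s2$recording$pelvis)
  s3 <- simulate_subject(gait_truth(), duration_s = 30, rate_hz = 60, seed = 10)
  expect_false(identical(s1$recording$pelvis, s3$recording$pelvis))
})

test_that("planted MMS amplitudes are recovered by the extraction pipeline", {
  sim <- simulate_subject(gait_truth(), duration_s = 120, rate_hz = 100,
                          seed = 2)
  mms <- mms_extract(sim$recording$pelvis, 100)
  planted <- sim$truth$planted$amplitudes$pelvis[seq_len(nrow(mms))]
  expect_gt(stats::cor(planted, mms$value), 0.999)
})

test_that("uncoupled node pairs carry no spurious causality", {
  sim <- simulate_subject(gait_truth(), duration_s = 180, rate_hz = 100,
                          seed = 3)
  ma <- mms_extract(sim$recording$pelvis, 100, center = TRUE)
  mb <- mms_extract(sim$recording$thorax, 100, center = TRUE)
  sw <- lag_sweep(ma$value_centered, mb$value_centered, 1:10, "ols", "strict")
  expect_lt(attr(sw, "max_gc"), 0.15)
})

test_that("planted spike-level coupling lags are recovered end to end", {
  hits <- 0
  runs <- 25
  for (s in 1:runs) {
    truth <- gait_truth(couplings = data.frame(
      source = "foot_left", target = "foot_right", gain = 0.4, lag = 3))
    sim <- simulate_subject(truth, duration_s = 180, rate_hz = 100, seed = s)
    src <- mms_extract(sim$recording$foot_left, 100, center = TRUE)
    tgt <- mms_extract(sim$recording$foot_right, 100, center = TRUE)
    sw <- lag_sweep(tgt$value_centered, src$value_centered, 1:10, "ols",
                    "strict")
    if (identical(attr(sw, "optimal_lag"), 3L)) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * runs))
})

test_that("planted gamma scale is recovered within 10% at 150 spikes", {
  # a single 150-spike fit has ~11% sampling noise on the scale, so recovery
  # is judged on the estimate averaged over seeds
  est <- vapply(1:10, function(s) {
    truth <- gait_truth(amplitude_shape = 100, amplitude_scale = 0.007)
    sim <- simulate_subject(truth, duration_s = 160, rate_hz = 100,
                            seed = 40 + s)
    gamma_signature(mms_extract(sim$recording$pelvis, 100)$value)$gamma_scale
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.007) / 0.007, 0.10)
})

test_that("cohorts with planted mode weights order correctly", {
  ok <- 0
  runs <- 12
  for (s in 1:runs) {
    groups <- list(
      low = gait_truth(mode_mixture = list(weight1 = 0.2, rate1 = 25,
                                           mean2 = 0.72, sd2 = 0.05)),
      high = gait_truth(mode_mixture = list(weight1 = 0.6, rate1 = 25,
                                            mean2 = 0.72, sd2 = 0.05)))
    cohort <- simulate_cohort(groups, n_per_group = 3, seed = 100 + s,
                              duration_s = 120)
    frac <- vapply(cohort$subjects, function(su) {
      mms <- mms_extract(su$recording$pelvis, 100)
      mode_decompose(mms$value, seed = 1)$mode1_fraction
    }, numeric(1))
    lab <- cohort$truth_table$group_label
    if (mean(frac[lab == "high"]) > mean(frac[lab == "low"])) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.95 * runs))
})

test_that("degenerate cohort specifications still work or fail loudly", {
  co <- simulate_cohort(list(g = gait_truth()), n_per_group = 1, seed = 1,
                        duration_s = 20, rate_hz = 40)
  expect_equal(nrow(co$truth_table), 1)
  c1 <- simulate_cohort(list(g = gait_truth()), 1, seed = 1, duration_s = 20,
                        rate_hz = 40)
  c2 <- simulate_cohort(list(g = gait_truth()), 1, seed = 2, duration_s = 20,
                        rate_hz = 40)
  expect_false(identical(c1$subjects[[1]]$recording$pelvis,
                         c2$subjects[[1]]$recording$pelvis))
  expect_error(simulate_subject(gait_truth(couplings = data.frame(
    source = "pelvis", target = "thorax", gain = 0.3, lag = 500)),
    duration_s = 20, rate_hz = 40, seed = 1), "spike count")
  expect_error(simulate_subject(gait_truth(), duration_s = 5, rate_hz = 40),
               "at least 10")
})
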