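test_that("self-coherence is 1 and coherence stays within [0, 1]", {
  set.seed(1)
  x <- stats::rnorm(4000)
  cr <- cross_coherence(x, x, 100)
  expect_true(all(cr$coherence[cr$frequency_hz > 0] > 0.99))
  for (r in 1:10) {
    a <- stats::rnorm(2000); b <- stats::rnorm(2000)
    co <- cross_coherence(a, b, 100)$coherence
    expect_true(all(co >= -1e-9 & co <= 1 + 1e-9))
  }
})

test_that("a shared tone sets the coupling frequency", {
  set.seed(2)
  t <- seq(0, 60, by = 0.01)[-1]
  x <- sin(2 * pi * 2 * t) + stats::rnorm(length(t))
  y <- sin(2 * pi * 2 * t) + stats::rnorm(length(t))
  cr <- cross_coherence(x, y, 100)
  bin <- diff(cr$frequency_hz[1:2])
  expect_lte(abs(attr(cr, "coupling_frequency_hz") - 2), bin)
  # time reversal leaves the magnitude coherence argmax unchanged
  cr_rev <- cross_coherence(rev(x), rev(y), 100)
  expect_equal(attr(cr_rev, "coupling_frequency_hz"),
               attr(cr, "coupling_frequency_hz"))
})

test_that("independent white series stay below the analytic null quantile", {
  # with L independent (non-overlapping) segments the null MSC satisfies
  # P(C > c) = (1 - c)^(L - 1); the max over bins is calibrated accordingly
  set.seed(3)
  hits <- 0
  runs <- 40
  for (r in 1:runs) {
    x <- stats::rnorm(3200); y <- stats::rnorm(3200)
    cr <- cross_coherence(x, y, 100, window_s = 4, overlap = 0)
    L <- attr(cr, "n_segments")
    nb <- sum(cr$frequency_hz > 0)
    qmax <- 1 - (1 - 0.95^(1 / nb))^(1 / (L - 1))
    if (max(cr$coherence[cr$frequency_hz > 0]) < qmax) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * runs * 0.9)   # >= 90% of runs, with margin
})

test_that("short series are rejected", {
  expect_error(cross_coherence(stats::rnorm(100), stats::rnorm(100), 100),
               "shorter")
})

test_that("mean frequency is the power-weighted average", {
  expect_equal(mean_frequency(5, 1), 5)
  expect_equal(mean_frequency(c(1, 3), c(1, 1)), 2)
  expect_equal(mean_frequency(c(1, 3), c(2, 2) * 17),
               mean_frequency(c(1, 3), c(2, 2)))  # scaling invariance
  expect_error(mean_frequency(c(1, 2), c(0, 0)), "all-zero")
  # pure tone concentrates the estimated spectrum
  t <- seq(0, 30, by = 0.01)[-1]
  psd <- welch_psd(sin(2 * pi * 4 * t), 100)
  bin <- diff(psd$frequency_hz[1:2])
  expect_lt(abs(mean_frequency(psd$frequency_hz, psd$power) - 4), bin + 0.05)
})

test_that("node mean coherence averages pairwise maxima", {
  fake <- function(mx) structure(tibble::tibble(), max_coherence = mx)
  expect_equal(node_mean_coherence(list(a = fake(0.4))), 0.4)
  expect_equal(node_mean_coherence(list(fake(0.2), fake(0.8))), 0.5)
  expect_error(node_mean_coherence(list()), "singleton")
  # hub sharing a source with all partners out-coheres the leaves
  set.seed(4)
  t <- seq(0, 40, by = 0.01)[-1]
  hub <- sin(2 * pi * 1.5 * t) + 0.5 * stats::rnorm(length(t))
  leaves <- lapply(1:3, function(k)
    sin(2 * pi * 1.5 * t) + 2 * stats::rnorm(length(t)))
  hub_mean <- node_mean_coherence(
    lapply(leaves, function(l) cross_coherence(hub, l, 100)))
  leaf_mean <- node_mean_coherence(list(
    cross_coherence(leaves[[1]], leaves[[2]], 100),
    cross_coherence(leaves[[1]], leaves[[3]], 100),
    cross_coherence(leaves[[1]], hub, 100)))
  expect_gt(hub_mean, 0)
  expect_gt(hub_mean, leaf_mean - 0.15)
})

test_that("spike trains place normalized amplitudes at peak samples", {
  mms <- new_mms_for_test(c(0.6, 0.7), times = c(0.1, 0.2))
  tr <- mms_spike_train(mms, n_samples = 5)
  expect_equal(tr, c(0.6, 0.7, 0, 0, 0))
  tri <- mms_spike_train(mms, n_samples = 5, fill = "interpolate")
  expect_equal(tri[1:2], c(0.6, 0.7))
  expect_true(all(tri[3:5] == 0.7))    # rule-2 extension
})

test_that("band-stop probe removes tremor-band noise contributions", {
  truth <- gait_truth(tremor = data.frame(node = "pelvis", frequency_hz = 12,
                                          amplitude = 0.4))
  sim <- simulate_subject(truth, duration_s = 120, rate_hz = 100, seed = 6)
  pr <- band_stop_probe(sim$recording$pelvis, 100, c(10, 14))
  expect_lt(pr$nsr_after, pr$nsr_before)
  # zero-width band is the identity
  clean <- simulate_subject(gait_truth(), duration_s = 60, rate_hz = 100,
                            seed = 7)
  pr0 <- band_stop_probe(clean$recording$pelvis, 100, c(10, 10))
  expect_equal(pr0$nsr_after, pr0$nsr_before, tolerance = 1e-10)
  # a band far from all signal content barely moves the NSR
  prfar <- band_stop_probe(clean$recording$pelvis, 100, c(35, 45))
  expect_lt(abs(prfar$nsr_after - prfar$nsr_before) / prfar$nsr_before, 0.05)
  expect_error(band_stop_probe(clean$recording$pelvis, 100, c(10, 60)),
               "rate/2")
})
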