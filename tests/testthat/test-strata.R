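test_that("the stride proxy divides mean speed by mean frequency", {
  t <- seq(0, 60, by = 0.01)[-1]
  speed <- 1.2 + 0.3 * sin(2 * pi * 1 * t)
  sp <- stride_proxy(speed, 100)
  expect_lt(abs(sp$mean_speed_ms - 1.2), 1e-6)
  expect_lt(abs(sp$mean_frequency_hz - 1), 0.05)
  expect_lt(abs(sp$speed_over_frequency_m - 1.2) / 1.2, 0.05)
  # doubling cadence at fixed speed halves the ratio
  sp2 <- stride_proxy(1.2 + 0.3 * sin(2 * pi * 2 * t), 100)
  expect_lt(abs(sp2$speed_over_frequency_m - 0.6) / 0.6, 0.05)
  expect_error(stride_proxy(numeric(0), 100), "empty")
})

test_that("the stride proxy matches generator ground truth", {
  truth <- gait_truth(cadence_hz = 0.9, com_mean_speed_ms = 1.0)
  sim <- simulate_subject(truth, duration_s = 180, rate_hz = 100, seed = 11)
  sp <- stride_proxy(sim$recording$com_speed, 100)
  expect_lt(abs(sp$speed_over_frequency_m - 1 / 0.9) / (1 / 0.9), 0.05)
})

test_that("stride proxy is stable under cropping a stationary walk", {
  sim <- simulate_subject(gait_truth(), duration_s = 180, rate_hz = 100,
                          seed = 12)
  s <- sim$recording$com_speed
  full <- stride_proxy(s, 100)$speed_over_frequency_m
  crop <- stride_proxy(s[2001:14000], 100)$speed_over_frequency_m
  expect_lt(abs(full - crop) / full, 0.05)
})

test_that("feature normalization maps to [0,1] and flags constants", {
  tab <- tibble::tibble(id = c("a", "b", "c"), f1 = c(2, 3, 4),
                        f2 = c(5, 5, 5))
  expect_warning(norm <- normalize_features(tab), "constant")
  expect_equal(norm$f1, c(0, 0.5, 1))
  expect_true(all(norm$f2 == 0))
  expect_equal(attr(norm, "constant_features"), "f2")
  # idempotent on an already-normalized range
  again <- normalize_features(norm[c("id", "f1")])
  expect_equal(again$f1, norm$f1)
  expect_error(normalize_features(tab[1, ]), "at least 2")
  z <- normalize_features(tab[c("id", "f1")], method = "zscore")
  expect_equal(mean(z$f1), 0)
  expect_equal(stats::sd(z$f1), 1)
})

test_that("k-means separates well-separated blobs exactly and is deterministic", {
  set.seed(1)
  blob <- rbind(matrix(stats::rnorm(40, 0, 0.1), ncol = 2),
                matrix(stats::rnorm(40, 10, 0.1), ncol = 2))
  feats <- tibble::tibble(x = blob[, 1], y = blob[, 2],
                          truth = rep(1:2, each = 20))
  cl <- cluster_subjects(feats, k = 2, seed = 3, columns = c("x", "y"))
  tabs <- table(cl$assignments$.cluster, feats$truth)
  expect_equal(sort(diag(tabs[order(tabs[, 1], decreasing = TRUE), ])),
               sort(c(20L, 20L)))
  expect_gt(cl$silhouette, 0.9)
  # k = 1: centroid is the mean
  cl1 <- cluster_subjects(feats, k = 1, seed = 3, columns = c("x", "y"))
  expect_equal(unlist(cl1$centroids), c(x = mean(blob[, 1]), y = mean(blob[, 2])))
  # deterministic under a fixed seed
  cl2 <- cluster_subjects(feats, k = 2, seed = 3, columns = c("x", "y"))
  expect_identical(cl$assignments$.cluster, cl2$assignments$.cluster)
  expect_error(cluster_subjects(feats[1:3, ], k = 5), "exceeds")
})

test_that("silhouette scan reports a best k without choosing it", {
  set.seed(2)
  feats <- tibble::tibble(x = c(stats::rnorm(15), stats::rnorm(15, 8)),
                          y = c(stats::rnorm(15), stats::rnorm(15, 8)))
  scan <- silhouette_scan(feats, 2:4, seed = 1)
  expect_equal(scan$k[which.max(scan$silhouette)], 2)
})

test_that("group difference maps zero out non-significant nodes", {
  set.seed(3)
  a <- tibble::as_tibble(matrix(stats::rnorm(200, 0.2, 0.02), 20, 10,
                                dimnames = list(NULL, paste0("n", 1:10))))
  # identical groups: all-zero map
  dm0 <- group_difference_map(a, a)
  expect_true(all(dm0$difference == 0))
  # one node shifted far: that node flagged with the right sign
  b <- a
  b$n4 <- b$n4 + 0.1   # 5 sd shift
  dm <- group_difference_map(a, b)
  expect_lt(dm$difference[dm$node == "n4"], 0)
  dm_swap <- group_difference_map(b, a)
  expect_equal(dm_swap$difference, -dm$difference)   # antisymmetry
  expect_error(group_difference_map(a[1, ], b), "at least 2")
})

test_that("group difference maps control the per-node false-positive rate", {
  set.seed(4)
  hits <- 0; total <- 0
  for (r in 1:60) {
    a <- tibble::as_tibble(matrix(stats::rnorm(100), 10, 10,
                                  dimnames = list(NULL, paste0("n", 1:10))))
    b <- tibble::as_tibble(matrix(stats::rnorm(100), 10, 10,
                                  dimnames = list(NULL, paste0("n", 1:10))))
    dm <- group_difference_map(a, b, alpha = 0.05)
    hits <- hits + sum(dm$difference != 0)
    total <- total + nrow(dm)
  }
  expect_lt(abs(hits / total - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("power: a 5-sd node shift is detected in almost every run", {
  set.seed(5)
  det <- 0
  for (r in 1:30) {
    a <- tibble::as_tibble(matrix(stats::rnorm(200, 0, 1), 20, 10,
                                  dimnames = list(NULL, paste0("n", 1:10))))
    b <- tibble::as_tibble(matrix(stats::rnorm(200, 0, 1), 20, 10,
                                  dimnames = list(NULL, paste0("n", 1:10))))
    b$n7 <- b$n7 + 5
    dm <- group_difference_map(a, b)
    if (dm$difference[dm$node == "n7"] != 0) det <- det + 1
  }
  expect_gte(det, 27)
})

test_that("centroid summaries are per-group means", {
  feats <- tibble::tibble(group_label = c("g1", "g1", "g2"),
                          f = c(1, 3, 10), g = c(0, 2, -2))
  cs <- centroid_summary(feats)
  expect_equal(cs$f, c(2, 10))
  expect_equal(cs$g, c(1, -2))
  expect_error(centroid_summary(dplyr::rename(feats, gl = "group_label")),
               "missing group column")
})
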