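test_that("sample moments follow the lagged-product definitions", {
  x <- c(1, -1, 1, -1)
  cs <- sample_moments(x, x, 1)
  expect_equal(cs$Rxx0, 1)
  expect_equal(cs$Rxxl, -1)
  expect_equal(cs$Rxy0, cs$Rxx0)     # x = y identity
  set.seed(1)
  n <- 2e4
  w <- stats::rnorm(n)
  cs <- sample_moments(w, stats::rnorm(n), 3)
  expect_lt(abs(cs$Rxxl), 3 / sqrt(n))   # white noise decorrelates
  expect_error(sample_moments(1:4, 1:4, 3), "insufficient")
})

test_that("the closed-form estimator reproduces the hand-derived example", {
  cs <- cov_set(Rxx0 = 2, Rxxl = 1, Ryy0 = 1, Rxy0 = 0.25, Rxyl = 0.5)
  g <- gc_single_lag(cs, "paper", "strict")
  expect_equal(g$a1, 2)
  expect_equal(g$a2, 0)
  expect_equal(g$b, 4)
  expect_equal(g$sigma1_sq, -6)
  expect_equal(g$sigma2_sq, -14)
  expect_false(g$valid)               # strict policy flags the lag invalid
  gp <- gc_single_lag(cs, "paper", "permissive")
  expect_true(gp$valid)
  expect_equal(gp$gc, log(3 / 7))
  # independent solver agrees
  o <- paper_gc_oracle(2, 1, 1, 0.25, 0.5)
  expect_equal(c(gp$a1, gp$a2, gp$b, gp$sigma1_sq, gp$sigma2_sq),
               c(o$a1, o$a2, o$b, o$sigma1_sq, o$sigma2_sq), tolerance = 1e-12)
})

test_that("closed-form estimator matches an independent solver on random moments", {
  set.seed(3)
  for (r in 1:1000) {
    Rxx0 <- stats::runif(1, 0.5, 3)
    Ryy0 <- stats::runif(1, 0.5, 3)
    Rxxl <- stats::runif(1, -1, 1) * Rxx0
    Rxy0 <- stats::runif(1, -0.8, 0.8) * sqrt(Rxx0 * Ryy0)
    Rxyl <- stats::runif(1, -0.8, 0.8) * sqrt(Rxx0 * Ryy0)
    g <- gc_single_lag(cov_set(Rxx0, Rxxl, Ryy0, Rxy0, Rxyl), "paper",
                       "permissive")
    if (is.na(g$a1)) next              # guarded degenerate system
    o <- paper_gc_oracle(Rxx0, Rxxl, Ryy0, Rxy0, Rxyl)
    expect_equal(g$a1, o$a1, tolerance = 1e-10)
    expect_equal(g$a2, o$a2, tolerance = 1e-10)
    expect_equal(g$b, o$b, tolerance = 1e-10)
    expect_equal(g$sigma1_sq, o$sigma1_sq, tolerance = 1e-10)
    expect_equal(g$sigma2_sq, o$sigma2_sq, tolerance = 1e-10)
    if (g$valid) expect_equal(g$gc, o$gc, tolerance = 1e-10)
  }
})

test_that("degenerate moment systems are flagged, not solved", {
  g <- gc_single_lag(cov_set(1, 0, 1, 0.3, 0.2), "paper")
  expect_false(g$valid)
  expect_match(g$reason, "a1 undefined")
  # collinear: Rxxl * Rxy0 == Rxyl * Rxx0
  g2 <- gc_single_lag(cov_set(1, 0.5, 1, 0.4, 0.2), "paper")
  expect_false(g2$valid)
  expect_match(g2$reason, "collinear")
})

test_that("OLS mode recovers the generative coefficients and a null gc", {
  d <- simulate_ar_pair(1e5, lag = 3, a2 = 0.5, b_yx = 0.4, seed = 11)
  g <- gc_single_lag(sample_moments(d$x, d$y, 3), "ols", "strict")
  expect_lt(abs(g$a2 - 0.5), 0.02)
  expect_lt(abs(g$b - 0.4), 0.02)
  expect_gt(g$gc, 0)
  # independent pair: b ~ 0 and gc ~ 0
  set.seed(12)
  x <- stats::rnorm(1e5); y <- stats::rnorm(1e5)
  g0 <- gc_single_lag(sample_moments(x, y, 4), "ols", "strict")
  expect_lt(abs(g0$b), 0.02)
  expect_lt(abs(g0$gc), 0.01)
  # the cause is a leading copy of x: near-perfect prediction at lag 5
  lead <- c(x[6:1e5], stats::rnorm(5))
  gs <- gc_single_lag(sample_moments(x, lead, 5), "ols", "strict")
  expect_gt(gs$gc, 2)
})

test_that("OLS gc is non-negative up to sampling noise", {
  set.seed(13)
  for (r in 1:20) {
    x <- stats::rnorm(1e4); y <- stats::rnorm(1e4)
    g <- gc_single_lag(sample_moments(x, y, sample(1:10, 1)), "ols",
                       "permissive")
    expect_gt(g$gc, -0.01)
  }
})

test_that("lag sweep locates the optimal lag, force and ties", {
  d <- simulate_ar_pair(5000, lag = 3, a2 = 0.5, b_yx = 0.4, seed = 21)
  sw <- lag_sweep(d$x, d$y, lags = 3, mode = "ols")
  expect_equal(attr(sw, "optimal_lag"), 3L)     # singleton sweep
  sw <- lag_sweep(d$x, d$y, 1:10, "ols")
  expect_equal(attr(sw, "force"),
               attr(sw, "max_gc") / attr(sw, "optimal_lag"))
  expect_error(lag_sweep(d$x, d$y, integer(0)), "empty lag range")
  # force falls as the optimal lag lengthens at fixed causality
  expect_gt(0.6 / 1, 0.6 / 3)
  g <- glance(sw)
  expect_named(g, c("optimal_lag", "max_gc", "force", "n_valid", "n_lags",
                    "mode", "policy"))
})

test_that("planted internal delays are recovered across seeds", {
  hits <- 0
  for (s in 1:30) {
    d <- simulate_ar_pair(2e4, lag = 3, a2 = 0.5, b_yx = 0.4, seed = 100 + s)
    sw <- lag_sweep(d$x, d$y, 1:10, "ols", "strict")
    if (identical(attr(sw, "optimal_lag"), 3L)) hits <- hits + 1
  }
  expect_gte(hits, 27)
})

test_that("the fast sweep agrees with the rich sweep", {
  set.seed(31)
  for (r in 1:20) {
    d <- simulate_ar_pair(3000, lag = sample(1:5, 1), a2 = 0.4,
                          b_yx = stats::runif(1, 0, 0.6), seed = r)
    sw <- lag_sweep(d$x, d$y, 1:8, "ols", "strict")
    fx <- gaitmms:::max_gc_fast(d$x, d$y, 1:8, "ols", "strict")
    expect_equal(attr(sw, "max_gc"), fx$max_gc, tolerance = 1e-12)
    expect_equal(attr(sw, "optimal_lag"), fx$optimal_lag)
  }
})
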