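# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Exhaustive scan for strict local maxima (plateaus count once, at their
# first sample; boundary runs never count).
brute_force_peaks <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # end of plateau
    if (j < n && x[i] > x[i - 1L] && x[i] > x[j + 1L]) {
      peaks <- c(peaks, i)
    }
    i <- j + 1L
  }
  peaks
}

# Closed-form moment estimator solved independently: generic linear solve of
# the 2x2 system plus direct substitution into the noise-variance formulas.
paper_gc_oracle <- function(Rxx0, Rxxl, Ryy0, Rxy0, Rxyl) {
  a1 <- Rxx0 / Rxxl
  A <- matrix(c(Rxxl, Rxx0, Rxyl, Rxy0), 2, 2)
  ab <- solve(A, c(Rxx0, Rxxl))
  a2 <- ab[1]; b <- ab[2]
  s1 <- (1 - a1^2) * Rxx0
  s2 <- (1 - a2^2) * Rxx0 - b^2 * Ryy0 - 2 * a2 * b * Rxy0
  list(a1 = a1, a2 = a2, b = b, sigma1_sq = s1, sigma2_sq = s2,
       gc = if (s1 / s2 > 0) log(s1 / s2) else NA_real_)
}

# Direct minimization over unimodal cdfs: for every mode placement (below /
# above all data, at a data value with a jump, or at an interior position
# searched by golden section), solve the constrained sup-distance problem as
# a linear program (boot::simplex). Ground truth for the dip statistic at
# small n.
dip_oracle <- function(x, golden_iters = 25) {
  n <- length(x)
  tab <- table(sort(x))
  v <- as.numeric(names(tab)); m <- length(v)
  if (m == 1) return(0)
  C <- cumsum(as.numeric(tab)) / n
  P <- c(0, C[-m])

  solve_lp <- function(nextra, cons) {
    nv <- m + nextra + 1L
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    for (cn in cons) {
      r <- numeric(nv); r[cn$idx] <- cn$coef
      if (cn$dir == "<=") { A1 <- rbind(A1, r); b1 <- c(b1, cn$rhs) }
      else { A2 <- rbind(A2, r); b2 <- c(b2, cn$rhs) }
    }
    obj <- numeric(nv); obj[nv] <- 1
    res <- tryCatch(boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                                  maxi = FALSE),
                    error = function(e) NULL)
    if (is.null(res) || res$solved != 1) return(Inf)
    sol <- res$soln
    ok <- all(A1 %*% sol <= b1 + 1e-8) && all(A2 %*% sol >= b2 - 1e-8)
    if (!ok) Inf else res$value
  }
  di <- function(nextra) m + nextra + 1L

  gate_cons <- function(nextra, mode_at = NA) {
    cons <- list()
    for (u in 1:m) {
      up <- if (!is.na(mode_at) && u == mode_at) C[u] else P[u]
      cons <- c(cons, list(
        list(idx = c(u, di(nextra)), coef = c(1, -1), rhs = up, dir = "<="),
        list(idx = c(u, di(nextra)), coef = c(1, 1), rhs = C[u], dir = ">=")))
    }
    for (u in 1:(m - 1)) {
      cons <- c(cons, list(list(idx = c(u, u + 1), coef = c(1, -1), rhs = 0,
                                dir = "<=")))
    }
    c(cons, list(list(idx = m, coef = 1, rhs = 1, dir = "<=")))
  }
  convex_triple <- function(i1, i2, i3x, i3idx) {
    dx1 <- v[i2] - v[i1]; dx2 <- i3x - v[i2]
    list(idx = c(i1, i2, i3idx), coef = c(dx2, -dx1 - dx2, dx1), rhs = 0,
         dir = ">=")
  }
  concave_triple <- function(i1x, i1idx, i2, i3) {
    dx1 <- v[i2] - i1x; dx2 <- v[i3] - v[i2]
    list(idx = c(i1idx, i2, i3), coef = c(dx2, -dx1 - dx2, dx1), rhs = 0,
         dir = "<=")
  }
  convex_range <- function(r) {
    cons <- list()
    if (length(r) >= 3) for (u in 2:(length(r) - 1)) {
      cons <- c(cons, list(convex_triple(r[u - 1], r[u], v[r[u + 1]], r[u + 1])))
    }
    cons
  }
  concave_range <- function(r) {
    cons <- list()
    if (length(r) >= 3) for (u in 2:(length(r) - 1)) {
      cons <- c(cons, list(concave_triple(v[r[u - 1]], r[u - 1], r[u], r[u + 1])))
    }
    cons
  }

  best <- Inf
  best <- min(best, solve_lp(0, c(gate_cons(0), concave_range(1:m))))
  best <- min(best, solve_lp(0, c(gate_cons(0), convex_range(1:m))))
  for (k in 1:m) {
    cons <- gate_cons(1, mode_at = k)
    h <- m + 1L
    cons <- c(cons, list(
      list(idx = c(h, di(1)), coef = c(1, -1), rhs = P[k], dir = "<="),
      list(idx = c(h, di(1)), coef = c(1, 1), rhs = P[k], dir = ">="),
      list(idx = c(h, k), coef = c(1, -1), rhs = 0, dir = "<=")))
    if (k >= 2) cons <- c(cons, list(
      list(idx = c(k - 1, h), coef = c(1, -1), rhs = 0, dir = "<=")))
    if (k >= 3) {
      cons <- c(cons, convex_range(1:(k - 1)),
                list(convex_triple(k - 2, k - 1, v[k], h)))
    }
    if (k <= m - 2) cons <- c(cons, concave_range(k:m))
    best <- min(best, solve_lp(1, cons))
  }
  gap_lp <- function(j, mu) {
    cons <- gate_cons(2)
    a <- m + 1L; b <- m + 2L
    cons <- c(cons, list(
      list(idx = c(a, di(2)), coef = c(1, -1), rhs = C[j], dir = "<="),
      list(idx = c(b, di(2)), coef = c(1, -1), rhs = C[j], dir = "<="),
      list(idx = c(a, b), coef = c(1, -1), rhs = 0, dir = "<="),
      list(idx = c(j, a), coef = c(1, -1), rhs = 0, dir = "<="),
      list(idx = c(b, j + 1), coef = c(1, -1), rhs = 0, dir = "<=")))
    if (j >= 2) cons <- c(cons, convex_range(1:j),
                          list(convex_triple(j - 1, j, mu, a)))
    if (j <= m - 2) cons <- c(cons, concave_range((j + 1):m),
                              list(concave_triple(mu, b, j + 1, j + 2)))
    solve_lp(2, cons)
  }
  for (j in 1:(m - 1)) {
    a <- v[j]; b <- v[j + 1]
    fa <- gap_lp(j, a); fb <- gap_lp(j, b)
    best <- min(best, fa, fb)
    phi <- (sqrt(5) - 1) / 2
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- gap_lp(j, x1); f2 <- gap_lp(j, x2)
    for (it in seq_len(golden_iters)) {
      if (f1 <= f2) {
        b <- x2; x2 <- x1; f2 <- f1; x1 <- b - phi * (b - a); f1 <- gap_lp(j, x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2; x2 <- a + phi * (b - a); f2 <- gap_lp(j, x2)
      }
    }
    best <- min(best, f1, f2)
  }
  best
}

# build an mms_series directly from amplitude values (fixture helper)
new_mms_for_test <- function(values, times = seq_along(values) * 0.5) {
  gaitmms:::new_mms(
    tibble::tibble(peak_index = seq_along(values),
                   peak_time_s = times,
                   value = values,
                   value_centered = NA_real_,
                   interval_prev_s = c(NA_real_, diff(times))),
    rate_hz = 100, source_unit = "unitless")
}

# run feedback detection on a simulated pair; shared by unit and acceptance
# tests
run_feedback <- function(pair, lags = 1:5, alpha = 0.01, B = 199, seed = 1) {
  sab <- lag_sweep(pair$x, pair$y, lags, "ols", "strict")
  sba <- lag_sweep(pair$y, pair$x, lags, "ols", "strict")
  gab <- gc_significance(pair$x, pair$y, lags, "ols", "strict", alpha = alpha,
                         n_surrogates = B, seed = seed, sweep = sab)
  gba <- gc_significance(pair$y, pair$x, lags, "ols", "strict", alpha = alpha,
                         n_surrogates = B, seed = seed + 7777, sweep = sba)
  detect_feedback(sab, sba, gab, gba)
}
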