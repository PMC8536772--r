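#' Gamma stochastic signature of a positive sample
#'
#' MLE gamma fit of the (uncentered) MMS amplitudes. The fitted scale is the
#' noise-to-signal ratio (NSR): for a gamma variate, variance / mean
#' `= (a b^2)/(a b) = b`. Sample skewness is the adjusted Fisher-Pearson
#' coefficient.
#'
#' @param values Strictly positive numeric values, `n >= 20`.
#' @return A one-row tibble: `gamma_shape`, `gamma_scale`, `nsr`
#'   (`= gamma_scale`), `skewness`, `n`.
#' @export
gamma_signature <- function(values) {
  if (length(values) < 20L) {
    stop("gamma signature needs at least 20 values", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("gamma signature requires strictly positive values", call. = FALSE)
  }
  fit <- fit_gamma_mle(values)
  tibble::tibble(gamma_shape = fit$shape, gamma_scale = fit$scale,
                 nsr = fit$scale, skewness = sample_skewness(values),
                 n = length(values))
}

# adjusted Fisher-Pearson sample skewness
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Exponential + Gaussian mode decomposition
#'
#' Fits a two-component mixture to MMS amplitude values by expectation-
#' maximization: mode 1 is an exponential anchored at the sample minimum
#' (the low-amplitude, memoryless mode), mode 2 a Gaussian (the rhythmic
#' mode). Points are assigned by maximal posterior responsibility;
#' `mode1_fraction` is the assigned share of points and the dominant mode is
#' the one holding the larger share.
#'
#' @param values Numeric values, `n >= 50`.
#' @param seed Integer seed (initialisation is deterministic, but kept for
#'   interface symmetry with stochastic alternatives).
#' @param max_iter,tol EM stopping controls.
#' @return A list of class `mode_decomposition`: `mode1_fraction`,
#'   `mode2_fraction`, `mode1_rate`, `mode2_mean`, `mode2_sd`, `weight1`
#'   (mixture weight), `dominant_mode` (`"exponential"` or `"gaussian"`),
#'   `responsibilities` (n x 2 matrix), `log_lik` (trace, non-decreasing),
#'   `converged`, `effectively_unimodal`.
#' @export
mode_decompose <- function(values, seed = NULL, max_iter = 500, tol = 1e-8) {
  n <- length(values)
  if (n < 50L) stop("mode decomposition needs at least 50 values", call. = FALSE)
  x0 <- min(values)
  z <- values - x0                       # exponential support anchor
  # deterministic split initialisation at the lower quartile
  q <- stats::quantile(values, 0.25, names = FALSE)
  low <- values <= q
  w <- mean(low)
  rate <- 1 / max(mean(z[low]), 1e-8)
  mu <- mean(values[!low]); sd2 <- max(stats::sd(values[!low]), 1e-6)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dexp(z, rate)
    d2 <- (1 - w) * stats::dnorm(values, mu, sd2)
    tot <- d1 + d2
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    r1 <- d1 / tot
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    s1 <- sum(r1)
    w <- min(max(s1 / n, 1e-10), 1 - 1e-10)
    rate <- s1 / max(sum(r1 * z), 1e-12)
    s2 <- n - s1
    mu <- sum((1 - r1) * values) / max(s2, 1e-12)
    sd2 <- sqrt(sum((1 - r1) * (values - mu)^2) / max(s2, 1e-12))
    sd2 <- max(sd2, 1e-8)
  }
  if (!converged) {
    warning("EM reached max_iter without meeting the tolerance", call. = FALSE)
  }
  resp <- cbind(exponential = r1, gaussian = 1 - r1)
  assign1 <- r1 > 0.5
  frac1 <- mean(assign1)
  unimodal <- w < 0.02 || w > 0.98
  structure(list(
    mode1_fraction = frac1, mode2_fraction = 1 - frac1,
    mode1_rate = rate, mode2_mean = mu, mode2_sd = sd2,
    weight1 = w, anchor = x0,
    dominant_mode = if (frac1 >= 0.5) "exponential" else "gaussian",
    responsibilities = resp, log_lik = ll_trace,
    converged = converged, effectively_unimodal = unimodal
  ), class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf(
    "<mode_decomposition> %.1f%% exponential (rate %.3g) / %.1f%% gaussian (mean %.3g, sd %.3g)%s\n",
    100 * x$mode1_fraction, x$mode1_rate, 100 * x$mode2_fraction,
    x$mode2_mean, x$mode2_sd,
    if (x$effectively_unimodal) " [effectively unimodal]" else ""))
  invisible(x)
}

#' @export
tidy.mode_decomposition <- function(x, ...) {
  tibble::tibble(
    mode = c("exponential", "gaussian"),
    fraction = c(x$mode1_fraction, x$mode2_fraction),
    weight = c(x$weight1, 1 - x$weight1),
    parameter_1 = c(x$mode1_rate, x$mode2_mean),
    parameter_2 = c(NA_real_, x$mode2_sd)
  )
}

#' @export
glance.mode_decomposition <- function(x, ...) {
  tibble::tibble(mode1_fraction = x$mode1_fraction,
                 dominant_mode = x$dominant_mode,
                 log_lik = x$log_lik[length(x$log_lik)],
                 iterations = length(x$log_lik),
                 converged = x$converged,
                 effectively_unimodal = x$effectively_unimodal)
}

#' Full stochastic signature of an MMS series
#'
#' Combines the gamma NSR/skewness, the dip test and the mode decomposition
#' into one per-signal feature row. Signals with fewer than `min_peaks`
#' spikes yield `NA` signature fields (reported missing, not fitted).
#'
#' @param mms An `mms_series`.
#' @param n_boot,seed Passed to [dip_test()].
#' @param min_peaks Minimum spike count to attempt fits.
#' @return One-row tibble of class `stochastic_signature`.
#' @export
stochastic_signature <- function(mms, n_boot = 2000, seed = NULL,
                                 min_peaks = 20) {
  v <- mms$value
  if (length(v) < min_peaks) {
    return(structure(tibble::tibble(
      gamma_shape = NA_real_, gamma_scale = NA_real_, nsr = NA_real_,
      skewness = NA_real_, dip_statistic = NA_real_, dip_p = NA_real_,
      mode1_fraction = NA_real_, dominant_mode = NA_character_,
      n_peaks = length(v)
    ), class = c("stochastic_signature", class(tibble::tibble()))))
  }
  gs <- gamma_signature(v)
  dp <- dip_test(v, n_boot = n_boot, seed = seed)
  md <- if (length(v) >= 50L) mode_decompose(v, seed = seed) else NULL
  structure(tibble::tibble(
    gamma_shape = gs$gamma_shape, gamma_scale = gs$gamma_scale, nsr = gs$nsr,
    skewness = gs$skewness, dip_statistic = dp$dip, dip_p = dp$p_value,
    mode1_fraction = if (is.null(md)) NA_real_ else md$mode1_fraction,
    dominant_mode = if (is.null(md)) NA_character_ else md$dominant_mode,
    n_peaks = length(v)
  ), class = c("stochastic_signature", class(tibble::tibble())))
}

#' Joint amplitude-timing histogram of an MMS series
#'
#' 2-D histogram of (normalized peak amplitude, preceding inter-peak
#' interval) with a chi-square independence diagnostic (reported as a
#' diagnostic only — spike amplitude/timing dependence is expected in real
#' gait).
#'
#' @param mms An `mms_series` with at least 2 peaks.
#' @param bins Number of bins per axis (default 10).
#' @return A list: `counts` (bins x bins matrix), `amplitude_breaks`,
#'   `interval_breaks`, `chisq_stat`, `chisq_p`, `n`.
#' @export
amplitude_timing_hist2d <- function(mms, bins = 10) {
  df <- tibble::as_tibble(mms)
  df <- df[!is.na(df$interval_prev_s), ]
  if (nrow(df) < 1L) stop("need at least 2 peaks", call. = FALSE)
  ab <- seq(min(df$value), max(df$value), length.out = bins + 1L)
  ib <- seq(min(df$interval_prev_s), max(df$interval_prev_s),
            length.out = bins + 1L)
  ai <- pmin(pmax(findInterval(df$value, ab, rightmost.closed = TRUE), 1L), bins)
  ii <- pmin(pmax(findInterval(df$interval_prev_s, ib, rightmost.closed = TRUE), 1L), bins)
  counts <- table(factor(ai, levels = seq_len(bins)),
                  factor(ii, levels = seq_len(bins)))
  counts <- matrix(as.integer(counts), bins, bins)
  # chi-square on a coarse quantile partition so expected counts stay sane
  k <- max(2L, min(4L, floor(sqrt(nrow(df) / 5))))
  qa <- cut(df$value, stats::quantile(df$value, seq(0, 1, length.out = k + 1)),
            include.lowest = TRUE)
  qi <- cut(df$interval_prev_s,
            stats::quantile(df$interval_prev_s, seq(0, 1, length.out = k + 1)),
            include.lowest = TRUE)
  ct <- suppressWarnings(stats::chisq.test(table(qa, qi)))
  list(counts = counts, amplitude_breaks = ab, interval_breaks = ib,
       chisq_stat = unname(ct$statistic), chisq_p = ct$p.value, n = nrow(df))
}
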