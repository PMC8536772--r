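#' Detect strict local maxima and their flanking minima
#'
#' Peaks are transitions of the slope from positive to negative. Runs of equal
#' consecutive samples (plateaus) are represented by their first sample, so
#' tie-breaking is deterministic. Each peak is paired with the nearest local
#' minimum before and after it; when no interior minimum exists on a side the
#' boundary sample is used. Boundary samples are never peaks.
#'
#' @param x Numeric series, length >= 3.
#' @param rate_hz Sampling rate used to convert indices to seconds.
#' @param min_prominence Optional absolute prominence floor: peaks rising less
#'   than this above the mean of their flanking minima are dropped. 0 (the
#'   default) applies no filter.
#' @return A tibble with columns `peak_index`, `peak_time_s`, `min_before`,
#'   `min_after` (indices into `x`). A monotone series yields zero rows.
#' @export
detect_peaks <- function(x, rate_hz = 1, min_prominence = 0) {
  if (length(x) < 3L) stop("series must have at least 3 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  # compress runs of equal values; keep first index of each run
  r <- rle(x)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  m <- length(vals)
  empty <- tibble::tibble(peak_index = integer(), peak_time_s = numeric(),
                          min_before = integer(), min_after = integer())
  if (m < 3L) return(empty)
  d <- sign(diff(vals))                    # +1 rising, -1 falling (no zeros)
  interior <- 2:(m - 1L)
  is_peak <- d[interior - 1L] > 0 & d[interior] < 0
  is_min  <- d[interior - 1L] < 0 & d[interior] > 0
  peak_runs <- interior[is_peak]
  if (length(peak_runs) == 0L) return(empty)
  min_runs <- interior[is_min]
  peak_idx <- starts[peak_runs]
  min_idx <- starts[min_runs]
  # nearest local minimum strictly before / after each peak; boundary fallback
  before <- vapply(peak_idx, function(p) {
    cand <- min_idx[min_idx < p]
    if (length(cand)) max(cand) else 1L
  }, integer(1))
  after <- vapply(peak_idx, function(p) {
    cand <- min_idx[min_idx > p]
    if (length(cand)) min(cand) else length(x)
  }, integer(1))
  out <- tibble::tibble(
    peak_index = peak_idx,
    peak_time_s = (peak_idx - 1L) / rate_hz,
    min_before = before,
    min_after = after
  )
  if (min_prominence > 0) {
    prom <- x[out$peak_index] - (x[out$min_before] + x[out$min_after]) / 2
    out <- out[prom >= min_prominence, , drop = FALSE]
  }
  out
}

# Quantize normalized amplitudes to a 2^-26 grid (~1.5e-8). The ratio
# p/(p + m) is scale-invariant in exact arithmetic but not bitwise in doubles
# (fl(c*p) and fl(c*m) round independently); snapping to a grid far below any
# sensor's amplitude resolution makes the standardization literally exact.
quantize_unit <- function(v) round(v * 67108864) / 67108864

#' Normalize detected peaks into micro-movement spikes
#'
#' Each peak amplitude `p` is standardized by the average `m` of its two
#' flanking minima: `value = p / (p + m)`, a unitless quantity in (0, 1] that
#' cancels amplitude scale and hence anatomical differences. Values equal 1
#' only when both flanking minima are 0. Peaks with non-positive amplitude are
#' skipped with a warning.
#'
#' @param x The original scalar series (non-negative amplitudes).
#' @param peaks Result of [detect_peaks()] on `x`.
#' @param rate_hz Sampling rate in Hz.
#' @param source_unit Physical unit of `x`, carried as metadata.
#' @return A tibble of class `mms_series` with columns `peak_index`,
#'   `peak_time_s`, `value` (uncentered), `value_centered` (`NA` until
#'   [gamma_center()] is applied) and `interval_prev_s`; attributes `rate_hz`,
#'   `source_unit`, `centered`, `gamma_shape`, `gamma_scale`.
#' @export
normalize_peaks <- function(x, peaks, rate_hz = 1, source_unit = "unitless") {
  p <- x[peaks$peak_index]
  keep <- p > 0
  if (any(!keep)) {
    warning(sprintf("skipped %d non-positive peak(s)", sum(!keep)), call. = FALSE)
    peaks <- peaks[keep, , drop = FALSE]
    p <- p[keep]
  }
  mbar <- (x[peaks$min_before] + x[peaks$min_after]) / 2
  value <- quantize_unit(p / (p + mbar))
  new_mms(tibble::tibble(
    peak_index = peaks$peak_index,
    peak_time_s = peaks$peak_time_s,
    value = value,
    value_centered = NA_real_,
    interval_prev_s = c(NA_real_, diff(peaks$peak_time_s))
  ), rate_hz = rate_hz, source_unit = source_unit)
}

new_mms <- function(df, rate_hz, source_unit, centered = FALSE,
                    gamma_shape = NA_real_, gamma_scale = NA_real_) {
  structure(df,
            rate_hz = rate_hz, source_unit = source_unit, centered = centered,
            gamma_shape = gamma_shape, gamma_scale = gamma_scale,
            class = c("mms_series", class(tibble::tibble())))
}

#' @export
print.mms_series <- function(x, ...) {
  cat(sprintf("<mms_series> %d spikes%s [source: %s]\n", nrow(x),
              if (isTRUE(attr(x, "centered"))) " (gamma-centered)" else "",
              attr(x, "source_unit")))
  NextMethod()
}

#' Extract a micro-movement spike series from a scalar signal
#'
#' Convenience wrapper: [detect_peaks()] then [normalize_peaks()], optionally
#' followed by [gamma_center()].
#'
#' @param x Non-negative scalar series (e.g. angular speed in rad/s).
#' @param rate_hz Sampling rate in Hz.
#' @param center If `TRUE`, subtract the MLE gamma-fitted mean (requires at
#'   least `min_peaks` spikes).
#' @param min_peaks Minimum spike count for the gamma fit (default 20).
#' @param source_unit Physical unit of `x`.
#' @return An `mms_series` tibble; see [normalize_peaks()].
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' mms <- mms_extract(1 + sin(2 * pi * 2 * t)^2, rate_hz = 100)
#' nrow(mms)  # ~20 peaks for a 2 Hz rhythm over 10 s
mms_extract <- function(x, rate_hz, center = FALSE, min_peaks = 20,
                        source_unit = "unitless") {
  mms <- normalize_peaks(x, detect_peaks(x, rate_hz), rate_hz = rate_hz,
                         source_unit = source_unit)
  if (center) mms <- gamma_center(mms, min_peaks = min_peaks)
  mms
}

#' Subtract the gamma-fitted mean from MMS amplitudes
#'
#' Fits a gamma distribution to the uncentered spike amplitudes by maximum
#' likelihood and stores `value_centered = value - shape * scale`. The fitted
#' parameters are retained so that the subtracted mean is reproducible as
#' `shape * scale`.
#'
#' @param mms An uncentered `mms_series`.
#' @param min_peaks Minimum number of spikes required for the fit.
#' @return The centered `mms_series`.
#' @export
gamma_center <- function(mms, min_peaks = 20) {
  v <- mms$value
  if (length(v) < min_peaks) {
    stop(sprintf("gamma fit needs at least %d spikes (have %d)",
                 min_peaks, length(v)), call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    stop("gamma fit undefined for a constant amplitude series", call. = FALSE)
  }
  fit <- fit_gamma_mle(v)
  out <- mms
  out$value_centered <- v - fit$shape * fit$scale
  new_mms(tibble::as_tibble(out), rate_hz = attr(mms, "rate_hz"),
          source_unit = attr(mms, "source_unit"), centered = TRUE,
          gamma_shape = fit$shape, gamma_scale = fit$scale)
}

# Exact gamma MLE via the profile likelihood: the scale profiles out as
# mean/shape and the shape solves log(a) - digamma(a) = log(mean) - mean(log),
# solved by Newton. Deterministic and scale-equivariant to machine precision,
# which generic-optimizer fits are not.
fit_gamma_mle <- function(v) {
  v <- as.numeric(v)
  if (any(v <= 0)) stop("gamma fit requires strictly positive values", call. = FALSE)
  mbar <- mean(v)
  s <- log(mbar) - mean(log(v))
  if (!is.finite(s) || s <= 0) {
    stop("gamma MLE undefined: zero-variance or degenerate sample", call. = FALSE)
  }
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)   # Minka initialisation
  for (it in 1:100) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
    a <- a_new
    if (it == 100) stop("gamma MLE did not converge", call. = FALSE)
  }
  list(shape = a, scale = mbar / a)
}

#' Inter-peak interval series and summary
#'
#' @param mms An `mms_series` with at least 2 spikes.
#' @return A list with `intervals` (tibble: `interval_s`), `mean_s`, `sd_s`.
#' @export
inter_peak_intervals <- function(mms) {
  if (nrow(mms) < 2L) stop("need at least 2 peaks for intervals", call. = FALSE)
  iv <- diff(mms$peak_time_s)
  list(intervals = tibble::tibble(interval_s = iv),
       mean_s = mean(iv), sd_s = stats::sd(iv))
}

#' Write an MMS series as CSV with a JSON gamma sidecar
#'
#' @param mms An `mms_series`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mms <- function(mms, path) {
  df <- tibble::as_tibble(mms)[, c("peak_time_s", "value", "value_centered",
                                   "interval_prev_s")]
  readr::write_csv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(rate_hz = attr(mms, "rate_hz"), source_unit = attr(mms, "source_unit"),
         centered = isTRUE(attr(mms, "centered")),
         gamma_shape = attr(mms, "gamma_shape"),
         gamma_scale = attr(mms, "gamma_scale")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MMS spike train
#'
#' @param object An `mms_series`.
#' @param centered Plot centered values when available.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mms_series <- function(object, centered = FALSE, ...) {
  df <- tibble::as_tibble(object)
  y <- if (centered && isTRUE(attr(object, "centered"))) df$value_centered else df$value
  ggplot2::ggplot(tibble::tibble(t = df$peak_time_s, v = y),
                  ggplot2::aes(x = .data$t, xend = .data$t, y = 0, yend = .data$v)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (centered) "MMS (centered)" else "MMS amplitude") +
    ggplot2::theme_minimal()
}
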