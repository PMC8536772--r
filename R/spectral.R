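# Welch-style segment-averaged spectra: shared engine for coherence and PSD.
# Segments are demeaned, Hann-tapered, 50% overlapped by default.
welch_segments <- function(n, rate_hz, window_s = 4, overlap = 0.5) {
  nseg <- max(8L, min(n, round(window_s * rate_hz)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  list(nseg = nseg, starts = starts,
       taper = 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)))
}

welch_cross <- function(x, y, rate_hz, window_s = 4, overlap = 0.5) {
  n <- min(length(x), length(y))
  if (n < 2L * round(window_s * rate_hz)) {
    stop("series shorter than two analysis windows", call. = FALSE)
  }
  w <- welch_segments(n, rate_hz, window_s, overlap)
  nf <- w$nseg %/% 2L
  sxx <- syy <- numeric(nf + 1L)
  sxy <- complex(nf + 1L)
  for (s in w$starts) {
    xi <- x[s:(s + w$nseg - 1L)]; yi <- y[s:(s + w$nseg - 1L)]
    xi <- (xi - mean(xi)) * w$taper
    yi <- (yi - mean(yi)) * w$taper
    fx <- stats::fft(xi)[1:(nf + 1L)]
    fy <- stats::fft(yi)[1:(nf + 1L)]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  list(frequency_hz = (0:nf) * rate_hz / w$nseg,
       sxx = sxx, syy = syy, sxy = sxy, n_segments = length(w$starts))
}

#' Magnitude-squared cross-coherence between two series
#'
#' Segment-averaged (Welch) coherence: the cross-spectral density normalized
#' by the product of the auto-spectral densities,
#' `C(f) = |Sxy(f)|^2 / (Sxx(f) Syy(f))`, bounded in \[0, 1\]. The coupling
#' frequency is the non-DC frequency at which the coherence is maximal (ties
#' resolve to the lowest frequency); the DC bin is excluded because nonzero-
#' mean spike trains are trivially coherent there.
#'
#' @param x,y Sample-indexed series of equal length (e.g. MMS spike trains
#'   from [mms_spike_train()], or raw speed series).
#' @param rate_hz Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 4 s: at least 8
#'   segments on a 3-minute walk while resolving the gait band).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A tibble of class `coherence_result` with columns `frequency_hz`,
#'   `coherence`, `phase_lag_rad`; attributes `max_coherence`,
#'   `coupling_frequency_hz`, `n_segments`.
#' @export
cross_coherence <- function(x, y, rate_hz, window_s = 4, overlap = 0.5) {
  cs <- welch_cross(x, y, rate_hz, window_s, overlap)
  coh <- Mod(cs$sxy)^2 / (cs$sxx * cs$syy)
  coh[!is.finite(coh)] <- 0
  phase <- Arg(cs$sxy)
  out <- tibble::tibble(frequency_hz = cs$frequency_hz, coherence = coh,
                        phase_lag_rad = phase)
  nondc <- which(out$frequency_hz > 0)
  imax <- nondc[which.max(out$coherence[nondc])]
  structure(out,
            max_coherence = out$coherence[imax],
            coupling_frequency_hz = out$frequency_hz[imax],
            n_segments = cs$n_segments,
            class = c("coherence_result", class(tibble::tibble())))
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> max %.3f at %.3g Hz (%d segments)\n",
              attr(x, "max_coherence"), attr(x, "coupling_frequency_hz"),
              attr(x, "n_segments")))
  NextMethod()
}

#' @export
glance.coherence_result <- function(x, ...) {
  tibble::tibble(max_coherence = attr(x, "max_coherence"),
                 coupling_frequency_hz = attr(x, "coupling_frequency_hz"),
                 n_segments = attr(x, "n_segments"))
}

#' Plot a coherence spectrum
#' @param object A `coherence_result`.
#' @param ... Unused.
#' @return A ggplot object with the coupling frequency marked.
#' @export
autoplot.coherence_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency_hz, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "coupling_frequency_hz"),
                        linetype = "dashed", colour = "red3") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude-squared coherence") +
    ggplot2::theme_minimal()
}

#' Sample-indexed spike-train representation of an MMS series
#'
#' Places each normalized peak amplitude at its sample position, with zeros
#' (default) or linear interpolation between peaks — the representation used
#' by the frequency-domain analyses, which operate on the full time series
#' rather than only the peak sequence.
#'
#' @param mms An `mms_series`.
#' @param n_samples Length of the output train (defaults to span of peaks).
#' @param fill `"zero"` or `"interpolate"`.
#' @param centered Use centered values when available.
#' @return Numeric vector of length `n_samples`.
#' @export
mms_spike_train <- function(mms, n_samples = NULL, fill = c("zero", "interpolate"),
                            centered = FALSE) {
  fill <- match.arg(fill)
  idx <- mms$peak_index
  if (is.null(n_samples)) n_samples <- max(idx)
  v <- if (centered && isTRUE(attr(mms, "centered"))) mms$value_centered else mms$value
  keep <- idx <= n_samples
  idx <- idx[keep]; v <- v[keep]
  if (fill == "zero") {
    train <- numeric(n_samples)
    train[idx] <- v
  } else {
    train <- stats::approx(idx, v, xout = seq_len(n_samples), rule = 2)$y
  }
  train
}

#' Per-node average maximal coherence
#'
#' The mean over partners of the maximal cross-coherence of a node's series
#' with every other node's series.
#'
#' @param results Named list (by partner node) of `coherence_result`s for one
#'   node.
#' @return Scalar mean of the partners' maximal coherences.
#' @export
node_mean_coherence <- function(results) {
  if (length(results) < 1L) stop("singleton network: no partners", call. = FALSE)
  mean(vapply(results, function(r) attr(r, "max_coherence"), numeric(1)))
}

#' Mean frequency of a spectrum
#'
#' Power-weighted mean `sum(f * P) / sum(P)` over the spectrum bins.
#'
#' @param frequency_hz Bin central frequencies (Hz).
#' @param power Non-negative spectral density values, same length.
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(frequency_hz, power) {
  if (length(frequency_hz) != length(power)) {
    stop("frequency and power grids differ in length", call. = FALSE)
  }
  if (any(power < 0)) stop("power values must be non-negative", call. = FALSE)
  tot <- sum(power)
  if (tot <= 0) stop("all-zero power spectrum", call. = FALSE)
  sum(frequency_hz * power) / tot
}

#' Welch power spectral density of a demeaned series
#'
#' @param x Numeric series.
#' @param rate_hz Sampling rate.
#' @param window_s,overlap See [cross_coherence()].
#' @param drop_dc Drop the DC bin (default `TRUE`; the series is demeaned per
#'   segment anyway).
#' @return Tibble: `frequency_hz`, `power`.
#' @export
welch_psd <- function(x, rate_hz, window_s = 4, overlap = 0.5, drop_dc = TRUE) {
  cs <- welch_cross(x, x, rate_hz, window_s, overlap)
  out <- tibble::tibble(frequency_hz = cs$frequency_hz, power = cs$sxx)
  if (drop_dc) out <- out[out$frequency_hz > 0, ]
  out
}

#' Band-stop noise-cancellation probe
#'
#' Zero-phase band-stop filters a signal (Butterworth forward-backward), then
#' recomputes the MMS gamma noise-to-signal ratio, returning it before and
#' after filtering. A zero-width band is the identity. Used to quantify how
#' much of the gamma noise signature is carried by a candidate tremor band.
#'
#' @param x Non-negative scalar series.
#' @param rate_hz Sampling rate in Hz.
#' @param band_hz Length-2 numeric `c(low, high)` inside (0, rate/2).
#' @param order Butterworth order (default 4).
#' @param min_peaks Minimum spike count for the gamma fits.
#' @return A list: `nsr_before`, `nsr_after`, `filtered` (the filtered series).
#' @export
band_stop_probe <- function(x, rate_hz, band_hz, order = 4, min_peaks = 20) {
  if (length(band_hz) != 2L || any(band_hz < 0) || any(band_hz >= rate_hz / 2)) {
    stop("band must lie within (0, rate/2)", call. = FALSE)
  }
  band_hz <- sort(band_hz)
  # zero-phase filtering leaves micro-ripples on smooth stretches of the
  # signal; a prominence floor relative to the unfiltered peak structure keeps
  # those numerical ripples out of both NSR estimates
  pk0 <- detect_peaks(x, rate_hz)
  prom0 <- stats::median(x[pk0$peak_index] -
                           (x[pk0$min_before] + x[pk0$min_after]) / 2)
  floor_prom <- 0.05 * prom0
  # forward-backward filtering leaves start-up transients at both ends; both
  # NSR estimates are taken on the same trimmed interior
  margin <- min(round(2 * rate_hz), (length(x) - 10) %/% 4)
  interior <- (margin + 1L):(length(x) - margin)
  nsr_of <- function(sig) {
    sig <- sig[interior]
    pk <- detect_peaks(sig, rate_hz, min_prominence = floor_prom)
    mms <- normalize_peaks(sig, pk, rate_hz = rate_hz)
    mms <- gamma_center(mms, min_peaks = min_peaks)
    attr(mms, "gamma_scale")
  }
  before <- nsr_of(pmax(x, 0))
  if (diff(band_hz) == 0) {
    return(list(nsr_before = before, nsr_after = before, filtered = x))
  }
  bf <- signal::butter(order, band_hz / (rate_hz / 2), type = "stop")
  filtered <- as.numeric(signal::filtfilt(bf, x))
  list(nsr_before = before, nsr_after = nsr_of(pmax(filtered, 0)),
       filtered = filtered)
}
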