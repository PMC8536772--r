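# seed-scoped RNG: run expr with a local seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Ground-truth specification for the synthetic gait generator
#'
#' Describes a quasi-periodic multi-node walk with known structure: cadence
#' near 1 Hz with log-normal cycle-period jitter, gamma-distributed (or
#' exponential+Gaussian mixture) peak-amplitude jitter, directed spike-level
#' couplings between nodes, and optional tremor-band sinusoids. Peak
#' normalization maps amplitudes `p` with flanking troughs at `floor_level`
#' to `p / (p + floor_level)`, so planted normalized amplitudes must lie in
#' (0.5, 1); the defaults concentrate them near 0.7 with negligible mass
#' outside the representable range.
#'
#' @param nodes Character vector of node names.
#' @param cadence_hz Stride cadence (cycles per second).
#' @param cadence_jitter_sd SD of the log-normal cycle-period multiplier.
#' @param amplitude_shape,amplitude_scale Gamma parameters of the planted
#'   normalized peak amplitudes.
#' @param mode_mixture Optional list
#'   `list(weight1, rate1, mean2, sd2)`: with probability `weight1` an
#'   amplitude is `0.5 + Exp(rate1)`, otherwise `N(mean2, sd2)` — the
#'   exponential + Gaussian amplitude regime.
#' @param couplings Tibble or data frame with columns `source`, `target`,
#'   `gain`, `lag` (lag in spikes): the target's centered amplitude sequence
#'   receives `gain` times the source's centered amplitude `lag` spikes
#'   earlier.
#' @param tremor Optional tibble `node`, `frequency_hz`, `amplitude`.
#' @param floor_level Trough level of the carrier (signal units).
#' @param noise_sd SD of additive measurement noise on the carrier.
#' @param com_mean_speed_ms,com_osc_amplitude Mean and oscillation amplitude
#'   of the derived `com_speed` channel (m/s).
#' @return A list of class `gait_truth`.
#' @export
gait_truth <- function(nodes = c("pelvis", "thorax", "arm_left", "arm_right",
                                 "foot_left", "foot_right"),
                       cadence_hz = 1, cadence_jitter_sd = 0.05,
                       amplitude_shape = 100, amplitude_scale = 0.007,
                       mode_mixture = NULL,
                       couplings = NULL, tremor = NULL,
                       floor_level = 0.5, noise_sd = 0,
                       com_mean_speed_ms = 1.2, com_osc_amplitude = 0.5) {
  if (cadence_hz <= 0) stop("cadence must be positive", call. = FALSE)
  if (!is.null(couplings)) {
    couplings <- tibble::as_tibble(couplings)
    stopifnot(all(c("source", "target", "gain", "lag") %in% names(couplings)))
    if (any(couplings$lag < 1)) stop("coupling lags must be positive integers",
                                     call. = FALSE)
    bad <- setdiff(unique(c(couplings$source, couplings$target)), nodes)
    if (length(bad)) stop("coupling references unknown node(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, cadence_hz = cadence_hz,
                 cadence_jitter_sd = cadence_jitter_sd,
                 amplitude_shape = amplitude_shape,
                 amplitude_scale = amplitude_scale,
                 mode_mixture = mode_mixture,
                 couplings = couplings, tremor = tremor,
                 floor_level = floor_level, noise_sd = noise_sd,
                 com_mean_speed_ms = com_mean_speed_ms,
                 com_osc_amplitude = com_osc_amplitude),
            class = "gait_truth")
}

# draw planted normalized amplitudes in (0.5, 0.98)
draw_amplitudes <- function(truth, k) {
  if (is.null(truth$mode_mixture)) {
    v <- stats::rgamma(k, shape = truth$amplitude_shape,
                       scale = truth$amplitude_scale)
  } else {
    mm <- truth$mode_mixture
    pick1 <- stats::runif(k) < mm$weight1
    v <- ifelse(pick1,
                0.5 + stats::rexp(k, rate = mm$rate1),
                stats::rnorm(k, mm$mean2, mm$sd2))
  }
  pmin(pmax(v, 0.505), 0.98)
}

#' Simulate one subject's walk with known ground truth
#'
#' Per node, a rectified quasi-periodic carrier (one raised-sine bump per
#' stride cycle, troughs at `floor_level`) whose peak amplitudes are the
#' planted normalized values mapped back through the standardization
#' (`p = floor * v / (1 - v)`). Spike-level couplings add the lagged,
#' centered source amplitudes into the target before the mapping, giving the
#' downstream causality analysis a known optimal lag. A `com_speed` channel
#' (m/s) with configurable mean speed is appended for stride-proxy analyses.
#' Fully reproducible under `seed`.
#'
#' @param truth A [gait_truth()] specification.
#' @param duration_s Walk duration in seconds (>= 10).
#' @param rate_hz Sampling rate (>= 20).
#' @param seed Integer seed.
#' @param subject_id,group_label Metadata for the recording.
#' @return A list: `recording` (a [kin_recording()] with one column per node
#'   plus `com_speed`), `truth` (the input truth object plus the per-node planted amplitude
#'   sequences and peak times under `$planted`).
#' @export
#' @examples
#' sim <- simulate_subject(gait_truth(), duration_s = 30, rate_hz = 60, seed = 1)
#' sim$recording
simulate_subject <- function(truth, duration_s = 180, rate_hz = 100,
                             seed = NULL, subject_id = NA_character_,
                             group_label = NA_character_) {
  stopifnot(inherits(truth, "gait_truth"))
  if (duration_s < 10) stop("duration must be at least 10 s", call. = FALSE)
  if (rate_hz < 20) stop("sampling rate must be at least 20 Hz", call. = FALSE)
  with_seed(seed, {
    # shared jittered cycle clock
    n_cycles <- ceiling(duration_s * truth$cadence_hz * 1.5) + 10L
    periods <- (1 / truth$cadence_hz) *
      exp(stats::rnorm(n_cycles, 0, truth$cadence_jitter_sd))
    bounds <- c(0, cumsum(periods))
    keep <- which(bounds[-1] <= duration_s)
    if (length(keep) < 3L) stop("duration too short for this cadence", call. = FALSE)
    starts <- bounds[keep]
    periods <- periods[keep]
    k <- length(keep)
    if (!is.null(truth$couplings) && any(truth$couplings$lag >= k)) {
      stop("coupling lag exceeds the expected spike count", call. = FALSE)
    }
    # planted normalized amplitudes per node, then spike-level coupling
    amps <- lapply(truth$nodes, function(nd) draw_amplitudes(truth, k))
    names(amps) <- truth$nodes
    if (!is.null(truth$couplings)) {
      base <- amps
      for (r in seq_len(nrow(truth$couplings))) {
        cp <- truth$couplings[r, ]
        l <- as.integer(cp$lag)
        src <- base[[cp$source]] - mean(base[[cp$source]])
        tgt <- amps[[cp$target]]
        tgt[(l + 1L):k] <- tgt[(l + 1L):k] + cp$gain * src[1:(k - l)]
        amps[[cp$target]] <- pmin(pmax(tgt, 0.505), 0.98)
      }
    }
    t_grid <- seq(0, duration_s, by = 1 / rate_hz)
    cyc <- pmin(pmax(findInterval(t_grid, starts), 1L), k)
    phase <- (t_grid - starts[cyc]) / periods[cyc]
    bump <- sin(pi * pmin(phase, 1))^2
    m0 <- truth$floor_level
    channels <- lapply(truth$nodes, function(nd) {
      p <- m0 * amps[[nd]] / (1 - amps[[nd]])   # invert v = p / (p + m0)
      sig <- m0 + (p[cyc] - m0) * bump
      if (truth$noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, truth$noise_sd)
      if (!is.null(truth$tremor)) {
        tr <- truth$tremor[truth$tremor$node == nd, , drop = FALSE]
        for (rr in seq_len(nrow(tr))) {
          sig <- sig + tr$amplitude[rr] * sin(2 * pi * tr$frequency_hz[rr] * t_grid)
        }
      }
      sig
    })
    names(channels) <- truth$nodes
    channels$com_speed <- (truth$com_mean_speed_ms - truth$com_osc_amplitude / 2) +
      truth$com_osc_amplitude * bump
    rec <- kin_recording(tibble::as_tibble(channels), rate_hz = rate_hz,
                         unit = "rad/s", subject_id = subject_id,
                         group_label = group_label)
    tr <- truth
    tr$planted <- list(amplitudes = amps, cycle_starts = starts,
                       peak_times_s = starts + periods / 2, n_cycles = k)
    list(recording = rec, truth = tr)
  })
}

#' Simulate a cohort of subjects across groups
#'
#' Each group is a [gait_truth()] spec; per subject, the cadence and (when a
#' mode mixture is present) the exponential-mode weight are drawn around the
#' group means so that subjects vary realistically within groups.
#'
#' @param groups Named list of [gait_truth()] specs, one per group.
#' @param n_per_group Subjects per group (scalar or per-group vector).
#' @param seed Integer seed.
#' @param duration_s,rate_hz Passed to [simulate_subject()].
#' @param cadence_sd Between-subject SD of cadence (Hz).
#' @param weight_sd Between-subject SD of the exponential-mode weight.
#' @return A list: `subjects` (list of [simulate_subject()] results) and
#'   `truth_table` (tibble: subject_id, group_label, cadence_hz,
#'   mode1_weight, n_cycles).
#' @export
simulate_cohort <- function(groups, n_per_group = 5, seed = 1,
                            duration_s = 180, rate_hz = 100,
                            cadence_sd = 0.05, weight_sd = 0.05) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list of gait_truth specs", call. = FALSE)
  }
  if (length(n_per_group) == 1L) {
    n_per_group <- rep(n_per_group, length(groups))
  }
  if (any(n_per_group < 1L)) stop("need at least 1 subject per group", call. = FALSE)
  with_seed(seed, {
    subjects <- list()
    rows <- list()
    for (gi in seq_along(groups)) {
      gname <- names(groups)[gi]
      for (si in seq_len(n_per_group[gi])) {
        gt <- groups[[gi]]
        gt$cadence_hz <- max(0.2, stats::rnorm(1, gt$cadence_hz, cadence_sd))
        w1 <- NA_real_
        if (!is.null(gt$mode_mixture)) {
          w1 <- min(max(stats::rnorm(1, gt$mode_mixture$weight1, weight_sd),
                        0.02), 0.98)
          gt$mode_mixture$weight1 <- w1
        }
        sid <- sprintf("%s_%02d", gname, si)
        sub_seed <- sample.int(.Machine$integer.max, 1)
        sim <- simulate_subject(gt, duration_s, rate_hz, seed = sub_seed,
                                subject_id = sid, group_label = gname)
        subjects[[sid]] <- sim
        rows[[sid]] <- tibble::tibble(
          subject_id = sid, group_label = gname,
          cadence_hz = gt$cadence_hz, mode1_weight = w1,
          n_cycles = sim$truth$planted$n_cycles)
      }
    }
    list(subjects = subjects, truth_table = dplyr::bind_rows(rows))
  })
}

#' Simulate a coupled autoregressive pair with a single internal delay
#'
#' Generates the two-process structure the causal estimator assumes:
#' `y` drives `x` with gain `b_yx` at lag `l` (and optionally `x` drives `y`
#' with gain `b_xy`), each with a self term `a2` and unit-variance innovation
#' noise. The canonical ground-truth generator for lag-recovery, calibration
#' and feedback experiments.
#'
#' @param n Series length.
#' @param lag Positive integer coupling delay.
#' @param a2 Self-coefficient of each process.
#' @param b_yx Gain of `y` into `x` (`y -> x`).
#' @param b_xy Gain of `x` into `y` (`x -> y`); 0 for unidirectional.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
simulate_ar_pair <- function(n, lag = 3, a2 = 0.5, b_yx = 0.4, b_xy = 0,
                             seed = NULL) {
  lag <- as.integer(lag)
  stopifnot(n > 10 * lag, lag >= 1L)
  with_seed(seed, {
    burn <- 10L * lag + 100L
    N <- n + burn
    wx <- stats::rnorm(N); wy <- stats::rnorm(N)
    # the lag-l recursion splits into l independent stride chains, each AR(1)
    ar1_chains <- function(w, coef) {
      out <- numeric(N)
      for (s in seq_len(lag)) {
        idx <- seq.int(s, N, by = lag)
        out[idx] <- as.numeric(stats::filter(w[idx], coef, method = "recursive"))
      }
      out
    }
    if (b_xy == 0) {
      y <- ar1_chains(wy, a2)
      x <- ar1_chains(wx + b_yx * c(rep(0, lag), y[1:(N - lag)]), a2)
    } else if (b_xy == b_yx) {
      # symmetric coupling decouples in the sum/difference coordinates
      su <- ar1_chains(wx + wy, a2 + b_yx)
      di <- ar1_chains(wx - wy, a2 - b_yx)
      x <- (su + di) / 2; y <- (su - di) / 2
    } else {
      x <- numeric(N); y <- numeric(N)
      for (i in (lag + 1L):N) {
        x[i] <- a2 * x[i - lag] + b_yx * y[i - lag] + wx[i]
        y[i] <- a2 * y[i - lag] + b_xy * x[i - lag] + wy[i]
      }
    }
    tibble::tibble(x = x[(burn + 1L):N], y = y[(burn + 1L):N])
  })
}
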