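#' Sample moments for the single-delay causal model
#'
#' Computes the sample auto- and cross-moments needed by the closed-form
#' estimator at candidate lag `l`:
#' `Rxx(0)`, `Rxx(l)`, `Ryy(0)`, `Rxy(0)`, `Rxy(l)`, with
#' `R(tau) = (1/(n - tau)) * sum` over aligned samples of the lagged product
#' and the symmetric zero-lag convention `Rxy(0) = mean(x_t * y_t)`. Both
#' series are mean-centered and truncated to their common length first.
#'
#' @param x,y Numeric series (the putative effect `x` and cause `y`).
#' @param l Positive integer lag, in series-index units.
#' @return A list of class `cov_set` with fields `Rxx0`, `Rxxl`, `Ryy0`,
#'   `Rxy0`, `Rxyl`, `lag`, `n`.
#' @export
sample_moments <- function(x, y, l) {
  l <- as.integer(l)
  if (l < 1L) stop("lag must be a positive integer", call. = FALSE)
  n <- min(length(x), length(y))
  if (n <= l + 2L) stop("insufficient samples for lag", call. = FALSE)
  x <- x[seq_len(n)] - mean(x[seq_len(n)])
  y <- y[seq_len(n)] - mean(y[seq_len(n)])
  idx <- (l + 1L):n
  structure(list(
    Rxx0 = mean(x * x),
    Rxxl = sum(x[idx] * x[idx - l]) / (n - l),
    Ryy0 = mean(y * y),
    Rxy0 = mean(x * y),
    Rxyl = sum(x[idx] * y[idx - l]) / (n - l),
    lag = l, n = n
  ), class = "cov_set")
}

#' Construct a covariance set directly
#'
#' Useful for testing the closed-form estimator on hand-built moments.
#'
#' @param Rxx0,Rxxl,Ryy0,Rxy0,Rxyl Sample moments (see [sample_moments()]).
#' @param lag Candidate lag the moments were computed at.
#' @return A `cov_set` list.
#' @export
cov_set <- function(Rxx0, Rxxl, Ryy0, Rxy0, Rxyl, lag = 1L) {
  if (Rxx0 <= 0 || Ryy0 <= 0) stop("Rxx0 and Ryy0 must be positive", call. = FALSE)
  structure(list(Rxx0 = Rxx0, Rxxl = Rxxl, Ryy0 = Ryy0, Rxy0 = Rxy0,
                 Rxyl = Rxyl, lag = as.integer(lag), n = NA_integer_),
            class = "cov_set")
}

#' Granger causality at a single internal delay
#'
#' Fits the non-causal model `x_n = a1 x_(n-l) + w1` and the causal model
#' `x_n = a2 x_(n-l) + b y_(n-l) + w2` from sample moments and returns the
#' logarithmic causality `GC = log(sigma1^2 / sigma2^2)`; `GC > 0` means the
#' causal model predicts `x` better.
#'
#' Two estimator modes are provided:
#' \describe{
#'   \item{`"paper"`}{The closed-form moment equations solved verbatim:
#'     `a1 = Rxx(0)/Rxx(l)`; the 2x2 system
#'     `Rxx(0) = a2 Rxx(l) + b Rxy(l)`, `Rxx(l) = a2 Rxx(0) + b Rxy(0)`;
#'     `sigma1^2 = (1 - a1^2) Rxx(0)`;
#'     `sigma2^2 = (1 - a2^2) Rxx(0) - b^2 Ryy(0) - 2 a2 b Rxy(0)`.
#'     These equations drop noise-process cross terms that are nonzero under
#'     the generative model, so the variances can go negative on real data —
#'     the `"strict"` policy then marks the lag invalid.}
#'   \item{`"ols"`}{Standard least-squares normal equations:
#'     `[Rxx(l); Rxy(l)] = [[Rxx(0), Rxy(0)], [Rxy(0), Ryy(0)]] [a2; b]`,
#'     `a1 = Rxx(l)/Rxx(0)`, with residual variances
#'     `sigma1^2 = Rxx(0) - a1 Rxx(l)` and
#'     `sigma2^2 = Rxx(0) - a2 Rxx(l) - b Rxy(l)`.}
#' }
#'
#' @param cov A `cov_set` from [sample_moments()] or [cov_set()].
#' @param mode `"paper"` (replication default) or `"ols"`.
#' @param policy `"strict"` (GC defined only if both variances are positive)
#'   or `"permissive"` (GC defined whenever the variance ratio is positive).
#' @return A one-row tibble: `a1`, `a2`, `b`, `sigma1_sq`, `sigma2_sq`, `gc`,
#'   `valid`, `reason`.
#' @export
#' @examples
#' cs <- cov_set(Rxx0 = 2, Rxxl = 1, Ryy0 = 1, Rxy0 = 0.25, Rxyl = 0.5)
#' gc_single_lag(cs, mode = "paper", policy = "permissive")  # gc = log(3/7)
gc_single_lag <- function(cov, mode = c("paper", "ols"),
                          policy = c("strict", "permissive")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  scale <- cov$Rxx0 * max(abs(cov$Rxx0), abs(cov$Ryy0))
  out <- tibble::tibble(a1 = NA_real_, a2 = NA_real_, b = NA_real_,
                        sigma1_sq = NA_real_, sigma2_sq = NA_real_,
                        gc = NA_real_, valid = FALSE, reason = NA_character_)
  if (mode == "paper") {
    if (abs(cov$Rxxl) < 1e-12 * abs(cov$Rxx0)) {
      out$reason <- "Rxx(l) ~ 0: a1 undefined"
      return(out)
    }
    a1 <- cov$Rxx0 / cov$Rxxl
    # [Rxxl Rxyl; Rxx0 Rxy0] [a2; b] = [Rxx0; Rxxl]
    det <- cov$Rxxl * cov$Rxy0 - cov$Rxyl * cov$Rxx0
    if (abs(det) < 1e-12 * scale) {
      out$reason <- "collinear"
      return(out)
    }
    a2 <- (cov$Rxx0 * cov$Rxy0 - cov$Rxyl * cov$Rxxl) / det
    b  <- (cov$Rxxl * cov$Rxxl - cov$Rxx0 * cov$Rxx0) / det
    s1 <- (1 - a1^2) * cov$Rxx0
    s2 <- (1 - a2^2) * cov$Rxx0 - b^2 * cov$Ryy0 - 2 * a2 * b * cov$Rxy0
  } else {
    det <- cov$Rxx0 * cov$Ryy0 - cov$Rxy0^2
    if (abs(det) < 1e-12 * scale) {
      out$reason <- "collinear"
      return(out)
    }
    a1 <- cov$Rxxl / cov$Rxx0
    a2 <- (cov$Ryy0 * cov$Rxxl - cov$Rxy0 * cov$Rxyl) / det
    b  <- (cov$Rxx0 * cov$Rxyl - cov$Rxy0 * cov$Rxxl) / det
    s1 <- cov$Rxx0 - a1 * cov$Rxxl
    s2 <- cov$Rxx0 - a2 * cov$Rxxl - b * cov$Rxyl
  }
  out$a1 <- a1; out$a2 <- a2; out$b <- b
  out$sigma1_sq <- s1; out$sigma2_sq <- s2
  ok <- if (policy == "strict") s1 > 0 && s2 > 0 else s1 / s2 > 0
  if (ok) {
    out$gc <- log(s1 / s2)
    out$valid <- TRUE
  } else {
    out$reason <- "non-positive noise variance"
  }
  out
}

#' Sweep candidate internal delays and locate the optimal lag
#'
#' Evaluates [gc_single_lag()] over a lag grid. The optimal lag is the valid
#' lag with maximal GC (ties broken towards the smallest lag — the shortest
#' timing consistent with maximal information flow); the causal force is
#' `max_gc / optimal_lag`, a proxy for the speed of information transmission.
#' By default lags are in spike-index units (one lag = one inter-peak step);
#' callers working on raw sample-indexed series simply pass those series.
#'
#' @param x,y Numeric series (effect, cause): typically centered MMS values.
#' @param lags Integer lag grid; capped at `floor(n/4)`.
#' @param mode,policy See [gc_single_lag()].
#' @return A tibble of class `lag_sweep` (one row per lag) with attributes
#'   `optimal_lag`, `max_gc`, `force`, `mode`, `policy`, `no_valid`.
#' @export
lag_sweep <- function(x, y, lags = 1:50, mode = c("paper", "ols"),
                      policy = c("strict", "permissive")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  if (length(lags) == 0L) stop("empty lag range", call. = FALSE)
  n <- min(length(x), length(y))
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be positive integers", call. = FALSE)
  lags <- lags[lags <= max(1L, n %/% 4L)]
  if (length(lags) == 0L) stop("all lags exceed n/4 for these series", call. = FALSE)
  rows <- purrr::map(lags, function(l) {
    res <- tryCatch(gc_single_lag(sample_moments(x, y, l), mode, policy),
                    error = function(e) NULL)
    if (is.null(res)) {
      res <- tibble::tibble(a1 = NA_real_, a2 = NA_real_, b = NA_real_,
                            sigma1_sq = NA_real_, sigma2_sq = NA_real_,
                            gc = NA_real_, valid = FALSE,
                            reason = "insufficient samples")
    }
    dplyr::bind_cols(tibble::tibble(lag = l), res)
  })
  tab <- dplyr::bind_rows(rows)
  valid <- tab$valid & is.finite(tab$gc)
  if (any(valid)) {
    best <- which(valid)[which.max(tab$gc[valid])]  # which.max -> smallest on ties
    optimal_lag <- tab$lag[best]
    max_gc <- tab$gc[best]
    force <- if (optimal_lag > 0) max_gc / optimal_lag else NA_real_
    no_valid <- FALSE
  } else {
    optimal_lag <- NA_integer_; max_gc <- NA_real_; force <- NA_real_
    no_valid <- TRUE
  }
  structure(tab, optimal_lag = optimal_lag, max_gc = max_gc, force = force,
            mode = mode, policy = policy, no_valid = no_valid,
            class = c("lag_sweep", class(tibble::tibble())))
}

#' @export
print.lag_sweep <- function(x, ...) {
  if (isTRUE(attr(x, "no_valid"))) {
    cat("<lag_sweep> no valid lag\n")
  } else {
    cat(sprintf("<lag_sweep> optimal lag %d, max GC %.4g, force %.4g (%s/%s)\n",
                attr(x, "optimal_lag"), attr(x, "max_gc"), attr(x, "force"),
                attr(x, "mode"), attr(x, "policy")))
  }
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.lag_sweep <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.lag_sweep <- function(x, ...) {
  tibble::tibble(optimal_lag = attr(x, "optimal_lag"),
                 max_gc = attr(x, "max_gc"),
                 force = attr(x, "force"),
                 n_valid = sum(x$valid),
                 n_lags = nrow(x),
                 mode = attr(x, "mode"),
                 policy = attr(x, "policy"))
}

#' Plot a lag sweep
#' @param object A `lag_sweep`.
#' @param ... Unused.
#' @return A ggplot object marking the optimal lag.
#' @export
autoplot.lag_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[df$valid, ], ggplot2::aes(x = .data$lag, y = .data$gc)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "lag (spikes)", y = "Granger causality") +
    ggplot2::theme_minimal()
  if (!isTRUE(attr(object, "no_valid"))) {
    p <- p + ggplot2::geom_vline(xintercept = attr(object, "optimal_lag"),
                                 linetype = "dashed", colour = "red3")
  }
  p
}

# lean numeric max-GC over a lag grid (no tibbles): mirrors gc_single_lag /
# lag_sweep semantics exactly; used in surrogate loops where allocation
# overhead dominates.
max_gc_fast <- function(x, y, lags, mode = "paper", policy = "strict") {
  n <- min(length(x), length(y))
  x <- x[seq_len(n)] - mean(x[seq_len(n)])
  y <- y[seq_len(n)] - mean(y[seq_len(n)])
  lags <- lags[lags <= max(1L, n %/% 4L) & n > lags + 2L]
  Rxx0 <- mean(x * x); Ryy0 <- mean(y * y); Rxy0 <- mean(x * y)
  scale <- Rxx0 * max(abs(Rxx0), abs(Ryy0))
  best <- -Inf; best_lag <- NA_integer_
  for (l in lags) {
    idx <- (l + 1L):n
    Rxxl <- sum(x[idx] * x[idx - l]) / (n - l)
    Rxyl <- sum(x[idx] * y[idx - l]) / (n - l)
    if (mode == "paper") {
      if (abs(Rxxl) < 1e-12 * abs(Rxx0)) next
      det <- Rxxl * Rxy0 - Rxyl * Rxx0
      if (abs(det) < 1e-12 * scale) next
      a1 <- Rxx0 / Rxxl
      a2 <- (Rxx0 * Rxy0 - Rxyl * Rxxl) / det
      b <- (Rxxl * Rxxl - Rxx0 * Rxx0) / det
      s1 <- (1 - a1^2) * Rxx0
      s2 <- (1 - a2^2) * Rxx0 - b^2 * Ryy0 - 2 * a2 * b * Rxy0
    } else {
      det <- Rxx0 * Ryy0 - Rxy0^2
      if (abs(det) < 1e-12 * scale) next
      a1 <- Rxxl / Rxx0
      a2 <- (Ryy0 * Rxxl - Rxy0 * Rxyl) / det
      b <- (Rxx0 * Rxyl - Rxy0 * Rxxl) / det
      s1 <- Rxx0 - a1 * Rxxl
      s2 <- Rxx0 - a2 * Rxxl - b * Rxyl
    }
    ok <- if (policy == "strict") s1 > 0 && s2 > 0 else s1 / s2 > 0
    if (ok) {
      g <- log(s1 / s2)
      if (is.finite(g) && g > best) { best <- g; best_lag <- l }
    }
  }
  if (is.finite(best)) list(max_gc = best, optimal_lag = best_lag)
  else list(max_gc = NA_real_, optimal_lag = NA_integer_)
}

#' Surrogate-based significance of the maximal causality
#'
#' Builds a null distribution by circularly shifting the candidate cause `y`
#' by random offsets well beyond the lag grid (at least 4x the maximum lag,
#' capped by the series length, so residual autocorrelation at small shifts
#' cannot leak into the null), recomputing the maximal GC over the same lag
#' grid for each surrogate. The p-value is the standard permutation estimate
#' `(1 + #(surrogate >= observed)) / (1 + B)`.
#'
#' @param x,y Numeric series (effect, cause).
#' @param lags Lag grid used for the observed sweep and each surrogate.
#' @param mode,policy See [gc_single_lag()].
#' @param alpha Significance level (default 0.01).
#' @param n_surrogates Number of circular-shift surrogates (>= 99).
#' @param seed Integer seed for the surrogate offsets.
#' @param sweep Optional precomputed observed [lag_sweep()] to reuse.
#' @return A list: `p_value`, `significant`, `observed_gc`, `n_surrogates`.
#' @export
gc_significance <- function(x, y, lags = 1:50, mode = c("paper", "ols"),
                            policy = c("strict", "permissive"),
                            alpha = 0.01, n_surrogates = 199, seed = NULL,
                            sweep = NULL) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  if (n_surrogates < 99L) stop("need at least 99 surrogates", call. = FALSE)
  n <- min(length(x), length(y))
  maxlag <- max(lags)
  if (n < 4L * maxlag) {
    stop("series shorter than 4x the maximum lag", call. = FALSE)
  }
  if (is.null(sweep)) sweep <- lag_sweep(x, y, lags, mode, policy)
  obs <- attr(sweep, "max_gc")
  if (!is.finite(obs)) {
    return(list(p_value = 1, significant = FALSE, observed_gc = NA_real_,
                n_surrogates = n_surrogates))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  min_off <- max(maxlag, min(4L * maxlag, n %/% 3L))
  offsets <- sample(seq.int(min_off, n - min_off), n_surrogates, replace = TRUE)
  yv <- y[seq_len(n)]
  exceed <- 0L
  for (off in offsets) {
    ys <- c(yv[(off + 1L):n], yv[seq_len(off)])
    g <- max_gc_fast(x, ys, lags, mode, policy)$max_gc
    if (is.finite(g) && g >= obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_surrogates)
  list(p_value = p, significant = p <= alpha, observed_gc = obs,
       n_surrogates = n_surrogates)
}

#' Detect a feedback loop between two nodes
#'
#' Following Granger's definition, a feedback loop is present when causality
#' is detected in both directions: both sweeps carry a positive maximal GC and
#' both pass the significance test.
#'
#' @param sweep_ab,sweep_ba [lag_sweep()] results for the two directions.
#' @param sig_ab,sig_ba [gc_significance()] results for the two directions.
#' @return `TRUE` or `FALSE`.
#' @export
detect_feedback <- function(sweep_ab, sweep_ba, sig_ab, sig_ba) {
  gab <- attr(sweep_ab, "max_gc"); gba <- attr(sweep_ba, "max_gc")
  isTRUE(sig_ab$significant) && isTRUE(sig_ba$significant) &&
    is.finite(gab) && gab > 0 && is.finite(gba) && gba > 0
}

#' Assemble a directed causal network over body nodes
#'
#' Runs the lag sweep (and, optionally, surrogate significance) for every
#' ordered pair of node series and summarises the result: per-node out-degree
#' (count of significant outgoing edges), maximal outward GC and its lag, the
#' network asymmetry index, and the set of feedback pairs.
#'
#' The asymmetry index is the normalized L1 directional difference
#' `sum_{i<j} |GC(i->j) - GC(j->i)| / sum_{i<j} (GC(i->j) + GC(j->i))`
#' over pairs where both directions carry a valid positive GC; 0 for a
#' perfectly symmetric network, towards 1 for one-way flow.
#'
#' @param series Named list of numeric series (one per node), e.g. centered
#'   MMS values; names define the node set.
#' @param lags,mode,policy See [lag_sweep()].
#' @param significance If `TRUE`, run [gc_significance()] per edge; otherwise
#'   every valid positive-GC edge is treated as significant (useful for quick
#'   exploration).
#' @param alpha,n_surrogates,seed Passed to [gc_significance()].
#' @return A list of class `causal_network`: `nodes` (tibble: `node`,
#'   `out_degree`, `max_outward_gc`, `max_outward_lag`), `edges` (tibble:
#'   `source`, `target`, `max_gc`, `optimal_lag`, `force`, `p_value`,
#'   `significant`), `asymmetry_index`, `feedback_pairs` (tibble: `node_a`,
#'   `node_b`).
#' @export
build_network <- function(series, lags = 1:50, mode = c("paper", "ols"),
                          policy = c("strict", "permissive"),
                          significance = TRUE, alpha = 0.01,
                          n_surrogates = 199, seed = NULL) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  nodes <- names(series)
  if (is.null(nodes) || any(!nzchar(nodes)) || anyDuplicated(nodes)) {
    stop("`series` must be a named list with unique node names", call. = FALSE)
  }
  if (length(nodes) < 2L) stop("need at least 2 nodes", call. = FALSE)
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edge_rows <- purrr::pmap(pairs, function(source, target) {
    # edge source -> target: source is the cause (y), target the effect (x)
    sw <- lag_sweep(series[[target]], series[[source]], lags, mode, policy)
    if (significance) {
      edge_seed <- if (is.null(seed)) NULL else
        seed + 7L * match(source, nodes) + 131L * match(target, nodes)
      sig <- gc_significance(series[[target]], series[[source]], lags, mode,
                             policy, alpha, n_surrogates, seed = edge_seed,
                             sweep = sw)
      p <- sig$p_value; signif <- sig$significant
    } else {
      g <- attr(sw, "max_gc")
      p <- NA_real_; signif <- is.finite(g) && g > 0
    }
    tibble::tibble(source = source, target = target,
                   max_gc = attr(sw, "max_gc"),
                   optimal_lag = attr(sw, "optimal_lag"),
                   force = attr(sw, "force"),
                   p_value = p, significant = signif)
  })
  edges <- dplyr::bind_rows(edge_rows)
  node_tab <- edges |>
    dplyr::group_by(source) |>
    dplyr::summarise(
      out_degree = sum(.data$significant, na.rm = TRUE),
      max_outward_gc = if (any(is.finite(.data$max_gc)))
        max(.data$max_gc, na.rm = TRUE) else NA_real_,
      max_outward_lag = if (any(is.finite(.data$optimal_lag)))
        max(.data$optimal_lag, na.rm = TRUE) else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::rename(node = "source") |>
    dplyr::arrange(match(.data$node, nodes))
  # asymmetry over unordered pairs with both directions valid and positive
  num <- 0; den <- 0
  fb <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      a <- nodes[i]; b <- nodes[j]
      eab <- edges[edges$source == a & edges$target == b, ]
      eba <- edges[edges$source == b & edges$target == a, ]
      gab <- eab$max_gc; gba <- eba$max_gc
      if (is.finite(gab) && is.finite(gba) && gab > 0 && gba > 0) {
        num <- num + abs(gab - gba)
        den <- den + (gab + gba)
      }
      if (isTRUE(eab$significant) && isTRUE(eba$significant) &&
          is.finite(gab) && gab > 0 && is.finite(gba) && gba > 0) {
        fb[[length(fb) + 1L]] <- tibble::tibble(node_a = a, node_b = b)
      }
    }
  }
  feedback_pairs <- if (length(fb)) dplyr::bind_rows(fb) else
    tibble::tibble(node_a = character(), node_b = character())
  structure(list(nodes = node_tab, edges = edges,
                 asymmetry_index = if (den > 0) num / den else NA_real_,
                 feedback_pairs = feedback_pairs),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d nodes, %d significant / %d edges, asymmetry %.3f, %d feedback pair(s)\n",
              nrow(x$nodes), sum(x$edges$significant, na.rm = TRUE),
              nrow(x$edges), x$asymmetry_index, nrow(x$feedback_pairs)))
  invisible(x)
}

#' @export
tidy.causal_network <- function(x, ...) x$edges

#' @export
glance.causal_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes),
                 n_edges = nrow(x$edges),
                 n_significant = sum(x$edges$significant, na.rm = TRUE),
                 asymmetry_index = x$asymmetry_index,
                 n_feedback_pairs = nrow(x$feedback_pairs))
}

#' Plot a causal network as node-and-arrow diagram
#' @param object A `causal_network`.
#' @param ... Unused.
#' @return A ggplot object; node size encodes out-degree, edge colour the GC.
#' @export
autoplot.causal_network <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  pos <- tibble::tibble(node = nodes$node, px = cos(theta), py = sin(theta))
  ed <- dplyr::filter(object$edges, .data$significant) |>
    dplyr::left_join(pos, by = c(source = "node")) |>
    dplyr::rename(x0 = "px", y0 = "py") |>
    dplyr::left_join(pos, by = c(target = "node")) |>
    dplyr::rename(x1 = "px", y1 = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data$max_gc),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in")),
      alpha = 0.8) +
    ggplot2::geom_point(
      data = dplyr::left_join(nodes, pos, by = "node"),
      ggplot2::aes(x = .data$px, y = .data$py, size = .data$out_degree)) +
    ggplot2::geom_text(
      data = dplyr::left_join(nodes, pos, by = "node"),
      ggplot2::aes(x = 1.15 * .data$px, y = 1.15 * .data$py, label = .data$node),
      size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(colour = "max GC", size = "out-degree")
}

#' Export a causal network to GraphML
#'
#' @param network A `causal_network`.
#' @param path Output `.graphml` path.
#' @param significant_only Keep only significant edges.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path, significant_only = TRUE) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  ed <- network$edges
  if (significant_only) ed <- ed[ed$significant %in% TRUE, ]
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Group-level feedback percentage map
#'
#' For a set of per-subject networks sharing a node set, computes for every
#' unordered node pair the percentage of subjects in whom a feedback loop was
#' detected.
#'
#' @param networks List of `causal_network` objects.
#' @return A tibble: `node_a`, `node_b`, `pct_subjects` (0-100).
#' @export
group_feedback_map <- function(networks) {
  if (length(networks) == 0L) stop("empty group", call. = FALSE)
  node_sets <- purrr::map(networks, function(nw) sort(nw$nodes$node))
  if (length(unique(node_sets)) != 1L) {
    stop("networks do not share a node set", call. = FALSE)
  }
  nodes <- sort(networks[[1]]$nodes$node)
  pairs <- tidyr::expand_grid(node_a = nodes, node_b = nodes) |>
    dplyr::filter(.data$node_a < .data$node_b)
  counts <- purrr::reduce(networks, .init = rep(0, nrow(pairs)), function(acc, nw) {
    fb <- nw$feedback_pairs
    key <- paste(pmin(fb$node_a, fb$node_b), pmax(fb$node_a, fb$node_b))
    acc + as.numeric(paste(pairs$node_a, pairs$node_b) %in% key)
  })
  pairs$pct_subjects <- 100 * counts / length(networks)
  pairs
}
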