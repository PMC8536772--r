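#' Stride proxy: speed over frequency
#'
#' Mean center-of-mass speed divided by the mean frequency of the (demeaned)
#' speed spectrum. Speed is m/s, frequency 1/s, so the ratio is in meters:
#' distance travelled per stride, since the spectral mean frequency of a
#' quasi-periodic speed series tracks the cadence.
#'
#' @param speed Numeric center-of-mass speed series (m/s).
#' @param rate_hz Sampling rate in Hz.
#' @param window_s Spectral window (see [welch_psd()]).
#' @return A one-row tibble: `mean_speed_ms`, `mean_frequency_hz`,
#'   `speed_over_frequency_m`.
#' @export
stride_proxy <- function(speed, rate_hz, window_s = 4) {
  if (length(speed) == 0L) stop("empty speed series", call. = FALSE)
  psd <- welch_psd(speed, rate_hz, window_s = window_s)
  fmean <- mean_frequency(psd$frequency_hz, psd$power)
  if (fmean <= 0) stop("zero mean frequency", call. = FALSE)
  tibble::tibble(mean_speed_ms = mean(speed),
                 mean_frequency_hz = fmean,
                 speed_over_frequency_m = mean(speed) / fmean)
}

#' Normalize cohort features
#'
#' Min-max to \[0, 1\] (default) or z-score, per numeric feature column.
#' Constant features are set to 0 and flagged in the `constant_features`
#' attribute instead of being divided by zero.
#'
#' @param features Cohort tibble, one row per subject; non-numeric columns
#'   (ids, labels) pass through untouched.
#' @param method `"minmax"` or `"zscore"`.
#' @return The normalized tibble, with attribute `constant_features`.
#' @export
normalize_features <- function(features, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (nrow(features) < 2L) stop("need at least 2 subjects", call. = FALSE)
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  constant <- character(0)
  out <- features
  for (cl in num_cols) {
    v <- out[[cl]]
    ok <- is.finite(v)
    rng <- range(v[ok])
    if (!any(ok) || diff(rng) == 0) {
      constant <- c(constant, cl)
      out[[cl]] <- ifelse(ok, 0, v)
      next
    }
    out[[cl]] <- if (method == "minmax") {
      (v - rng[1]) / diff(rng)
    } else {
      (v - mean(v[ok])) / stats::sd(v[ok])
    }
  }
  if (length(constant)) {
    warning("constant feature(s) set to 0: ", paste(constant, collapse = ", "),
            call. = FALSE)
  }
  attr(out, "constant_features") <- constant
  out
}

#' Cluster subjects in a feature space
#'
#' Euclidean k-means (best of `n_init` seeded restarts) on the numeric
#' columns, with the mean silhouette width reported. Deterministic under a
#' fixed seed.
#'
#' @param features Tibble, one row per subject.
#' @param k Number of clusters (user-specified per group).
#' @param seed Integer seed.
#' @param n_init Number of random restarts.
#' @param columns Feature columns to use; defaults to all numeric columns.
#' @return A list of class `subject_clusters`: `assignments` (tibble with the
#'   input plus `.cluster`), `centroids`, `inertia`, `silhouette`, `k`.
#' @export
cluster_subjects <- function(features, k, seed = 1, n_init = 25,
                             columns = NULL) {
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  mat <- as.matrix(features[columns])
  if (any(!is.finite(mat))) stop("features contain non-finite values", call. = FALSE)
  if (k > nrow(mat)) stop("k exceeds the number of subjects", call. = FALSE)
  if (k == nrow(mat)) {
    # one point per cluster: trivial partition (kmeans requires k < n)
    out <- features
    out$.cluster <- factor(seq_len(nrow(mat)))
    return(structure(list(assignments = tibble::as_tibble(out),
                          centroids = tibble::as_tibble(as.data.frame(mat)),
                          inertia = 0, silhouette = NA_real_, k = k),
                     class = "subject_clusters"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = n_init, iter.max = 100)
  sil <- if (k >= 2L && nrow(mat) > k) {
    mean(cluster::silhouette(km$cluster, stats::dist(mat))[, "sil_width"])
  } else NA_real_
  out <- features
  out$.cluster <- factor(km$cluster)
  structure(list(assignments = tibble::as_tibble(out),
                 centroids = tibble::as_tibble(km$centers),
                 inertia = km$tot.withinss, silhouette = sil, k = k),
            class = "subject_clusters")
}

#' @export
print.subject_clusters <- function(x, ...) {
  cat(sprintf("<subject_clusters> k = %d, inertia %.4g, mean silhouette %.3f\n",
              x$k, x$inertia, x$silhouette))
  invisible(x)
}

#' @export
tidy.subject_clusters <- function(x, ...) x$assignments

#' @export
glance.subject_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, silhouette = x$silhouette,
                 n = nrow(x$assignments))
}

#' Silhouette scan to suggest k
#'
#' Runs [cluster_subjects()] over a k grid and reports mean silhouette per k.
#' A helper for choosing k; it never overrides an explicit choice.
#'
#' @param features Tibble, one row per subject.
#' @param k_range Candidate k values (>= 2).
#' @param seed,n_init,columns See [cluster_subjects()].
#' @return Tibble: `k`, `silhouette`, `inertia`.
#' @export
silhouette_scan <- function(features, k_range = 2:5, seed = 1, n_init = 25,
                            columns = NULL) {
  purrr::map_dfr(k_range[k_range >= 2 & k_range < nrow(features)], function(k) {
    cl <- cluster_subjects(features, k, seed = seed, n_init = n_init,
                           columns = columns)
    tibble::tibble(k = k, silhouette = cl$silhouette, inertia = cl$inertia)
  })
}

#' Per-node group-difference map of mean inter-peak timings
#'
#' Welch two-sample t-test per node between two groups of per-subject node
#' timing means; entries are `mean(groupA) - mean(groupB)` where the test is
#' significant at `alpha` and 0 otherwise (the zero marks "no significant
#' difference"). No multiple-testing correction is applied by default,
#' mirroring per-node maps at a fixed alpha; Benjamini-Hochberg is available.
#'
#' @param group_a,group_b Tibbles (or matrices), one row per subject, one
#'   numeric column per node.
#' @param alpha Per-node significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `node`, `difference` (0 when non-significant), `p_value`.
#' @export
group_difference_map <- function(group_a, group_b, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  a <- tibble::as_tibble(group_a); b <- tibble::as_tibble(group_b)
  nodes <- intersect(names(a), names(b))
  nodes <- nodes[vapply(a[nodes], is.numeric, logical(1))]
  if (length(nodes) == 0L) stop("no shared numeric node columns", call. = FALSE)
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  res <- purrr::map_dfr(nodes, function(nd) {
    tt <- stats::t.test(a[[nd]], b[[nd]], var.equal = FALSE)
    tibble::tibble(node = nd,
                   raw_difference = mean(a[[nd]]) - mean(b[[nd]]),
                   p_value = tt$p.value)
  })
  padj <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$difference <- ifelse(padj < alpha, res$raw_difference, 0)
  res[, c("node", "difference", "p_value")]
}

#' Per-group centroids in a feature space
#'
#' @param features Tibble, one row per subject.
#' @param group Column name holding the group label (default
#'   `"group_label"`).
#' @param columns Feature columns; defaults to all numeric columns.
#' @return Tibble: one row per group with the per-feature means.
#' @export
centroid_summary <- function(features, group = "group_label", columns = NULL) {
  if (!group %in% names(features)) stop("missing group column: ", group,
                                        call. = FALSE)
  if (is.null(columns)) {
    columns <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       group)
  }
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(columns),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}
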