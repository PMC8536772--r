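#' Default pipeline configuration
#'
#' Central defaults for the end-to-end analysis: node groups, lag range,
#' estimator mode and validity policy, significance settings, spectral
#' window, and clustering k. All values can be overridden by name.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    signature_node = "pelvis",
    pelvic_nodes = "pelvis",
    feet = c("foot_left", "foot_right"),
    com_channel = "com_speed",
    lags = 1:10,
    mode = "ols",
    policy = "strict",
    significance = FALSE,
    alpha = 0.01,
    n_surrogates = 199,
    window_s = 4,
    k_per_group = 2,
    dip_n_boot = 500,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Extract MMS series for every node of a recording
#'
#' @param recording A [kin_recording()].
#' @param nodes Channels to process (default: all except the COM channel).
#' @param config A [pipeline_config()].
#' @param center Gamma-center each series.
#' @return Named list of `mms_series`.
#' @export
recording_mms <- function(recording, nodes = NULL, config = pipeline_config(),
                          center = TRUE) {
  if (is.null(nodes)) {
    nodes <- setdiff(names(recording), c("time_s", config$com_channel))
  }
  rt <- rate_hz(recording)
  out <- lapply(nodes, function(nd) {
    mms_extract(recording[[nd]], rt, center = center,
                source_unit = attr(recording, "unit"))
  })
  names(out) <- nodes
  out
}

#' Per-subject feature vector
#'
#' Assembles the stratification features from one recording: the exponential-
#' mode percentage, dip statistic and stride proxy (the cluster triplet); the
#' pelvic-area NSR and mean skewness with the network asymmetry index (the
#' departure-from-normative triplet); feet causal forces in both directions
#' with the mean inter-peak timing and feet NSR (the causal force space); and
#' the per-node mean inter-peak intervals (nested in `node_timings`).
#'
#' @param recording A [kin_recording()] containing the configured node
#'   channels and COM speed channel.
#' @param config A [pipeline_config()].
#' @return A one-row tibble; per-node mean timings are in the list-column
#'   `node_timings`.
#' @export
subject_features <- function(recording, config = pipeline_config()) {
  rt <- rate_hz(recording)
  mms <- recording_mms(recording, config = config, center = TRUE)
  nodes <- names(mms)
  sig_node <- config$signature_node
  if (!sig_node %in% nodes) sig_node <- nodes[1]
  sig_vals <- mms[[sig_node]]$value
  md <- if (length(sig_vals) >= 50) mode_decompose(sig_vals, seed = config$seed) else NULL
  dip <- if (length(sig_vals) >= 4) dip_statistic(sig_vals) else NA_real_
  stride <- if (config$com_channel %in% names(recording)) {
    stride_proxy(recording[[config$com_channel]], rt, config$window_s)
  } else {
    tibble::tibble(mean_speed_ms = NA_real_, mean_frequency_hz = NA_real_,
                   speed_over_frequency_m = NA_real_)
  }
  pelvic <- intersect(config$pelvic_nodes, nodes)
  pelvic_sig <- purrr::map_dfr(pelvic, function(nd) {
    v <- mms[[nd]]$value
    if (length(v) >= 20) gamma_signature(v) else
      tibble::tibble(gamma_shape = NA, gamma_scale = NA, nsr = NA,
                     skewness = NA, n = length(v))
  })
  centered <- lapply(mms, function(m) m$value_centered)
  nw <- build_network(centered, lags = config$lags, mode = config$mode,
                      policy = config$policy, significance = FALSE)
  feet <- intersect(config$feet, nodes)
  force_lr <- force_rl <- nsr_feet <- NA_real_
  if (length(feet) == 2L) {
    sw_lr <- lag_sweep(centered[[feet[2]]], centered[[feet[1]]],
                       config$lags, config$mode, config$policy)
    sw_rl <- lag_sweep(centered[[feet[1]]], centered[[feet[2]]],
                       config$lags, config$mode, config$policy)
    force_lr <- attr(sw_lr, "force")
    force_rl <- attr(sw_rl, "force")
    nsr_feet <- mean(vapply(feet, function(nd) attr(mms[[nd]], "gamma_scale"),
                            numeric(1)))
  }
  timings <- vapply(mms, function(m) {
    if (nrow(m) >= 2) mean(diff(m$peak_time_s)) else NA_real_
  }, numeric(1))
  tibble::tibble(
    subject_id = attr(recording, "subject_id"),
    group_label = attr(recording, "group_label"),
    mode1_pct = if (is.null(md)) NA_real_ else 100 * md$mode1_fraction,
    dip = dip,
    speed_over_frequency_m = stride$speed_over_frequency_m,
    mean_speed_ms = stride$mean_speed_ms,
    mean_frequency_hz = stride$mean_frequency_hz,
    pelvic_nsr = mean(pelvic_sig$nsr),
    mean_skewness = mean(pelvic_sig$skewness),
    asymmetry_index = nw$asymmetry_index,
    mean_force_LR = force_lr,
    mean_force_RL = force_rl,
    nsr = nsr_feet,
    mean_timing_s = mean(timings, na.rm = TRUE),
    node_timings = list(tibble::tibble(node = names(timings),
                                       mean_interval_s = unname(timings)))
  )
}

#' Cohort feature table
#'
#' @param cohort Result of [simulate_cohort()], or a list of recordings.
#' @param config A [pipeline_config()].
#' @return Tibble, one row per subject (see [subject_features()]).
#' @export
cohort_features <- function(cohort, config = pipeline_config()) {
  recs <- if (!is.null(cohort$subjects)) {
    lapply(cohort$subjects, `[[`, "recording")
  } else cohort
  purrr::map_dfr(recs, subject_features, config = config)
}

#' Spread per-node timings into a wide matrix for group maps
#'
#' @param features Output of [cohort_features()].
#' @return Tibble: `subject_id`, `group_label`, one column per node.
#' @export
node_timing_table <- function(features) {
  features |>
    dplyr::select("subject_id", "group_label", "node_timings") |>
    tidyr::unnest("node_timings") |>
    tidyr::pivot_wider(names_from = "node", values_from = "mean_interval_s")
}

#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Chains feature extraction, normalization, per-group clustering and group
#' centroid summaries; the building block behind the command-line `all`
#' subcommand.
#'
#' @param cohort See [cohort_features()].
#' @param config A [pipeline_config()].
#' @return A list: `features`, `normalized`, `clusters` (per group),
#'   `centroids`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  feats <- cohort_features(cohort, config)
  axis_cols <- c("mode1_pct", "dip", "speed_over_frequency_m", "pelvic_nsr",
                 "asymmetry_index", "mean_force_LR", "mean_force_RL", "nsr",
                 "mean_timing_s")
  axis_cols <- axis_cols[vapply(axis_cols, function(cl)
    any(is.finite(feats[[cl]])), logical(1))]
  normalized <- suppressWarnings(
    normalize_features(feats[c("subject_id", "group_label", axis_cols)]))
  clusters <- lapply(split(feats, feats$group_label), function(g) {
    cluster_subjects(g, k = min(config$k_per_group, nrow(g)),
                     seed = config$seed,
                     columns = intersect(axis_cols, names(g)))
  })
  centroids <- centroid_summary(feats, group = "group_label",
                                columns = axis_cols)
  list(features = feats, normalized = normalized, clusters = clusters,
       centroids = centroids, config = config)
}

#' Write pipeline outputs and a run manifest
#'
#' Writes the cohort feature table, normalized features, centroids and
#' cluster assignments as CSV under `out_dir`, plus a `manifest.json`
#' recording every config value so runs are self-describing. Numeric CSV
#' output is formatted deterministically.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 12)))
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  wr(dplyr::select(result$features, -"node_timings"), "features.csv")
  wr(result$normalized, "features_normalized.csv")
  wr(result$centroids, "centroids.csv")
  wr(node_timing_table(result$features), "node_timings.csv")
  assignments <- purrr::imap_dfr(result$clusters, function(cl, g) {
    dplyr::select(cl$assignments, "subject_id", "group_label", ".cluster")
  })
  wr(assignments, "cluster_assignments.csv")
  cfg <- unclass(result$config)
  jsonlite::write_json(
    list(config = cfg, package_version = as.character(utils::packageVersion("gaitmms")),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
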