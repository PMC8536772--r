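#' Construct a kinematic recording
#'
#' A kinematic recording is a tibble with a `time_s` column and one column per
#' body-node channel, uniformly sampled at `rate_hz`. Three-dimensional
#' channels use the `node.x` / `node.y` / `node.z` suffix convention. Rows
#' containing non-finite values are dropped (and counted) so that every
#' retained sample is usable downstream.
#'
#' @param data A data frame of channel columns (a `time_s` column is added or
#'   rebuilt from `rate_hz`).
#' @param rate_hz Positive sampling rate in Hz.
#' @param unit Physical unit of the channels, one of `"rad/s"`, `"m/s"`,
#'   `"m/s^2"`, `"m"`, or `"unitless"`.
#' @param subject_id,group_label Optional text metadata carried through the
#'   pipeline.
#'
#' @return A tibble of class `kin_recording` with attributes `rate_hz`,
#'   `unit`, `subject_id`, `group_label` and `dropped_rows`.
#' @export
#' @examples
#' rec <- kin_recording(
#'   data.frame(pelvis = abs(sin(1:200 / 10)), thorax = abs(cos(1:200 / 10))),
#'   rate_hz = 100, unit = "rad/s"
#' )
#' node_names(rec)
kin_recording <- function(data, rate_hz, unit = "unitless",
                          subject_id = NA_character_,
                          group_label = NA_character_) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  unit <- match.arg(unit, c("rad/s", "m/s", "m/s^2", "m", "unitless"))
  data <- tibble::as_tibble(data)
  data$time_s <- NULL
  if (ncol(data) == 0L) stop("recording has no channel columns", call. = FALSE)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all channel columns must be numeric", call. = FALSE)
  }
  keep <- stats::complete.cases(data) &
    apply(is.finite(as.matrix(data)), 1L, all)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    warning(sprintf("dropped %d row(s) with non-finite values", dropped),
            call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 2L) {
    stop("recording needs at least 2 finite samples", call. = FALSE)
  }
  data <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(nrow(data)) - 1) / rate_hz),
    data
  )
  structure(
    data,
    rate_hz = rate_hz,
    unit = unit,
    subject_id = subject_id,
    group_label = group_label,
    dropped_rows = dropped,
    class = c("kin_recording", class(tibble::tibble()))
  )
}

#' @export
print.kin_recording <- function(x, ...) {
  cat(sprintf(
    "<kin_recording> %d samples x %d channels @ %g Hz [%s]%s\n",
    nrow(x), ncol(x) - 1L, attr(x, "rate_hz"), attr(x, "unit"),
    if (!is.na(attr(x, "subject_id"))) paste0(" subject ", attr(x, "subject_id")) else ""
  ))
  NextMethod()
}

#' Node (channel) names of a recording
#'
#' For 3-D channels the `.x/.y/.z` suffixes are stripped, so each node is
#' reported once.
#'
#' @param recording A [kin_recording()].
#' @return Character vector of node names.
#' @export
node_names <- function(recording) {
  cols <- setdiff(names(recording), "time_s")
  unique(sub("\\.[xyz]$", "", cols))
}

#' Sampling rate of a recording
#' @param recording A [kin_recording()].
#' @return Sampling rate in Hz.
#' @export
rate_hz <- function(recording) attr(recording, "rate_hz")

#' Read a kinematic recording from a delimited text file
#'
#' Expects a wide CSV/TSV table whose header row names the node channels. The
#' sampling rate is taken from the `rate_hz` argument or, if `NULL`, from a
#' `# rate_hz=<value>` comment line in the file. Rows with non-finite entries
#' are dropped with a warning stating the count.
#'
#' @param path Path to a delimited text file.
#' @param rate_hz Sampling rate in Hz; overrides any rate comment in the file.
#' @param unit Physical unit of the channels (see [kin_recording()]).
#' @param delim Field delimiter; guessed from the file extension by default.
#' @param subject_id,group_label Optional metadata.
#' @return A [kin_recording()].
#' @export
read_recording <- function(path, rate_hz = NULL, unit = "unitless",
                           delim = NULL,
                           subject_id = NA_character_,
                           group_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  header <- readLines(path, n = 20L)
  rate_line <- grep("^#\\s*rate_hz\\s*=", header, value = TRUE)
  if (is.null(rate_hz)) {
    if (length(rate_line) == 0L) {
      stop("sampling rate unspecified: pass `rate_hz` or add a `# rate_hz=` line",
           call. = FALSE)
    }
    rate_hz <- as.numeric(sub("^#\\s*rate_hz\\s*=\\s*", "", rate_line[1]))
    if (!is.finite(rate_hz)) stop("sampling rate unspecified", call. = FALSE)
  }
  tab <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L) stop("file contains a header but no samples", call. = FALSE)
  kin_recording(tab, rate_hz = rate_hz, unit = unit,
                subject_id = subject_id, group_label = group_label)
}

#' Write a recording (or derived series table) as CSV with a rate comment
#'
#' @param recording A [kin_recording()] or plain data frame.
#' @param path Output path.
#' @param rate Sampling rate written into the `# rate_hz=` comment; taken from
#'   the recording attribute when available.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, rate = attr(recording, "rate_hz")) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(rate)) writeLines(sprintf("# rate_hz=%.10g", rate), con)
  df <- as.data.frame(recording)
  df$time_s <- NULL
  writeLines(paste(names(df), collapse = ","), con)
  lines <- do.call(paste, c(lapply(df, function(col) sprintf("%.10g", col)),
                            sep = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Length-weighted center-of-mass speed
#'
#' Combines per-node scalar speed series into a single center-of-mass speed by
#' a length-weighted average, `V_com = sum(V_i * L_i) / sum(L_i)` — the
#' center-of-mass formula with segment lengths standing in for masses. When
#' `lengths` is `NULL` all nodes get equal weight (a plain mean) and a warning
#' is emitted, since the result then ignores anatomy.
#'
#' @param speeds A [kin_recording()] or data frame of per-node scalar speed
#'   columns (a `time_s` column, if present, is ignored).
#' @param lengths Named numeric vector of positive segment lengths in meters
#'   (names must match the node set exactly), or `NULL` for equal weights.
#' @param nodes Optional subset of nodes to combine (e.g. a lower-body group).
#' @return A tibble with columns `time_s` (when available) and `com_speed`.
#' @export
com_velocity <- function(speeds, lengths = NULL, nodes = NULL) {
  df <- tibble::as_tibble(speeds)
  time_s <- df[["time_s"]]
  df$time_s <- NULL
  if (!is.null(nodes)) {
    missing_nodes <- setdiff(nodes, names(df))
    if (length(missing_nodes) > 0L) {
      stop("nodes not present in recording: ",
           paste(missing_nodes, collapse = ", "), call. = FALSE)
    }
    df <- df[nodes]
  }
  if (is.null(lengths)) {
    warning("no segment lengths supplied; using equal weights (plain mean)",
            call. = FALSE)
    lengths <- stats::setNames(rep(1, ncol(df)), names(df))
  }
  if (!setequal(names(lengths), names(df))) {
    stop("node sets of speeds and lengths do not match", call. = FALSE)
  }
  lengths <- lengths[names(df)]
  if (any(!is.finite(lengths)) || any(lengths < 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  total <- sum(lengths)
  if (total <= 0) stop("total segment length is zero", call. = FALSE)
  com <- as.numeric(as.matrix(df) %*% (lengths / total))
  out <- tibble::tibble(com_speed = com)
  if (!is.null(time_s)) out <- dplyr::bind_cols(tibble::tibble(time_s = time_s), out)
  out
}

#' Euclidean norm of 3-D channels
#'
#' Collapses each `node.x/.y/.z` triple into a scalar series
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param recording A [kin_recording()] (or data frame) holding `.x/.y/.z`
#'   columns for one or more nodes.
#' @param nodes Nodes to collapse; defaults to every node with a full triple.
#' @return A tibble with `time_s` (when available) and one scalar column per
#'   node.
#' @export
euclidean_norm_series <- function(recording, nodes = NULL) {
  df <- tibble::as_tibble(recording)
  time_s <- df[["time_s"]]
  cols <- setdiff(names(df), "time_s")
  base <- unique(sub("\\.[xyz]$", "", cols[grepl("\\.[xyz]$", cols)]))
  if (is.null(nodes)) nodes <- base
  out <- purrr::map(nodes, function(nd) {
    triple <- paste0(nd, c(".x", ".y", ".z"))
    if (!all(triple %in% cols)) {
      stop(sprintf("node '%s' does not have 3-component .x/.y/.z channels", nd),
           call. = FALSE)
    }
    sqrt(df[[triple[1]]]^2 + df[[triple[2]]]^2 + df[[triple[3]]]^2)
  })
  names(out) <- nodes
  out <- tibble::as_tibble(out)
  if (!is.null(time_s)) out <- dplyr::bind_cols(tibble::tibble(time_s = time_s), out)
  out
}
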