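#' Subject time-course panel
#'
#' The central input container: one time-by-channel matrix per subject plus
#' a channel table (channel label and network membership) and a subject
#' manifest (group, age, gender, education, mean framewise displacement and
#' any clinical scores). All subjects must share the channel set and order.
#'
#' @param series Named list of numeric matrices (rows = time points,
#'   columns = channels), one per subject; names are subject ids.
#' @param channels Tibble with columns `channel` and `network`.
#' @param manifest Tibble with one row per subject; must contain
#'   `subject_id` and `group`, typically also `age`, `gender`, `education`,
#'   `mean_fd`.
#' @param tr Sampling interval in seconds (repetition time).
#' @param node_series Optional named list of parallel node-level time
#'   courses (e.g. atlas regions) used by the multilayer stage.
#' @param node_networks Optional character vector assigning each node
#'   column to a network, for network-level switching summaries.
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(series, channels, manifest, tr = 2,
                     node_series = NULL, node_networks = NULL) {
  if (!is.list(series) || length(series) == 0L || is.null(names(series))) {
    abort("`series` must be a non-empty named list of matrices")
  }
  channels <- as_tibble(channels)
  manifest <- as_tibble(manifest)
  stopifnot(all(c("channel", "network") %in% names(channels)),
            all(c("subject_id", "group") %in% names(manifest)))
  if (anyDuplicated(manifest$subject_id)) abort("subject ids must be unique")
  if (!setequal(names(series), manifest$subject_id)) {
    abort("`series` names must match manifest subject ids")
  }
  series <- series[manifest$subject_id]
  nc <- vapply(series, ncol, integer(1))
  if (length(unique(nc)) != 1L || unique(nc) != nrow(channels)) {
    bad <- names(series)[nc != nrow(channels)]
    abort(sprintf(
      "channel count mismatch: manifest declares %d channels but subject(s) %s have %s",
      nrow(channels), paste(bad, collapse = ", "),
      paste(unique(nc[nc != nrow(channels)]), collapse = ", ")))
  }
  for (id in names(series)) {
    x <- series[[id]]
    if (nrow(x) < 2L) abort(sprintf("subject %s has fewer than 2 time points", id))
    if (anyNA(x) || any(!is.finite(x))) {
      abort(sprintf("subject %s has missing or non-finite values", id))
    }
  }
  structure(list(series = series, channels = channels, manifest = manifest,
                 tr = tr, node_series = node_series,
                 node_networks = node_networks),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  dims <- vapply(x$series, nrow, integer(1))
  cat(sprintf("<ts_panel> %d subjects, %d channels, T = %s, TR = %gs\n",
              length(x$series), nrow(x$channels),
              paste(unique(range(dims)), collapse = "-"), x$tr))
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}

#' Number of subjects and grouping summary of a panel
#'
#' @param x A `ts_panel`.
#' @param ... Unused.
#' @return One-row tibble with subject, channel and time-point counts.
#' @method glance ts_panel
#' @export
glance.ts_panel <- function(x, ...) {
  tibble(n_subjects = length(x$series),
         n_channels = nrow(x$channels),
         n_timepoints = nrow(x$series[[1]]),
         tr_seconds = x$tr,
         n_groups = dplyr::n_distinct(x$manifest$group))
}
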