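#' Pearson correlation matrix of a multichannel time series
#'
#' Computes the channel-by-channel Pearson correlation matrix of a
#' time-by-channel numeric matrix, the static functional network
#' connectivity (before the Fisher z transform).
#'
#' @param ts Numeric matrix, rows = time points, columns = channels
#'   (independent-component or node time courses).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || anyNA(ts) || any(!is.finite(ts))) {
    abort("time series must be a finite numeric matrix with no missing values")
  }
  if (nrow(ts) < 3L) abort("need at least 3 time points for a correlation matrix")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(ts)[bad] %||% as.character(bad)
    abort(sprintf("constant channel(s) with zero variance: %s",
                  paste(nm, collapse = ", ")))
  }
  r <- stats::cor(ts)
  (r + t(r)) / 2
}

#' Fisher z transform of correlation coefficients
#'
#' `z = atanh(r)`, with `|r| >= 1 - eps` clipped to `1 - eps` so the
#' transform stays finite for degenerate (perfectly correlated) pairs.
#'
#' @param r Numeric vector or matrix of correlations, `|r| <= 1`.
#' @param eps Clipping margin away from `+-1` (default `1e-7`).
#' @return Object of the same shape in Fisher-z units.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(!is.finite(r))) abort("non-finite correlation passed to fisher_z()")
  if (any(abs(r) > 1 + 1e-12)) abort("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  atanh(r)
}

#' Static functional network connectivity for a cohort
#'
#' One Fisher-z connectivity matrix per subject: Pearson correlations
#' between all channel pairs of the subject's time courses, z-transformed.
#' The diagonal is stored as zero; downstream feature extraction uses the
#' strict lower triangle only.
#'
#' @param panel A [ts_panel] of subject time courses.
#' @param detrend Remove a per-channel linear trend before correlating
#'   (default `FALSE`).
#' @return An object of class `sfnc_result`: list with `z` (named list of
#'   symmetric zero-diagonal z-matrices) and `channels`.
#' @seealso [tidy.sfnc_result()] for the long pair table.
#' @export
sfnc <- function(panel, detrend = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  z <- map(panel$series, function(x) {
    if (detrend) x <- detrend_columns(x)
    zm <- fisher_z(pearson_matrix(x))
    diag(zm) <- 0
    zm
  })
  structure(list(z = z, channels = panel$channels), class = "sfnc_result")
}

detrend_columns <- function(x) {
  t_idx <- seq_len(nrow(x))
  apply(x, 2, function(col) stats::residuals(stats::lm.fit(cbind(1, t_idx), col)))
}

#' Long pair table of static connectivity
#'
#' @param x An `sfnc_result`.
#' @param ... Unused.
#' @return Tibble with one row per (subject, channel pair): columns
#'   `subject_id`, `channel_i`, `channel_j`, `z`.
#' @method tidy sfnc_result
#' @export
tidy.sfnc_result <- function(x, ...) {
  labels <- x$channels$channel
  idx <- pair_index(length(labels), labels)
  purrr::imap(x$z, function(zm, id) {
    tibble(subject_id = id,
           channel_i = idx$channel_i, channel_j = idx$channel_j,
           z = zm[cbind(idx$i, idx$j)])
  }) |> purrr::list_rbind()
}

#' @export
print.sfnc_result <- function(x, ...) {
  cat(sprintf("<sfnc_result> %d subjects, %d channels (Fisher-z)\n",
              length(x$z), nrow(x$channels)))
  invisible(x)
}

#' Heatmap of the cohort-mean static connectivity matrix
#'
#' @param object An `sfnc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfnc_result
#' @export
autoplot.sfnc_result <- function(object, ...) {
  labels <- object$channels$channel
  m <- Reduce(`+`, object$z) / length(object$z)
  df <- tidyr::expand_grid(i = seq_along(labels), j = seq_along(labels))
  df$z <- m[cbind(df$i, df$j)]
  df$channel_i <- factor(labels[df$i], levels = labels)
  df$channel_j <- factor(labels[df$j], levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel_i, .data$channel_j,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean z",
                  title = "Cohort-mean static FNC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
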