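#' Tapered sliding-window specification
#'
#' A rectangular window of `width` TRs convolved with a truncated discrete
#' Gaussian (`sigma` TRs, cut at +-3 sigma), advanced in steps of `step`
#' TR. The central `width` samples of the full convolution are kept and
#' normalized to sum to one; the resulting taper is strictly positive,
#' symmetric and unimodal.
#'
#' @param width Window width in TR units (default 20).
#' @param gaussian_sigma Gaussian taper width in TR units (default 3).
#' @param step Window advance in TR units (default 1).
#' @return A `window_spec` list with the `taper` weight vector.
#' @export
window_spec <- function(width = 20, gaussian_sigma = 3, step = 1) {
  width <- check_scalar_count(width, "width", 2L)
  step <- check_scalar_count(step, "step", 1L)
  stopifnot(gaussian_sigma > 0)
  structure(list(width = width, gaussian_sigma = gaussian_sigma, step = step,
                 taper = build_taper(width, gaussian_sigma)),
            class = "window_spec")
}

#' Gaussian-convolved rectangular taper weights
#'
#' @param width Window width (>= 2).
#' @param gaussian_sigma Gaussian sigma in TR units (> 0); as
#'   `gaussian_sigma -> 0` the taper tends to uniform `1/width` weights.
#' @return Numeric weight vector of length `width`, summing to 1.
#' @export
build_taper <- function(width, gaussian_sigma) {
  width <- check_scalar_count(width, "width", 2L)
  if (!is.numeric(gaussian_sigma) || gaussian_sigma <= 0) {
    abort("`gaussian_sigma` must be positive")
  }
  half <- max(1L, ceiling(3 * gaussian_sigma))
  off <- seq(-half, half)
  g <- exp(-off^2 / (2 * gaussian_sigma^2))
  g <- g / sum(g)
  # full convolution of ones(width) with g has length width + 2*half;
  # sample m of the full convolution is sum_j g[j] over overlapping rect
  full_len <- width + 2L * half
  w <- vapply(seq_len(full_len), function(m) {
    j <- seq_along(off)
    rect_idx <- m - (j - 1L)
    sum(g[rect_idx >= 1L & rect_idx <= width])
  }, numeric(1))
  w <- w[(half + 1L):(half + width)]
  w / sum(w)
}

weighted_corr <- function(x, w) {
  m <- colSums(x * w)
  xc <- sweep(x, 2, m)
  cv <- crossprod(xc * sqrt(w))
  v <- diag(cv)
  degenerate <- v < 1e-12
  v[degenerate] <- 1
  r <- cv / sqrt(outer(v, v))
  if (any(degenerate)) {
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  list(r = r, degenerate = any(degenerate))
}

#' Windowed Fisher-z connectivity for one subject
#'
#' Slides the tapered window along the time axis; within each window the
#' Pearson correlation is computed with taper-weighted means and
#' covariances, then Fisher-z transformed. A channel that is constant
#' within a window yields zero correlations for its pairs (with a warning).
#'
#' @param ts Time-by-channel numeric matrix with `T >= width` rows.
#' @param spec A [window_spec()].
#' @return List with `z` (C x C x W array of Fisher-z values, zero
#'   diagonal) and `starts` (window start indices);
#'   `W = floor((T - width)/step) + 1`.
#' @export
windowed_fnc <- function(ts, spec = window_spec()) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts); C <- ncol(ts)
  if (n_t < spec$width) abort("time series shorter than the window width")
  starts <- seq(1L, n_t - spec$width + 1L, by = spec$step)
  z <- array(0, dim = c(C, C, length(starts)))
  any_deg <- FALSE
  for (wi in seq_along(starts)) {
    s <- starts[wi]
    wc <- weighted_corr(ts[s:(s + spec$width - 1L), , drop = FALSE], spec$taper)
    any_deg <- any_deg || wc$degenerate
    zm <- fisher_z(wc$r)
    diag(zm) <- 0
    z[, , wi] <- zm
  }
  if (any_deg) warn("constant channel within a window: affected pair correlations set to 0")
  list(z = z, starts = starts)
}

#' Dynamic functional network connectivity for a cohort
#'
#' Applies [windowed_fnc()] subject-wise over a panel.
#'
#' @param panel A [ts_panel].
#' @param spec A [window_spec()].
#' @param use_nodes Use the node-level series instead of the component
#'   series (default `FALSE`).
#' @return A `dfnc_result`: per-subject stacks of windowed z-matrices plus
#'   the window specification and panel metadata.
#' @export
dfnc <- function(panel, spec = window_spec(), use_nodes = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  series <- if (use_nodes) panel$node_series else panel$series
  if (is.null(series)) abort("panel has no node-level series")
  res <- map(series, windowed_fnc, spec = spec)
  channels <- if (use_nodes) {
    tibble(channel = colnames(series[[1]]),
           network = panel$node_networks %||%
             rep("all", ncol(series[[1]])))
  } else panel$channels
  structure(list(z = map(res, "z"), starts = map(res, "starts"),
                 spec = spec, channels = channels, manifest = panel$manifest),
            class = "dfnc_result")
}

#' @export
print.dfnc_result <- function(x, ...) {
  cat(sprintf("<dfnc_result> %d subjects, %d channels, %d windows (width %d, step %d, sigma %g)\n",
              length(x$z), nrow(x$channels), dim(x$z[[1]])[3],
              x$spec$width, x$spec$step, x$spec$gaussian_sigma))
  invisible(x)
}

pool_windows <- function(dfnc) {
  C <- nrow(dfnc$channels)
  idx <- pair_index(C)
  mats <- map(dfnc$z, function(a) {
    t(apply(a, 3, function(m) m[cbind(idx$i, idx$j)]))
  })
  x <- do.call(rbind, mats)
  meta <- tibble(subject_id = rep(names(dfnc$z), vapply(mats, nrow, integer(1))),
                 window = unlist(lapply(mats, function(m) seq_len(nrow(m)))))
  list(x = x, meta = meta)
}

kmeans_once <- function(x, k, metric, seed, max_iter = 500L) {
  set.seed(seed)
  n <- nrow(x)
  tx <- t(x)
  # k-means++ seeding: subsequent centers drawn proportionally to their
  # distance from the nearest chosen center, robust to imbalanced states
  idx <- sample.int(n, 1)
  if (k > 1) {
    d_min <- rep(Inf, n)
    for (j in 2:k) {
      last <- x[idx[j - 1], ]
      d_new <- if (metric == "euclidean") {
        colSums((tx - last)^2)
      } else {
        colSums(abs(tx - last))
      }
      d_min <- pmin(d_min, d_new)
      if (all(d_min == 0)) {
        idx <- c(idx, sample.int(n, 1))
      } else {
        idx <- c(idx, sample.int(n, 1, prob = d_min))
      }
    }
  }
  cent <- x[idx, , drop = FALSE]
  assign_old <- rep(0L, n)
  dist_to <- function(cent) {
    if (metric == "euclidean") {
      d <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(cent) +
        outer(rep(1, n), rowSums(cent^2))
      pmax(d, 0)
    } else {
      # city-block: centroid recycles down the columns of t(x)
      vapply(seq_len(k), function(j) colSums(abs(tx - cent[j, ])),
             numeric(n))
    }
  }
  for (it in seq_len(max_iter)) {
    d <- dist_to(cent)
    a <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      rows <- a == j
      if (!any(rows)) {
        # empty cluster: reseed at the point farthest from its centroid
        far <- which.max(d[cbind(seq_len(n), a)])
        cent[j, ] <- x[far, ]
        a[far] <- j
        rows <- a == j
      }
      cent[j, ] <- if (metric == "euclidean") {
        colMeans(x[rows, , drop = FALSE])
      } else {
        apply(x[rows, , drop = FALSE], 2, stats::median)
      }
    }
    if (identical(a, assign_old)) break
    assign_old <- a
  }
  d <- dist_to(cent)
  obj <- sum(d[cbind(seq_len(n), a)])
  list(centroids = cent, assignment = a, objective = obj)
}

#' k-means decomposition of pooled windowed connectivity into states
#'
#' Pools every subject's windowed Fisher-z pair vectors and clusters them
#' into `k` recurring connectivity states by Lloyd-style k-means with
#' k-means++ seeding, best of `n_restarts` restarts. City-block distance (with
#' per-coordinate median centroids) is the default, matching common dFNC
#' practice; squared-Euclidean (mean centroids) is available. States are
#' renumbered in descending order of pooled occurrence, so state 1 is the
#' most visited.
#'
#' @param dfnc A `dfnc_result` (or a plain windows-by-pairs matrix).
#' @param k Number of states (default 6).
#' @param distance `"cityblock"` (default) or `"euclidean"`.
#' @param n_restarts Random restarts (default 20).
#' @param seed Master seed; restart seeds derive from it.
#' @return A `state_model`: `centroids` (k x pairs), `assignments` tibble
#'   (`subject_id`, `window`, `state`), `inertia`, `distance_metric`, `k`.
#' @export
cluster_states <- function(dfnc, k = 6, distance = c("cityblock", "euclidean"),
                           n_restarts = 20, seed = 1L) {
  distance <- match.arg(distance)
  k <- check_scalar_count(k, "k")
  n_restarts <- check_scalar_count(n_restarts, "n_restarts")
  if (inherits(dfnc, "dfnc_result")) {
    pooled <- pool_windows(dfnc)
    channels <- dfnc$channels
  } else {
    pooled <- list(x = as.matrix(dfnc),
                   meta = tibble(subject_id = "S1",
                                 window = seq_len(nrow(dfnc))))
    channels <- NULL
  }
  if (nrow(pooled$x) < k) abort("fewer pooled windows than states requested")

  runs <- lapply(seq_len(n_restarts), function(r) {
    kmeans_once(pooled$x, k, distance, derive_seed(seed, r))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]

  # deterministic state indices: descending pooled occurrence
  counts <- tabulate(best$assignment, nbins = k)
  ord <- order(-counts, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  assignment <- relab[best$assignment]
  centroids <- best$centroids[ord, , drop = FALSE]

  structure(list(
    centroids = centroids,
    assignments = dplyr::mutate(pooled$meta, state = as.integer(assignment)),
    inertia = best$objective,
    distance_metric = distance,
    k = k, seed = seed, channels = channels
  ), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d (%s distance), %d windows, objective %.4g\n",
              x$k, x$distance_metric, nrow(x$assignments), x$inertia))
  print(dplyr::count(x$assignments, .data$state))
  invisible(x)
}

#' @describeIn cluster_states Window assignments as a tibble.
#' @param x,object A `state_model`.
#' @param ... Unused.
#' @method tidy state_model
#' @export
tidy.state_model <- function(x, ...) x$assignments

#' @describeIn cluster_states One-row model summary.
#' @method glance state_model
#' @export
glance.state_model <- function(x, ...) {
  tibble(k = x$k, distance_metric = x$distance_metric, inertia = x$inertia,
         n_windows = nrow(x$assignments),
         n_subjects = dplyr::n_distinct(x$assignments$subject_id))
}

#' @describeIn cluster_states Centroid heatmaps, one facet per state.
#' @method autoplot state_model
#' @export
autoplot.state_model <- function(object, ...) {
  if (is.null(object$channels)) abort("state model carries no channel labels")
  labels <- object$channels$channel
  idx <- pair_index(length(labels), labels)
  df <- purrr::map_dfr(seq_len(object$k), function(s) {
    dplyr::mutate(idx, state = paste("State", s), z = object$centroids[s, ])
  })
  df$channel_i <- factor(df$channel_i, levels = labels)
  df$channel_j <- factor(df$channel_j, levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel_j, .data$channel_i,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "centroid z",
                  title = "Connectivity-state centroids") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Temporal state metrics for one assignment sequence
#'
#' Fraction time is the share of windows spent in each state; mean dwell
#' time is the average length (in windows) of maximal consecutive runs of
#' a state, `NA` for states never visited; the transition count is the
#' number of adjacent-window label changes.
#'
#' @param assignments Integer state labels over windows (one subject).
#' @param k Number of states.
#' @return List with `fraction_time`, `mean_dwell_time` (length-k vectors)
#'   and `n_transitions`.
#' @export
state_metrics <- function(assignments, k) {
  k <- check_scalar_count(k, "k")
  a <- as.integer(assignments)
  if (length(a) == 0L) abort("empty assignment sequence")
  if (any(a < 1L | a > k)) abort("state labels must lie in 1..k")
  runs <- rle(a)
  ft <- tabulate(a, nbins = k) / length(a)
  mdt <- vapply(seq_len(k), function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len) == 0L) NA_real_ else mean(len)
  }, numeric(1))
  list(fraction_time = ft, mean_dwell_time = mdt,
       n_transitions = sum(diff(a) != 0L))
}

#' Per-subject temporal state metrics table
#'
#' @param model A `state_model`.
#' @return Tibble with one row per subject: `ft_1..ft_k`, `mdt_1..mdt_k`,
#'   `n_transitions`.
#' @export
state_metrics_table <- function(model) {
  stopifnot(inherits(model, "state_model"))
  k <- model$k
  model$assignments |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$window, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) {
      m <- state_metrics(d$state, k)
      out <- c(stats::setNames(m$fraction_time, paste0("ft_", seq_len(k))),
               stats::setNames(m$mean_dwell_time, paste0("mdt_", seq_len(k))),
               n_transitions = m$n_transitions)
      as_tibble(as.list(out))
    }) |>
    dplyr::ungroup()
}

#' Across-window variability of dynamic connectivity
#'
#' Per subject and channel pair, the sample standard deviation (denominator
#' `W - 1`) of the windowed Pearson correlation coefficients `r` (not their
#' Fisher-z transforms) across windows.
#'
#' @param dfnc A `dfnc_result` with at least 2 windows.
#' @return A `variability_result`: named list `sd` of C x C symmetric
#'   zero-diagonal matrices plus `channels`.
#' @export
dfnc_variability <- function(dfnc) {
  stopifnot(inherits(dfnc, "dfnc_result"))
  if (dim(dfnc$z[[1]])[3] < 2L) abort("need at least 2 windows for variability")
  sds <- map(dfnc$z, function(a) {
    r <- tanh(a)
    m <- apply(r, c(1, 2), stats::sd)
    diag(m) <- 0
    m
  })
  structure(list(sd = sds, channels = dfnc$channels),
            class = "variability_result")
}

#' @method tidy variability_result
#' @export
tidy.variability_result <- function(x, ...) {
  labels <- x$channels$channel
  idx <- pair_index(length(labels), labels)
  purrr::imap(x$sd, function(m, id) {
    tibble(subject_id = id, channel_i = idx$channel_i,
           channel_j = idx$channel_j, sd_r = m[cbind(idx$i, idx$j)])
  }) |> purrr::list_rbind()
}
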