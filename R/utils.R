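#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int imap pmap
NULL

# Row-major strict lower-triangle pair order: (2,1), (3,1), (3,2), (4,1), ...
# This ordering is the package-wide convention for vectorizing symmetric
# connectivity matrices; centroids, variability tables and GLM feature
# columns all follow it.
pair_index <- function(n_channels, labels = NULL) {
  stopifnot(n_channels >= 2)
  i <- unlist(lapply(2:n_channels, function(r) rep(r, r - 1L)))
  j <- unlist(lapply(2:n_channels, function(r) seq_len(r - 1L)))
  out <- tibble(i = as.integer(i), j = as.integer(j))
  if (!is.null(labels)) {
    out$channel_i <- labels[out$i]
    out$channel_j <- labels[out$j]
  }
  out
}

# Vectorize a symmetric matrix along the canonical pair order.
lower_pairs <- function(m) {
  idx <- pair_index(ncol(m))
  m[cbind(idx$i, idx$j)]
}

# Inverse of lower_pairs(): rebuild a symmetric zero-diagonal matrix.
unvec_pairs <- function(v, n_channels) {
  idx <- pair_index(n_channels)
  m <- matrix(0, n_channels, n_channels)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  x
}

# Deterministic half-up rounding (round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Sub-seed derivation: stable under subject/task reordering, stays within
# the 32-bit integer range R's RNG accepts.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483647) + 1L
}

# Nearest positive-definite projection by eigenvalue clipping.
clip_to_pd <- function(sigma, eps = 1e-6) {
  es <- eigen(sigma, symmetric = TRUE)
  if (min(es$values) > eps) return(sigma)
  vals <- pmax(es$values, eps)
  out <- es$vectors %*% (vals * t(es$vectors))
  (out + t(out)) / 2
}

is_symmetric_num <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
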