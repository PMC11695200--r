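# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: literal queue BFS, step-up FDR by definition,
# direct quadruple-sum multilayer quality, restricted-growth-string
# partition enumeration, and naive convolution.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# All permutations of a small vector (used to match recovered state labels
# to generative ones).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

best_label_match <- function(recovered, truth, k) {
  best <- NULL
  best_acc <- -1
  for (p in perms(seq_len(k))) {
    acc <- mean(p[recovered] == truth)
    if (acc > best_acc) {
      best_acc <- acc
      best <- p
    }
  }
  list(mapped = best[recovered], accuracy = best_acc)
}

# Literal queue-based breadth-first search, one source at a time.
bfs_oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in which(adj[v, ] > 0)) {
        if (is.infinite(d[s, u])) {
          d[s, u] <- d[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bfs_oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, significant = q <= alpha)
}

# Direct quadruple-sum multilayer quality (independent of the package's
# vectorized evaluation).
oracle_multilayer_q <- function(labels, layers, gamma, omega) {
  n <- nrow(labels)
  L <- ncol(labels)
  twom <- vapply(layers, sum, numeric(1))
  k <- vapply(layers, colSums, numeric(n))
  k <- matrix(k, nrow = n)
  total <- 0
  for (l in seq_len(L)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (labels[i, l] == labels[j, l]) {
          null_term <- if (twom[l] > 0) gamma * k[i, l] * k[j, l] / twom[l] else 0
          total <- total + layers[[l]][i, j] - null_term
        }
      }
    }
    if (l < L) {
      for (i in seq_len(n)) {
        if (labels[i, l] == labels[i, l + 1]) total <- total + 2 * omega
      }
    }
  }
  twomu <- sum(twom) + 2 * omega * n * (L - 1)
  if (twomu == 0) 0 else total / twomu
}

# Restricted growth strings: all partitions of n items into at most
# max_comm blocks.
all_partitions <- function(n, max_comm = n) {
  out <- list()
  recurse <- function(prefix, used) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    top <- min(used + 1, max_comm)
    for (lab in seq_len(top)) {
      recurse(c(prefix, lab), max(used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum of the multilayer quality over all partitions of the
# (node, layer) units; feasible for ~8 units.
exhaustive_best_q <- function(net, params, max_comm) {
  n <- net$n_nodes
  L <- net$n_layers
  best <- -Inf
  for (p in all_partitions(n * L, max_comm)) {
    lab <- matrix(p, n, L)
    q <- multilayer_modularity(lab, net, params)
    if (q > best) best <- q
  }
  best
}

# Small random symmetric weight matrix with zero diagonal.
random_symmetric <- function(n, density = 0.5) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  vals <- ifelse(stats::runif(sum(up)) < density, stats::runif(sum(up)), 0)
  m[up] <- vals
  m + t(m)
}

# Quick small cohort for IO / pipeline tests.
tiny_cohort <- function(n = 3, t_len = 60, n_nodes = 0, seed = 7,
                        effects = list()) {
  make_cohort(sim_config(
    n_per_group = c(arhl = n, hc = n), n_timepoints = t_len,
    n_nodes = n_nodes, group_effect_spec = effects, seed = seed))
}

# The state-recovery benchmark: six well-separated all-pattern covariance
# states with a sticky chain. stay = 0.99 keeps transition-straddling windows
# rare while every state retains enough occupancy to be identifiable in a
# 20-subject cohort (stickier chains let single states nearly vanish).
recovery_config <- function(seed, n_per_group = c(a = 10, b = 10),
                            n_timepoints = 234) {
  sim_config(
    n_per_group = n_per_group, n_timepoints = n_timepoints, n_nodes = 0,
    transition_matrix = default_transition_matrix(6, stay = 0.99),
    state_covariances = state_covariance_library(default_channels(), 6, 0.85,
                                                 include_weak = FALSE),
    group_effect_spec = list(), seed = seed)
}

# Taper-weight mass of the dominant state per window: windows below a mass
# threshold straddle a transition and carry no well-defined generative label.
dominant_state_mass <- function(state_sequence, spec) {
  starts <- seq(1, length(state_sequence) - spec$width + 1, by = spec$step)
  vapply(starts, function(x) {
    lab <- state_sequence[x:(x + spec$width - 1)]
    max(tapply(spec$taper, lab, sum))
  }, numeric(1))
}
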