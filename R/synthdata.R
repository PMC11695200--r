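#' Default channel table: 13 components across six resting-state networks
#'
#' Mirrors the usual post-ICA component selection: central executive (3),
#' default mode (2), auditory (2), salience (1), visual (3) and
#' sensorimotor (2) components.
#'
#' @return Tibble with columns `channel`, `network`.
#' @export
default_channels <- function() {
  tibble(
    channel = c("CEN.1", "CEN.2", "CEN.3", "DMN.1", "DMN.2", "AUN.1",
                "AUN.2", "SN.1", "VN.1", "VN.2", "VN.3", "SMN.1", "SMN.2"),
    network = c("CEN", "CEN", "CEN", "DMN", "DMN", "AUN", "AUN", "SN",
                "VN", "VN", "VN", "SMN", "SMN")
  )
}

#' Library of state covariance matrices
#'
#' Builds `n_states` distinct symmetric positive-definite correlation
#' matrices over the given channels via a one-factor loading model: in each
#' state a pair of networks couples positively (loading `strength`) and one
#' network couples negatively, so consecutive states share at most one
#' network and centroids are well separated in pair-z space. The last state
#' is a diffuse weak-connectivity state (within-network r = 0.1 only),
#' emulating the commonly dominant weakly connected state.
#'
#' @param channels Tibble with `channel`, `network` columns.
#' @param n_states Number of states (default 6).
#' @param strength Factor loading magnitude in (0, 1); between-channel
#'   correlations within a coupled block are `strength^2`.
#' @param include_weak Make the last state the diffuse weak-connectivity
#'   state (default `TRUE`, realistic cohorts); `FALSE` gives all-pattern
#'   states, maximizing inter-centroid separation for recovery benchmarks.
#' @return List of `n_states` positive-definite covariance matrices.
#' @export
state_covariance_library <- function(channels = default_channels(),
                                     n_states = 6, strength = 0.8,
                                     include_weak = TRUE) {
  stopifnot(strength > 0, strength < 1)
  n_states <- check_scalar_count(n_states, "n_states")
  nets <- unique(channels$network)
  n_net <- length(nets)
  C <- nrow(channels)
  out <- vector("list", n_states)
  for (k in seq_len(n_states)) {
    if (k == n_states && include_weak) {
      r <- diag(C)
      same_net <- outer(channels$network, channels$network, `==`)
      r[same_net] <- 0.1
      diag(r) <- 1
    } else {
      pos <- nets[(k - 1 + 0:1) %% n_net + 1]
      neg <- nets[(k + 1) %% n_net + 1]
      lam <- ifelse(channels$network %in% pos, strength,
                    ifelse(channels$network %in% neg, -strength, 0))
      r <- tcrossprod(lam)
      diag(r) <- 1
    }
    out[[k]] <- clip_to_pd(r)
  }
  out
}

#' Default Markov transition matrix for connectivity states
#'
#' Sticky chain with self-transition probability `stay` and the remaining
#' mass spread uniformly; `stay = 0.97` at TR = 2 s gives mean dwell times
#' around 30 windows, in line with reported dominant-state occupancies.
#'
#' @param n_states Number of states.
#' @param stay Self-transition probability.
#' @return Row-stochastic `n_states x n_states` matrix.
#' @export
default_transition_matrix <- function(n_states = 6, stay = 0.97) {
  n_states <- check_scalar_count(n_states, "n_states")
  check_prob(stay, "stay")
  if (n_states == 1L) return(matrix(1, 1, 1))
  p <- matrix((1 - stay) / (n_states - 1), n_states, n_states)
  diag(p) <- stay
  p
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults encode the study conditions the pipeline targets: two groups of
#' 66 patients and 54 controls, 234 retained volumes at TR = 2 s, 13
#' component channels over six networks, 90 atlas nodes, six recurring
#' covariance states with sticky Markov transitions, group effects injected
#' as Fisher-z shifts on selected pairs, and covariates matching typical
#' case-control margins (age ~ N(58.6, 6.7) truncated to \[50, 80\] years,
#' education ~ N(10.9, 1.7) years, gender ~ Bernoulli(0.525), mean FD ~
#' N(0.23, 0.07) truncated at 0 mm).
#'
#' @param n_per_group Named integer vector of group sizes (names are group
#'   labels; first group receives the `group_effect_spec` shifts).
#' @param n_timepoints Retained volumes per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param channels Channel table (`channel`, `network`).
#' @param n_nodes Number of atlas-node time courses to co-generate
#'   (0 disables the node-level series).
#' @param n_states Number of covariance states.
#' @param transition_matrix Row-stochastic state transition matrix.
#' @param state_covariances List of per-state positive-definite covariance
#'   matrices over the channels.
#' @param group_effect_spec List of `list(pair = c(i, j), shift = dz,
#'   group = label)`: Fisher-z shift applied to that pair's correlation in
#'   every state covariance for subjects of that group.
#' @param covariate_model List of sampling functions (each `function(n)`)
#'   for `age`, `gender`, `education`, `mean_fd` and any clinical scores.
#' @param seed Master seed; per-subject streams are derived from
#'   (seed, subject index) so cohorts are reproducible under reordering.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_per_group = c(arhl = 66, hc = 54),
                       n_timepoints = 234,
                       tr_seconds = 2,
                       channels = default_channels(),
                       n_nodes = 90,
                       n_states = 6,
                       transition_matrix = default_transition_matrix(n_states),
                       state_covariances =
                         state_covariance_library(channels, n_states),
                       group_effect_spec = default_group_effects(),
                       covariate_model = default_covariate_model(),
                       seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_timepoints = n_timepoints,
              tr_seconds = tr_seconds, channels = as_tibble(channels),
              n_nodes = n_nodes, n_states = n_states,
              transition_matrix = transition_matrix,
              state_covariances = state_covariances,
              group_effect_spec = group_effect_spec,
              covariate_model = covariate_model, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_group_effects <- function() {
  # DMN-DMN weakening plus DMN-SN and DMN-VN strengthening in the patient
  # group, the directions reported for hearing-loss cohorts.
  list(list(pair = c(4L, 5L), shift = -0.3, group = "arhl"),
       list(pair = c(5L, 8L), shift = 0.3, group = "arhl"),
       list(pair = c(4L, 11L), shift = 0.3, group = "arhl"))
}

#' @rdname sim_config
#' @export
default_covariate_model <- function() {
  list(
    age = function(n) pmin(pmax(stats::rnorm(n, 58.6, 6.7), 50), 80),
    gender = function(n) stats::rbinom(n, 1, 0.525),
    education = function(n) stats::rnorm(n, 10.9, 1.7),
    mean_fd = function(n) pmax(stats::rnorm(n, 0.23, 0.07), 0),
    moca = function(n) pmin(pmax(round(stats::rnorm(n, 26.5, 1.8)), 18), 30),
    pta = function(n) stats::rnorm(n, 25, 8)
  )
}

validate_sim_config <- function(cfg) {
  check_scalar_count(cfg$n_timepoints, "n_timepoints")
  check_scalar_count(cfg$n_states, "n_states")
  if (any(cfg$n_per_group < 1)) abort("n_per_group entries must be >= 1")
  if (is.null(names(cfg$n_per_group))) abort("n_per_group must be named by group")
  p <- cfg$transition_matrix
  if (!is.matrix(p) || nrow(p) != ncol(p) || nrow(p) != cfg$n_states) {
    abort("transition_matrix must be square with one row per state")
  }
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12)) {
    abort("transition_matrix rows must be nonnegative and sum to 1")
  }
  C <- nrow(cfg$channels)
  if (length(cfg$state_covariances) != cfg$n_states) {
    abort("need one state covariance per state")
  }
  for (k in seq_along(cfg$state_covariances)) {
    s <- cfg$state_covariances[[k]]
    if (!is_symmetric_num(s, 1e-8) || nrow(s) != C) {
      abort(sprintf("state covariance %d is not a symmetric %dx%d matrix", k, C, C))
    }
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      abort(sprintf("state covariance %d is not positive definite", k))
    }
  }
  invisible(cfg)
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param p Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% p == pi`.
#' @export
stationary_distribution <- function(p) {
  es <- eigen(t(p))
  i <- which.min(abs(es$values - 1))
  v <- abs(Re(es$vectors[, i]))
  v / sum(v)
}

#' Sample a Markov state sequence
#'
#' Draws the initial state from the stationary distribution, then follows
#' the chain. Identical seed gives an identical sequence.
#'
#' @param transition_matrix Row-stochastic square matrix.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return Integer vector of state labels in `1..K`.
#' @export
sample_state_sequence <- function(transition_matrix, length, seed = 1L) {
  p <- transition_matrix
  if (!is.matrix(p) || nrow(p) != ncol(p)) abort("transition matrix must be square")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12)) {
    abort("transition matrix rows must be nonnegative and sum to 1")
  }
  length <- check_scalar_count(length, "length")
  k <- nrow(p)
  set.seed(seed)
  out <- integer(length)
  out[1] <- sample.int(k, 1, prob = stationary_distribution(p))
  if (length > 1L) {
    for (t in 2:length) out[t] <- sample.int(k, 1, prob = p[out[t - 1], ])
  }
  out
}

apply_group_effects <- function(sigmas, effects, group, channels) {
  if (length(effects) == 0L) return(sigmas)
  lapply(sigmas, function(s) {
    d <- sqrt(diag(s))
    r <- stats::cov2cor(s)
    for (ef in effects) {
      if (!identical(ef$group, group)) next
      i <- ef$pair[1]; j <- ef$pair[2]
      znew <- atanh(max(min(r[i, j], 1 - 1e-7), -(1 - 1e-7))) + ef$shift
      rnew <- tanh(znew)
      if (abs(rnew) >= 1) {
        abort(sprintf(
          "group effect on pair (%s, %s) with shift %.3g drives |r| to 1: covariance not positive definite",
          channels$channel[i], channels$channel[j], ef$shift))
      }
      r[i, j] <- r[j, i] <- rnew
    }
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) r <- clip_to_pd(r)
    diag(d) %*% r %*% diag(d)
  })
}

# Expand component-level factor states to an n_nodes-dimensional covariance
# by giving every node the loading of its network's components (mean loading
# of the network block), so node-level layers share the component dynamics.
expand_states_to_nodes <- function(cfg) {
  nets <- unique(cfg$channels$network)
  node_net <- rep(nets, length.out = cfg$n_nodes)
  sig <- lapply(cfg$state_covariances, function(s) {
    r <- stats::cov2cor(s)
    # per-network representative loading: signed sqrt of mean within-block
    # off-diagonal correlation against the first network's sign pattern
    lam_net <- vapply(nets, function(nw) {
      idx <- which(cfg$channels$network == nw)
      others <- setdiff(seq_len(nrow(r)), idx)
      v <- mean(r[idx, others, drop = FALSE])
      sign(v) * sqrt(min(abs(v) + 0.05, 0.9))
    }, numeric(1))
    lam <- lam_net[match(node_net, nets)]
    rn <- tcrossprod(lam)
    same <- outer(node_net, node_net, `==`)
    rn[same] <- pmax(rn[same], 0.2)
    diag(rn) <- 1
    clip_to_pd(rn)
  })
  list(sigmas = sig, node_networks = node_net)
}

#' Generate a synthetic cohort
#'
#' For each subject a state sequence is drawn from the Markov chain, and at
#' each time point a zero-mean multivariate normal vector with the active
#' state's covariance is emitted. Group effects are injected by shifting
#' the configured pairs' correlations on the Fisher-z scale and
#' reconstructing the (positive-definite) covariance. Covariates are drawn
#' from `covariate_model`. Per-subject random streams derive from
#' (master seed, subject index).
#'
#' @param config A [sim_config()].
#' @return List with `panel` (a [ts_panel]) and `truth` (state sequences,
#'   stationary distribution, per-group state covariances, config).
#' @export
make_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  C <- nrow(cfg$channels)

  group_sigmas <- lapply(unique(groups), function(g) {
    lapply(apply_group_effects(cfg$state_covariances, cfg$group_effect_spec,
                               g, cfg$channels),
           function(s) chol(s))
  })
  names(group_sigmas) <- unique(groups)

  node_info <- NULL
  node_chol <- NULL
  if (cfg$n_nodes > 0) {
    node_info <- expand_states_to_nodes(cfg)
    node_chol <- lapply(node_info$sigmas, chol)
  }

  set.seed(derive_seed(cfg$seed, 0L))
  cov_draws <- lapply(cfg$covariate_model, function(f) f(n))

  series <- vector("list", n)
  node_series <- if (cfg$n_nodes > 0) vector("list", n) else NULL
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    s_seed <- derive_seed(cfg$seed, i)
    seqs[[i]] <- sample_state_sequence(cfg$transition_matrix,
                                       cfg$n_timepoints, seed = s_seed)
    set.seed(derive_seed(s_seed, 1L))
    z <- matrix(stats::rnorm(cfg$n_timepoints * C), cfg$n_timepoints, C)
    x <- matrix(0, cfg$n_timepoints, C,
                dimnames = list(NULL, cfg$channels$channel))
    for (k in unique(seqs[[i]])) {
      rows <- seqs[[i]] == k
      x[rows, ] <- z[rows, , drop = FALSE] %*% group_sigmas[[groups[i]]][[k]]
    }
    series[[i]] <- x
    if (cfg$n_nodes > 0) {
      zn <- matrix(stats::rnorm(cfg$n_timepoints * cfg$n_nodes),
                   cfg$n_timepoints, cfg$n_nodes)
      xn <- matrix(0, cfg$n_timepoints, cfg$n_nodes,
                   dimnames = list(NULL, sprintf("node%02d", seq_len(cfg$n_nodes))))
      for (k in unique(seqs[[i]])) {
        rows <- seqs[[i]] == k
        xn[rows, ] <- zn[rows, , drop = FALSE] %*% node_chol[[k]]
      }
      node_series[[i]] <- xn
    }
  }
  names(series) <- ids
  if (!is.null(node_series)) names(node_series) <- ids
  names(seqs) <- ids

  manifest <- tibble(subject_id = ids, group = groups) |>
    dplyr::bind_cols(as_tibble(cov_draws))

  panel <- ts_panel(series, cfg$channels, manifest, tr = cfg$tr_seconds,
                    node_series = node_series,
                    node_networks = node_info$node_networks)
  truth <- list(state_sequences = seqs,
                stationary_distribution =
                  stationary_distribution(cfg$transition_matrix),
                config = cfg)
  list(panel = panel, truth = truth)
}

#' True state label per sliding window
#'
#' The generative state of a window is the state carrying the largest
#' taper-weight mass inside the window (ties go to the smaller state
#' label), the
#' natural ground truth for windowed estimates of a switching process.
#'
#' @param state_sequence Integer state labels over time.
#' @param spec A [window_spec()].
#' @return Integer vector of per-window true states.
#' @export
true_window_states <- function(state_sequence, spec) {
  w <- spec$width
  starts <- seq(1L, length(state_sequence) - w + 1L, by = spec$step)
  vapply(starts, function(s) {
    lab <- state_sequence[s:(s + w - 1L)]
    mass <- tapply(spec$taper, lab, sum)
    as.integer(names(mass)[which.max(mass)])
  }, integer(1))
}

#' Planted-partition layered network
#'
#' Stochastic block model per layer: non-switcher nodes keep one module
#' across all layers; switcher nodes move to the next module (cyclically)
#' at exactly the configured layers. Within-module edges appear with
#' probability `p_in`, between-module with `p_out`; edges have weight 1.
#'
#' @param n_nodes,n_layers Network size.
#' @param module_spec Integer base partition of the nodes (layer-1 modules);
#'   default two equal modules.
#' @param switcher_nodes Integer node indices that switch module.
#' @param switch_layers Layers (each in `2..n_layers`) at which switchers
#'   change module.
#' @param p_in,p_out Within/between-module edge probabilities, `p_in > p_out`.
#' @param seed Integer seed.
#' @return List with `net` (a [layered_network]) and `truth`
#'   (`planted_partitions` N x L matrix, `switcher_nodes`).
#' @export
make_layered_network <- function(n_nodes, n_layers,
                                 module_spec = rep(1:2, length.out = n_nodes),
                                 switcher_nodes = integer(0),
                                 switch_layers = integer(0),
                                 p_in = 0.9, p_out = 0.05, seed = 1L) {
  n_nodes <- check_scalar_count(n_nodes, "n_nodes", 2L)
  n_layers <- check_scalar_count(n_layers, "n_layers")
  check_prob(p_in, "p_in"); check_prob(p_out, "p_out")
  if (p_in <= p_out) abort("p_in must exceed p_out: planted structure unrecoverable")
  if (length(switch_layers) && (any(switch_layers < 2) || any(switch_layers > n_layers))) {
    abort("switch_layers must lie in 2..n_layers")
  }
  stopifnot(length(module_spec) == n_nodes)
  n_mod <- max(module_spec)

  part <- matrix(rep(module_spec, n_layers), n_nodes, n_layers)
  for (l in seq_len(n_layers)[-1]) {
    part[, l] <- part[, l - 1]
    if (l %in% switch_layers && length(switcher_nodes)) {
      part[switcher_nodes, l] <- part[switcher_nodes, l] %% max(n_mod, 2) + 1L
    }
  }

  set.seed(seed)
  idx <- pair_index(n_nodes)
  layers <- lapply(seq_len(n_layers), function(l) {
    same <- part[idx$i, l] == part[idx$j, l]
    p <- ifelse(same, p_in, p_out)
    on <- stats::runif(nrow(idx)) < p
    unvec_pairs(as.numeric(on), n_nodes)
  })
  net <- layered_network(layers)
  list(net = net,
       truth = list(planted_partitions = part, switcher_nodes = switcher_nodes))
}
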