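#' Time-ordered layered network
#'
#' An ordered stack of symmetric nonnegative weight matrices, one per time
#' window, sharing node identity across layers. Input container for the
#' multilayer modularity and network-switching analysis.
#'
#' @param layers List of symmetric nonnegative N x N matrices with zero
#'   diagonal, in temporal order.
#' @param node_labels Optional character vector of node (region) names.
#' @param node_networks Optional character vector assigning nodes to
#'   functional networks (for network-level switching summaries).
#' @return An object of class `layered_network`.
#' @export
layered_network <- function(layers, node_labels = NULL, node_networks = NULL) {
  if (!is.list(layers) || length(layers) == 0L) abort("`layers` must be a non-empty list")
  n <- nrow(layers[[1]])
  for (l in seq_along(layers)) {
    a <- layers[[l]]
    if (!is_symmetric_num(a, 1e-8)) abort(sprintf("layer %d is not symmetric", l))
    if (nrow(a) != n) abort("all layers must share the node set")
    if (any(a < 0)) abort(sprintf("layer %d has negative weights", l))
    diag(layers[[l]]) <- 0
  }
  node_labels <- node_labels %||% sprintf("node%02d", seq_len(n))
  structure(list(layers = layers, n_nodes = n, n_layers = length(layers),
                 node_labels = node_labels, node_networks = node_networks),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("<layered_network> %d nodes x %d layers\n", x$n_nodes, x$n_layers))
  invisible(x)
}

#' Layered network from one subject's time courses
#'
#' Windowed, tapered correlation matrices become the layers; negative
#' weights are set to zero by default (the modularity null model assumes
#' nonnegative weights), or replaced by their absolute value.
#'
#' @param ts Time-by-node numeric matrix.
#' @param spec A [window_spec()].
#' @param weights Use raw correlations (`"r"`, default) or Fisher-z
#'   values (`"z"`) as edge weights.
#' @param negative `"zero"` (default) or `"absolute"`.
#' @param node_networks Optional node-to-network assignment.
#' @return A [layered_network].
#' @export
layered_network_from_ts <- function(ts, spec = window_spec(),
                                    weights = c("r", "z"),
                                    negative = c("zero", "absolute"),
                                    node_networks = NULL) {
  weights <- match.arg(weights)
  negative <- match.arg(negative)
  wf <- windowed_fnc(ts, spec)
  layers <- lapply(seq_len(dim(wf$z)[3]), function(wi) {
    m <- wf$z[, , wi]
    if (weights == "r") m <- tanh(m)
    if (negative == "zero") m[m < 0] <- 0 else m <- abs(m)
    diag(m) <- 0
    m
  })
  layered_network(layers, node_labels = colnames(ts),
                  node_networks = node_networks)
}

#' Multilayer parameters
#'
#' @param gamma Intra-layer resolution, applied uniformly to all layers
#'   (default 1.1).
#' @param omega Ordinal interlayer coupling between a node's copies in
#'   adjacent layers (default 0.5).
#' @param n_repeats Optimizer restarts (default 20).
#' @param seed Master seed.
#' @return A `multilayer_params` list.
#' @export
multilayer_params <- function(gamma = 1.1, omega = 0.5, n_repeats = 20,
                              seed = 1L) {
  stopifnot(gamma > 0, omega >= 0)
  n_repeats <- check_scalar_count(n_repeats, "n_repeats")
  structure(list(gamma = gamma, omega = omega, n_repeats = n_repeats,
                 seed = seed), class = "multilayer_params")
}

ml_precompute <- function(net, params) {
  k <- vapply(net$layers, colSums, numeric(net$n_nodes))  # N x L strengths
  twom <- vapply(net$layers, sum, numeric(1))
  if (any(twom == 0)) warn("layer(s) with zero total weight: null term set to 0")
  twomu <- sum(twom) + 2 * params$omega * net$n_nodes * (net$n_layers - 1)
  list(k = k, twom = twom, twomu = twomu)
}

#' Multilayer modularity of a partition
#'
#' Evaluates
#' `Q = (1/2mu) * sum_{ijlr} [(A_ijl - gamma k_il k_jl / 2m_l) delta_lr +
#' delta_ij omega 1(|l-r|=1)] delta(g_il, g_jr)`,
#' the standard multilayer quality with uniform resolution `gamma` and
#' ordinal interlayer coupling `omega`; `2mu` is the total intra-layer
#' edge weight plus total ordinal coupling. Layers with zero total weight
#' contribute a zero null term.
#'
#' @param partition N x L integer matrix of community labels (or an
#'   `ml_partition`).
#' @param net A [layered_network].
#' @param params A [multilayer_params()].
#' @return Scalar quality Q.
#' @export
multilayer_modularity <- function(partition, net, params = multilayer_params()) {
  g <- if (inherits(partition, "ml_partition")) partition$labels else partition
  stopifnot(is.matrix(g), nrow(g) == net$n_nodes, ncol(g) == net$n_layers)
  pre <- ml_precompute(net, params)
  total <- 0
  for (l in seq_len(net$n_layers)) {
    gl <- g[, l]
    same <- outer(gl, gl, `==`)
    a_within <- sum(net$layers[[l]][same])
    if (pre$twom[l] > 0) {
      kc <- rowsum(pre$k[, l], gl)
      total <- total + a_within - params$gamma * sum(kc^2) / pre$twom[l]
    }
  }
  if (net$n_layers > 1) {
    coup <- sum(g[, -net$n_layers] == g[, -1])
    total <- total + 2 * params$omega * coup
  }
  if (pre$twomu == 0) return(0)
  total / pre$twomu
}

# One full GenLouvain-style optimization run: unit-level greedy moves with
# the implicit null model, then collapsed-graph moves, iterated.
louvain_run <- function(net, params, seed) {
  N <- net$n_nodes; L <- net$n_layers; NL <- N * L
  pre <- ml_precompute(net, params)
  gamma <- params$gamma; omega <- params$omega
  g <- seq_len(NL)                       # unit communities, singletons
  Kcl <- matrix(0, NL, L)                # community strength per layer
  for (l in seq_len(L)) Kcl[cbind(g[(l - 1) * N + seq_len(N)], l)] <- pre$k[, l]
  set.seed(seed)

  unit_pass <- function() {
    moved <- 0L
    for (u in sample.int(NL)) {
      i <- (u - 1L) %% N + 1L
      l <- (u - 1L) %/% N + 1L
      cc <- g[u]
      w <- net$layers[[l]][, i]
      nb <- which(w > 0)
      cand <- unique(c(cc,
                       if (length(nb)) g[(l - 1L) * N + nb],
                       if (l > 1L) g[u - N],
                       if (l < L) g[u + N]))
      if (length(cand) == 1L) next
      kil <- pre$k[i, l]
      Kcl[cc, l] <<- Kcl[cc, l] - kil
      s_by <- if (length(nb)) rowsum(w[nb], g[(l - 1L) * N + nb]) else NULL
      gains <- vapply(cand, function(d) {
        s_d <- if (!is.null(s_by)) {
          m <- match(as.character(d), rownames(s_by))
          if (is.na(m)) 0 else s_by[m, 1]
        } else 0
        null_d <- if (pre$twom[l] > 0) gamma * kil * Kcl[d, l] / pre$twom[l] else 0
        coup <- omega * ((l > 1L && g[u - N] == d) + (l < L && g[u + N] == d))
        s_d - null_d + coup
      }, numeric(1))
      best <- cand[which.max(gains)]
      if (gains[which.max(gains)] <= gains[1] + 1e-12) best <- cc
      g[u] <<- best
      Kcl[best, l] <<- Kcl[best, l] + kil
      if (best != cc) moved <- moved + 1L
    }
    moved
  }

  collapse_pass <- function() {
    comm <- match(g, sort(unique(g)))
    nc <- max(comm)
    if (nc == 1L) return(FALSE)
    bhat <- matrix(0, nc, nc)
    for (l in seq_len(L)) {
      gl <- comm[(l - 1L) * N + seq_len(N)]
      a_cd <- rowsum(t(rowsum(net$layers[[l]], gl, reorder = TRUE)), gl,
                     reorder = TRUE)
      present <- sort(unique(gl))
      bhat[present, present] <- bhat[present, present] + a_cd
      if (pre$twom[l] > 0) {
        kc <- rowsum(pre$k[, l], gl, reorder = TRUE)[, 1]
        bhat[present, present] <- bhat[present, present] -
          gamma * tcrossprod(kc) / pre$twom[l]
      }
    }
    if (L > 1L) {
      for (l in seq_len(L - 1L)) {
        c1 <- comm[(l - 1L) * N + seq_len(N)]
        c2 <- comm[l * N + seq_len(N)]
        for (i in seq_len(N)) {
          bhat[c1[i], c2[i]] <- bhat[c1[i], c2[i]] + omega
          bhat[c2[i], c1[i]] <- bhat[c2[i], c1[i]] + omega
        }
      }
    }
    h <- seq_len(nc)
    improved <- FALSE
    repeat {
      moved <- 0L
      for (x in sample.int(nc)) {
        rs <- rowsum(bhat[x, ], h)
        cur <- h[x]
        groups <- as.integer(rownames(rs))
        rs_cur <- rs[match(cur, groups), 1]
        # gain of moving x from its group to D: 2*(rs_D - rs_cur + bhat_xx)
        delta <- rs[, 1] - rs_cur + bhat[x, x]
        delta[match(cur, groups)] <- 0
        d_best <- groups[which.max(delta)]
        if (d_best != cur && max(delta) > 1e-12) {
          h[x] <- d_best
          moved <- moved + 1L
          improved <- TRUE
        }
      }
      if (moved == 0L) break
    }
    if (improved) g <<- h[comm]
    improved
  }

  repeat {
    moved <- unit_pass()
    while (unit_pass() > 0L) NULL
    improved <- collapse_pass()
    if (!improved && moved == 0L) break
  }
  matrix(match(g, unique(g)), N, L)
}

canonicalize_labels <- function(lab) {
  matrix(match(as.vector(lab), unique(as.vector(lab))),
         nrow(lab), ncol(lab))
}

#' Ordinal multilayer Louvain community detection
#'
#' Greedy modularity optimization over (node, layer) units: each unit may
#' join the community of an intra-layer neighbor or of its own copy in an
#' adjacent layer, moves are accepted when they increase the multilayer
#' quality, and converged unit-level passes alternate with moves on the
#' community-collapsed quality matrix until a local optimum. The node
#' visiting order is randomized from the seed; the best of `n_repeats`
#' restarts (by Q) is returned.
#'
#' @param net A [layered_network].
#' @param params A [multilayer_params()].
#' @return An `ml_partition`: `labels` (N x L integer matrix, canonical
#'   first-occurrence numbering) and `quality` (Q re-evaluated by
#'   [multilayer_modularity()]).
#' @export
louvain_multilayer <- function(net, params = multilayer_params()) {
  stopifnot(inherits(net, "layered_network"))
  best <- NULL; best_q <- -Inf
  for (r in seq_len(params$n_repeats)) {
    lab <- louvain_run(net, params, derive_seed(params$seed, r))
    q <- multilayer_modularity(lab, net, params)
    if (q > best_q + 1e-15) {
      best_q <- q; best <- lab
    }
  }
  structure(list(labels = canonicalize_labels(best), quality = best_q),
            class = "ml_partition")
}

#' @export
print.ml_partition <- function(x, ...) {
  cat(sprintf("<ml_partition> %d nodes x %d layers, %d communities, Q = %.4f\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(as.vector(x$labels))), x$quality))
  invisible(x)
}

#' Network switching rate per node
#'
#' The fraction of adjacent-layer transitions at which a node changes
#' community: `rate_i = #\{l : g_il != g_i,l+1\} / (L - 1)`, in \[0, 1\].
#'
#' @param partition An `ml_partition` or N x L label matrix.
#' @param node_labels Optional node names.
#' @param node_networks Optional node-to-network assignment; when given,
#'   network-level mean rates are attached as an attribute and returned by
#'   the `network` column.
#' @return Tibble with `node`, `rate` (and `network` if assignments given).
#' @export
switching_rate <- function(partition, node_labels = NULL,
                           node_networks = NULL) {
  g <- if (inherits(partition, "ml_partition")) partition$labels else partition
  stopifnot(is.matrix(g))
  if (ncol(g) < 2L) abort("need at least 2 layers for a switching rate")
  changes <- rowSums(g[, -ncol(g), drop = FALSE] != g[, -1, drop = FALSE])
  out <- tibble(node = node_labels %||% sprintf("node%02d", seq_len(nrow(g))),
                rate = changes / (ncol(g) - 1))
  if (!is.null(node_networks)) out$network <- node_networks
  out
}

#' Mean switching rate per network
#'
#' @param rates Output of [switching_rate()] with a `network` column.
#' @return Tibble with `network`, `mean_rate`.
#' @export
network_switching <- function(rates) {
  stopifnot("network" %in% names(rates))
  rates |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(mean_rate = mean(.data$rate), .groups = "drop")
}

#' Consensus switching rates over optimizer restarts
#'
#' The multilayer optimizer is stochastic in its visiting order; switching
#' rates are therefore reported as the mean over `n_repeats` independent
#' single runs with distinct derived seeds, together with the across-run
#' standard deviation.
#'
#' @param net A [layered_network].
#' @param params A [multilayer_params()]; `n_repeats` controls the number
#'   of consensus runs.
#' @return Tibble with `node`, `rate` (mean across runs), `run_sd` (and
#'   `network` when the net carries node networks).
#' @export
consensus_switching <- function(net, params = multilayer_params()) {
  stopifnot(inherits(net, "layered_network"))
  one <- multilayer_params(params$gamma, params$omega, n_repeats = 1,
                           seed = params$seed)
  rates <- vapply(seq_len(params$n_repeats), function(r) {
    one$seed <- derive_seed(params$seed, 1000L + r)
    p <- louvain_multilayer(net, one)
    switching_rate(p)$rate
  }, numeric(net$n_nodes))
  rates <- matrix(rates, nrow = net$n_nodes)
  out <- tibble(node = net$node_labels,
                rate = rowMeans(rates),
                run_sd = apply(rates, 1, stats::sd))
  if (!is.null(net$node_networks)) out$network <- net$node_networks
  out
}
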