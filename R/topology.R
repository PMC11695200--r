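#' Binarize a weighted connectivity matrix at a sparsity threshold
#'
#' Retains the top `round(sparsity * C(C-1)/2)` edges ranked by signed
#' weight (so anticorrelations drop first), ties broken by (i, j)
#' lexicographic order in the strict lower triangle; everything else is
#' removed. Absolute-value ranking is available for sensitivity analyses.
#'
#' @param weights Symmetric numeric matrix (e.g. a windowed correlation
#'   matrix); the diagonal is ignored.
#' @param sparsity Proportion of edges to retain, in (0, 1].
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return A `binary_graph`: logical adjacency matrix (zero diagonal) with
#'   attributes `sparsity` and `n_edges`.
#' @export
threshold_by_sparsity <- function(weights, sparsity,
                                  ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (!is_symmetric_num(weights, 1e-8)) abort("`weights` must be symmetric")
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 1) {
    abort("`sparsity` must lie in (0, 1]")
  }
  C <- nrow(weights)
  idx <- pair_index(C)
  w <- weights[cbind(idx$i, idx$j)]
  if (ranking == "absolute") w <- abs(w)
  n_keep <- round_half_up(sparsity * nrow(idx))
  if (n_keep == 0) {
    warn("sparsity retains zero edges: returning an empty graph")
  }
  # order by descending weight, ties by (i, j) lexicographic pair order
  ord <- order(-w, idx$i, idx$j)
  keep <- ord[seq_len(n_keep)]
  adj <- matrix(FALSE, C, C)
  adj[cbind(idx$i[keep], idx$j[keep])] <- TRUE
  adj <- adj | t(adj)
  structure(adj, class = "binary_graph", sparsity = sparsity, n_edges = n_keep)
}

# All-pairs shortest-path lengths of a small binary graph by boolean
# matrix powers (breadth-first reachability); O(diameter) multiplications
# of C x C matrices, far cheaper than per-call graph-object construction
# at the call volumes of the flexibility stage.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  a <- adj > 0
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a] <- 1
  pow <- a
  step <- 1L
  while (step < n) {
    pow <- (pow %*% a) > 0
    newly <- pow & is.infinite(d)
    if (!any(newly)) break
    step <- step + 1L
    d[newly] <- step
  }
  d
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' `E_glob = 1/(C(C-1)) * sum_{i != j} 1/d_ij`; disconnected pairs
#' contribute 0. Lies in \[0, 1\]; 1 for the complete graph.
#'
#' @param g Logical/0-1 symmetric adjacency matrix (class `binary_graph`
#'   or plain matrix).
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(g) {
  g <- unclass(g) * 1
  C <- nrow(g)
  if (C < 2) abort("need at least 2 nodes")
  if (sum(g) == 0) return(0)
  inv <- 1 / bfs_distances(g)
  diag(inv) <- 0
  sum(inv) / (C * (C - 1))
}

#' Local efficiency of a binary graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbors (0 for nodes with fewer than 2 neighbors). Captures
#' fault tolerance / segregation of local neighborhoods.
#'
#' @inheritParams global_efficiency
#' @return Scalar efficiency.
#' @export
local_efficiency <- function(g) {
  g <- unclass(g) * 1
  C <- nrow(g)
  if (C < 2) abort("need at least 2 nodes")
  vals <- vapply(seq_len(C), function(i) {
    nb <- which(g[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(g[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Across-window flexibility of graph efficiency
#'
#' For every subject and window, the windowed correlation matrix is
#' binarized at each sparsity in the grid, global and local efficiency are
#' computed, and each metric's sparsity curve is integrated by the
#' trapezoid rule (AUC; a single grid point degenerates to the metric
#' value). Flexibility is the across-window sample standard deviation of
#' the per-window AUC.
#'
#' @param dfnc A `dfnc_result` with at least 2 windows.
#' @param sparsity_grid Increasing vector of sparsity levels (default
#'   `seq(0.10, 0.34, by = 0.01)`, a common small-network range keeping
#'   mean degree above `log(C)` at the low end).
#' @param ranking Edge ranking passed to [threshold_by_sparsity()].
#' @return Tibble with `subject_id`, `eglob_flex`, `eloc_flex`.
#' @export
efficiency_flexibility <- function(dfnc,
                                   sparsity_grid = seq(0.10, 0.34, by = 0.01),
                                   ranking = "signed") {
  stopifnot(inherits(dfnc, "dfnc_result"))
  if (length(sparsity_grid) == 0 || is.unsorted(sparsity_grid, strictly = TRUE)) {
    abort("`sparsity_grid` must be non-empty and strictly increasing")
  }
  if (dim(dfnc$z[[1]])[3] < 2L) abort("need at least 2 windows")
  purrr::imap(dfnc$z, function(a, id) {
    r <- tanh(a)
    aucs <- vapply(seq_len(dim(r)[3]), function(wi) {
      effs <- vapply(sparsity_grid, function(s) {
        g <- threshold_by_sparsity(r[, , wi], s, ranking = ranking)
        c(global_efficiency(g), local_efficiency(g))
      }, numeric(2))
      if (length(sparsity_grid) == 1L) effs[, 1] else
        c(pracma::trapz(sparsity_grid, effs[1, ]),
          pracma::trapz(sparsity_grid, effs[2, ]))
    }, numeric(2))
    tibble(subject_id = id,
           eglob_flex = stats::sd(aucs[1, ]),
           eloc_flex = stats::sd(aucs[2, ]))
  }) |> purrr::list_rbind()
}
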