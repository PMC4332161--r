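# Global and nodal graph metrics on binarized undirected graphs.
# All functions accept either a `binary_graph` (from `binarize()` /
# `preprocess()`) or a plain 0/1 adjacency matrix.

#' Names of the nine global graph metrics, in canonical feature order
#'
#' @return Character vector of length 9. This order defines the feature
#'   space used for classification throughout the package.
#' @export
global_metric_names <- function() {
  c("assortativity", "global_flow_coefficient", "global_total_flow",
    "global_betweenness", "global_efficiency", "modularity",
    "characteristic_path_length", "transitivity", "small_worldness")
}

#' Degree centrality
#'
#' Number of neighbors of each node.
#'
#' @param g A `binary_graph` or 0/1 adjacency matrix.
#' @return Integer vector of per-node degrees, named by node labels when
#'   available.
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
#' degree_centrality(star)
#' @export
degree_centrality <- function(g) {
  a <- as_adjacency(g)
  d <- as.integer(rowSums(a > 0))
  names(d) <- rownames(a)
  d
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees of the two endpoints of every
#' edge, with each undirected edge contributing both orientations.
#' Positive values mean high-degree nodes attach to high-degree nodes.
#'
#' @inheritParams degree_centrality
#' @return Correlation in \[-1, 1\], or `NA` with an `undefined_metric`
#'   warning when the graph has no edges or all edge-end degrees are
#'   equal (regular graphs).
#' @export
assortativity <- function(g) {
  a <- as_adjacency(g)
  deg <- rowSums(a > 0)
  e <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  if (nrow(e) == 0)
    return(undefined_metric("assortativity", "graph has no edges"))
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  if (stats::var(x) == 0)
    return(undefined_metric("assortativity",
                            "zero degree variance over edge ends"))
  stats::cor(x, y)
}

#' Flow coefficients
#'
#' The flow coefficient of a node v is the number of length-two paths
#' through v that bridge neighbors of v not directly linked to each
#' other, divided by the number of possible neighbor pairs
#' `k(k-1)/2`. Only unlinked neighbor pairs count: for those, the
#' length-two route through v is a genuine shortest path. Nodes with
#' fewer than two neighbors have flow 0 by convention.
#'
#' @inheritParams degree_centrality
#' @return A list: `node_flow` (per-node coefficient in \[0, 1\]),
#'   `node_flow_count` (per-node count of bridging length-two paths),
#'   `global_flow_coefficient` (mean coefficient over all nodes), and
#'   `global_total_flow` (mean bridging-path count over all nodes).
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' flow_coefficients(tri)$global_flow_coefficient  # all pairs closed: 0
#' @export
flow_coefficients <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  flow <- numeric(n)
  cnt <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    possible <- k * (k - 1) / 2
    closed <- sum(a[nb, nb]) / 2
    cnt[v] <- possible - closed
    flow[v] <- cnt[v] / possible
  }
  names(flow) <- names(cnt) <- rownames(a)
  list(node_flow = flow, node_flow_count = cnt,
       global_flow_coefficient = mean(flow),
       global_total_flow = mean(cnt))
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered node pairs (s, t), both
#' distinct from v, of the fraction of shortest s-t paths passing
#' through v (Brandes' algorithm; unnormalized raw path counts).
#' Pairs with no connecting path contribute zero.
#'
#' @inheritParams degree_centrality
#' @return A list: `node` (per-node betweenness) and `global` (mean over
#'   nodes).
#' @examples
#' path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
#' path3[2, 3] <- path3[3, 2] <- 1
#' betweenness(path3)$node  # middle node lies on the single A-C path
#' @export
betweenness <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1] <- s
    qh <- 1L; qt <- 1L
    preds <- vector("list", n)
    visited <- integer(0)
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      visited <- c(visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          qt <- qt + 1L
          queue[qt] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered (s, t) pair was accumulated twice
  names(bc) <- rownames(a)
  list(node = bc, global = mean(bc))
}

# Shortest-path distance matrix by breadth-first frontier expansion.
graph_distances <- function(a) {
  n <- nrow(a)
  d_mat <- matrix(Inf, n, n)
  diag(d_mat) <- 0
  reach <- diag(n) > 0
  step <- 0L
  repeat {
    step <- step + 1L
    new_reach <- reach | ((reach %*% a) > 0)
    changed <- new_reach & !reach
    if (!any(changed) || step > n) break
    d_mat[changed] <- step
    reach <- new_reach
  }
  d_mat
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' disconnected pairs contributing zero.
#'
#' @inheritParams degree_centrality
#' @return Efficiency in \[0, 1\]; 1 for a complete graph, 0 for an
#'   edgeless one.
#' @export
global_efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) return(0)
  d_mat <- graph_distances(a)
  inv <- 1 / d_mat[upper.tri(d_mat) | lower.tri(d_mat)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over distinct reachable node pairs. On a
#' disconnected graph, unreachable pairs are excluded from the mean and
#' a warning is raised; the 25%-density whole-brain graphs this package
#' targets are essentially always connected.
#'
#' @inheritParams degree_centrality
#' @return Mean distance (at least 1 for any graph with an edge), or
#'   `NA` with a warning for an edgeless graph.
#' @export
characteristic_path_length <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2)
    return(undefined_metric("characteristic path length", "fewer than 2 nodes"))
  d_mat <- graph_distances(a)
  off <- d_mat[upper.tri(d_mat) | lower.tri(d_mat)]
  finite <- is.finite(off)
  if (!all(finite))
    warning("graph is disconnected; averaging over reachable pairs only",
            call. = FALSE)
  if (!any(finite))
    return(undefined_metric("characteristic path length", "no reachable pairs"))
  mean(off[finite])
}

#' Transitivity
#'
#' Ratio of three times the number of triangles to the number of
#' connected triplets (paths of length two), i.e. the collectively
#' normalized clustering of the whole graph.
#'
#' @inheritParams degree_centrality
#' @return Transitivity in \[0, 1\], or `NA` with a warning when the
#'   graph has no connected triplet.
#' @export
transitivity <- function(g) {
  a <- as_adjacency(g)
  deg <- rowSums(a > 0)
  triplets2 <- sum(deg * (deg - 1))      # 2 x connected triplets
  if (triplets2 == 0)
    return(undefined_metric("transitivity", "no connected triplets"))
  closed <- sum(a * (a %*% a))           # trace(A^3) = 6 x triangles
  closed / triplets2
}

# Modularity of a given partition: sum over communities of
# e_c / m - (d_c / 2m)^2, with e_c the intra-community edge weight and
# d_c the total degree of the community.
partition_modularity <- function(a, membership) {
  m2 <- sum(a)
  if (m2 == 0) return(NA_real_)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    q <- q + sum(a[idx, idx]) / m2 - (sum(a[idx, ]) / m2)^2
  }
  q
}

# One stochastic Louvain-style optimization run: greedy single-node
# moves (including detaching into a singleton community) in random
# order, alternated with greedy community merges, until neither
# improves. Returns the membership vector.
louvain_once <- function(a) {
  n <- nrow(a)
  m <- sum(a) / 2
  deg <- rowSums(a)
  comm <- seq_len(n)
  dtot <- deg  # total degree per community label
  node_pass <- function() {
    any_move <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        nb <- which(a[i, ] > 0)
        if (!length(nb)) next
        cur <- comm[i]
        # candidate targets: neighbor communities plus detaching into a
        # fresh singleton community (candidate 0)
        cand <- c(unique(comm[nb]), 0L)
        k_ic <- vapply(cand, function(cc) sum(a[i, nb[comm[nb] == cc]]),
                       numeric(1))
        k_ia <- if (cur %in% cand) k_ic[match(cur, cand)] else 0
        d_excl <- ifelse(cand == 0L, 0,
                         dtot[pmax(cand, 1L)] - (cand == cur) * deg[i])
        d_cur_excl <- dtot[cur] - deg[i]
        gain <- (k_ic - k_ia) / m -
          deg[i] * (d_excl - d_cur_excl) / (2 * m^2)
        best <- which.max(gain)
        if (gain[best] > 1e-12 && cand[best] != cur) {
          target <- cand[best]
          if (target == 0L) {
            free <- setdiff(seq_len(n), unique(comm))
            if (!length(free)) next  # all singletons already
            target <- free[1]
          }
          dtot[cur] <<- dtot[cur] - deg[i]
          dtot[target] <<- dtot[target] + deg[i]
          comm[i] <<- target
          moved <- TRUE
          any_move <- TRUE
        }
      }
      if (!moved) break
    }
    any_move
  }
  merge_pass <- function() {
    any_merge <- FALSE
    repeat {
      labs <- unique(comm)
      if (length(labs) < 2) break
      best_gain <- 1e-12
      best_pair <- NULL
      for (ii in seq_along(labs)[-length(labs)]) {
        for (jj in seq((ii + 1), length(labs))) {
          ca <- labs[ii]; cb <- labs[jj]
          e_ab <- sum(a[comm == ca, comm == cb, drop = FALSE])
          if (e_ab == 0) next
          gain <- e_ab / m - dtot[ca] * dtot[cb] / (2 * m^2)
          if (gain > best_gain) {
            best_gain <- gain
            best_pair <- c(ca, cb)
          }
        }
      }
      if (is.null(best_pair)) break
      dtot[best_pair[1]] <<- dtot[best_pair[1]] + dtot[best_pair[2]]
      comm[comm == best_pair[2]] <<- best_pair[1]
      any_merge <- TRUE
    }
    any_merge
  }
  repeat {
    a1 <- node_pass()
    a2 <- merge_pass()
    if (!a1 && !a2) break
  }
  comm
}

# Exact maximum-modularity search over the complete set-partition space
# (restricted-growth enumeration). Only feasible for very small graphs;
# used when n is small enough that Bell(n) stays tiny.
exact_max_modularity <- function(a) {
  n <- nrow(a)
  best_q <- -Inf
  assign <- integer(n)
  rec <- function(i, k) {
    if (i > n) {
      q <- partition_modularity(a, assign)
      if (q > best_q) best_q <<- q
      return()
    }
    for (lab in seq_len(k + 1)) {
      assign[i] <<- lab
      rec(i + 1, max(k, lab))
    }
  }
  rec(1L, 0L)
  best_q
}

#' Modularity
#'
#' Quality of the best community partition found by a stochastic
#' Louvain-style optimizer (greedy local moves over a randomized node
#' order plus community aggregation). Because the optimizer is
#' stochastic, the returned value is the average over `n_iter`
#' independent runs. For graphs small enough to search the complete
#' partition space (at most 7 nodes) the optimizer is replaced by an
#' exact, deterministic maximum-modularity search, so every run
#' returns the true optimum.
#'
#' @inheritParams degree_centrality
#' @param n_iter Number of independent optimization runs averaged.
#'   Default 10.
#' @param seed Optional integer seed controlling the randomized node
#'   orders; identical seeds give identical results.
#' @return Mean modularity Q over runs, or `NA` with a warning for an
#'   edgeless graph.
#' @examples
#' two_tri <- matrix(0, 6, 6)
#' two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
#' modularity(two_tri, seed = 1)  # 0.5: two clean communities
#' @export
modularity <- function(g, n_iter = 10, seed = NULL) {
  a <- as_adjacency(g)
  if (sum(a) == 0)
    return(undefined_metric("modularity", "graph has no edges"))
  if (nrow(a) <= 7) return(exact_max_modularity(a))
  with_seed(seed, {
    qs <- vapply(seq_len(n_iter), function(i) {
      partition_modularity(a, louvain_once(a))
    }, numeric(1))
    mean(qs)
  })
}

#' Degree-preserving graph randomization
#'
#' Rewires a binary graph by repeated double-edge swaps, preserving
#' every node's degree exactly while destroying other structure. Swaps
#' that would create self-loops or duplicate edges are rejected.
#'
#' @inheritParams degree_centrality
#' @param seed Optional integer seed; identical seeds give identical
#'   rewirings.
#' @param nswap_factor Attempted swaps per edge (default 10, i.e.
#'   `10 * |E|` attempts), a standard mixing heuristic.
#' @return A `binary_graph` with the same degree sequence. Graphs that
#'   admit no swap at all (e.g. stars) are returned unchanged with a
#'   warning.
#' @export
randomize_degree_preserving <- function(g, seed = NULL, nswap_factor = 10) {
  a <- as_adjacency(g)
  labels <- rownames(a)
  el <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  m <- nrow(el)
  if (m < 2) {
    warning("graph has fewer than 2 edges; no swap possible, returning input",
            call. = FALSE)
    return(binarize(a))
  }
  with_seed(seed, {
    attempts <- ceiling(nswap_factor * m)
    pick1 <- sample.int(m, attempts, replace = TRUE)
    pick2 <- sample.int(m, attempts, replace = TRUE)
    flip <- stats::runif(attempts) < 0.5
    successes <- 0L
    for (t in seq_len(attempts)) {
      i <- pick1[t]; j <- pick2[t]
      if (i == j) next
      va <- el[i, 1]; vb <- el[i, 2]
      vc <- el[j, 1]; vd <- el[j, 2]
      if (flip[t]) { tmp <- vc; vc <- vd; vd <- tmp }
      # propose replacing (va-vb), (vc-vd) with (va-vd), (vc-vb)
      if (va == vd || vc == vb) next
      if (a[va, vd] > 0 || a[vc, vb] > 0) next
      a[va, vb] <- 0; a[vb, va] <- 0
      a[vc, vd] <- 0; a[vd, vc] <- 0
      a[va, vd] <- 1; a[vd, va] <- 1
      a[vc, vb] <- 1; a[vb, vc] <- 1
      el[i, ] <- c(va, vd)
      el[j, ] <- c(vc, vb)
      successes <- successes + 1L
    }
    if (successes == 0L)
      warning("no degree-preserving swap was possible; returning input graph",
              call. = FALSE)
    rownames(a) <- colnames(a) <- labels
    binarize(a)
  })
}

#' Small-worldness
#'
#' Ratio of normalized transitivity to normalized characteristic path
#' length: `S = (T / <T_null>) / (L / <L_null>)`, where the null means
#' are taken over `n_null` independent degree-preserving randomizations
#' of the graph (ratio of means, not mean of ratios). `S > 1` indicates
#' clustering above and path length near the random expectation -
#' the small-world regime.
#'
#' @inheritParams randomize_degree_preserving
#' @param n_null Number of null graphs (default 10).
#' @return Small-worldness S, or `NA` with a warning when transitivity
#'   is undefined or the null-mean transitivity is zero.
#' @export
small_worldness <- function(g, n_null = 10, seed = NULL, nswap_factor = 10) {
  t_obs <- suppressWarnings(transitivity(g))
  l_obs <- suppressWarnings(characteristic_path_length(g))
  if (!is.finite(t_obs) || !is.finite(l_obs))
    return(undefined_metric("small-worldness",
                            "transitivity or path length undefined"))
  seeds <- derive_seeds(seed, n_null)
  t_null <- numeric(n_null)
  l_null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    gn <- suppressWarnings(
      randomize_degree_preserving(g, seed = seeds[[i]],
                                  nswap_factor = nswap_factor))
    t_null[i] <- suppressWarnings(transitivity(gn))
    l_null[i] <- suppressWarnings(characteristic_path_length(gn))
  }
  mt <- mean(t_null); ml <- mean(l_null)
  if (!is.finite(mt) || mt == 0 || !is.finite(ml) || ml == 0)
    return(undefined_metric("small-worldness",
                            "null-model transitivity or path length degenerate"))
  (t_obs / mt) / (l_obs / ml)
}

# All nine global metrics for one graph, as a named numeric vector in
# canonical order. Undefined metrics come back NA (warnings muffled,
# missingness is recorded by the caller).
global_metrics_one <- function(g, n_iter = 10, n_null = 10, seed = NULL) {
  seeds <- derive_seeds(seed, 2)
  quiet <- function(expr) {
    withCallingHandlers(expr, undefined_metric = function(w)
      invokeRestart("muffleWarning"))
  }
  fl <- flow_coefficients(g)
  out <- c(
    assortativity = quiet(assortativity(g)),
    global_flow_coefficient = fl$global_flow_coefficient,
    global_total_flow = fl$global_total_flow,
    global_betweenness = betweenness(g)$global,
    global_efficiency = global_efficiency(g),
    modularity = quiet(modularity(g, n_iter = n_iter, seed = seeds[[1]])),
    characteristic_path_length = quiet(characteristic_path_length(g)),
    transitivity = quiet(transitivity(g)),
    small_worldness = quiet(small_worldness(g, n_null = n_null,
                                            seed = seeds[[2]]))
  )
  out[global_metric_names()]
}

#' Compute the per-subject global graph feature table
#'
#' Applies all nine global metrics to each subject's preprocessed
#' binary graph. The stochastic metrics (modularity, small-worldness)
#' receive per-subject sub-seeds derived deterministically from `seed`.
#'
#' @param graphs Named list of `binary_graph` objects (one per subject),
#'   all preprocessed at the same sparsity.
#' @param n_iter Modularity optimization runs per subject (default 10).
#' @param n_null Null graphs for small-worldness (default 10).
#' @param seed Optional master seed for reproducibility.
#' @return A data frame with one row per subject: `subject_id` followed
#'   by the nine metric columns in the order of [global_metric_names()].
#'   Metrics undefined for a subject's graph are `NA`.
#' @export
compute_feature_table <- function(graphs, n_iter = 10, n_null = 10,
                                  seed = NULL) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  ids <- names(graphs)
  if (is.null(ids)) ids <- sprintf("subject_%03d", seq_along(graphs))
  seeds <- derive_seeds(seed, length(graphs))
  rows <- lapply(seq_along(graphs), function(i) {
    global_metrics_one(graphs[[i]], n_iter = n_iter, n_null = n_null,
                       seed = seeds[[i]])
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(subject_id = ids, tab)
  rownames(tab) <- NULL
  tab
}
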