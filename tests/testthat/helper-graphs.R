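# Graph fixtures and independent brute-force / igraph oracles used
# across the metric and acceptance tests. Everything here is built in
# code at test time; the oracles deliberately avoid the package's own
# code paths.

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

complete_graph <- function(n) matrix(1, n, n) - diag(n)

# ring lattice: each node connected to its k nearest neighbors (k even),
# with a fraction of edges rewired to random shortcuts
ring_lattice <- function(n, k, p_rewire = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  for (j in seq_len(k / 2)) {
    idx <- cbind(seq_len(n), (seq_len(n) + j - 1) %% n + 1)
    a[idx] <- 1
    a[idx[, 2:1]] <- 1
  }
  if (p_rewire > 0) {
    edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    for (e in sample(nrow(edges), round(p_rewire * nrow(edges)))) {
      i <- edges[e, 1]
      free <- which(a[i, ] == 0 & seq_len(n) != i)
      if (!length(free)) next
      j_new <- if (length(free) == 1) free else sample(free, 1)
      j_old <- edges[e, 2]
      a[i, j_old] <- a[j_old, i] <- 0
      a[i, j_new] <- a[j_new, i] <- 1
    }
  }
  a
}

random_er_graph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- (runif(sum(ut)) < p) * 1
  a + t(a)
}

random_weight_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(rexp(n * n, 1 / 20), n, n)
  w <- w + t(w)
  diag(w) <- 0
  w
}

is_connected_adj <- function(a) {
  n <- nrow(a)
  r <- diag(n)
  for (k in seq_len(n)) r <- r + r %*% a
  all(r > 0)
}

# ---- igraph-based oracles -------------------------------------------------

as_ig <- function(a) igraph::graph_from_adjacency_matrix(a, mode = "undirected")

oracle_degree <- function(a) as.integer(igraph::degree(as_ig(a)))

oracle_assortativity <- function(a) {
  r <- suppressWarnings(igraph::assortativity_degree(as_ig(a)))
  if (is.nan(r)) NA_real_ else r
}

oracle_transitivity <- function(a) {
  t_val <- igraph::transitivity(as_ig(a), type = "global")
  if (is.nan(t_val)) NA_real_ else t_val
}

oracle_betweenness <- function(a) igraph::betweenness(as_ig(a), directed = FALSE)

oracle_distances <- function(a) igraph::distances(as_ig(a))

oracle_efficiency <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_cpl <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (!length(off)) NA_real_ else mean(off)
}

# flow coefficient by direct enumeration of neighbor pairs
oracle_flow <- function(a) {
  n <- nrow(a)
  flow <- numeric(n)
  cnt <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    open <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (a[nb[i], nb[j]] == 0) open <- open + 1
      }
    }
    cnt[v] <- open
    flow[v] <- open / (k * (k - 1) / 2)
  }
  list(flow = flow, global_flow = mean(flow), total_flow = mean(cnt))
}

# exact maximum modularity by recursive enumeration of all set
# partitions, scoring each with igraph's modularity
oracle_max_modularity <- function(a) {
  n <- nrow(a)
  g <- as_ig(a)
  best <- -Inf
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      q <- igraph::modularity(g, assign)
      if (q > best) best <<- q
      return()
    }
    for (lab in seq_len(k + 1)) rec(c(assign, lab), max(k, lab))
  }
  rec(integer(0), 0)
  best
}

# all connected graphs on 2..n_max nodes, one representative per
# isomorphism class, deduplicated by a label-invariant fingerprint
# (sorted degree sequence, triangle count, rounded adjacency spectrum).
# Class counts are asserted by the caller: matching the known counts
# (1, 2, 6, 21, 112) proves the fingerprint neither merged nor split
# any class.
connected_graph_classes <- function(n_max = 6) {
  reps <- list()
  counts <- integer(0)
  for (n in 2:n_max) {
    np <- n * (n - 1) / 2
    ut <- which(upper.tri(matrix(0, n, n)))
    seen <- new.env()
    cnt <- 0L
    for (code in seq_len(2^np - 1)) {
      a <- matrix(0, n, n)
      a[ut] <- as.integer(intToBits(code)[seq_len(np)])
      a <- a + t(a)
      if (!is_connected_adj(a)) next
      ev <- round(sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values), 5)
      key <- paste(c(n, sort(rowSums(a)), sum(diag(a %*% a %*% a)), ev),
                   collapse = "_")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cnt <- cnt + 1L
      reps[[length(reps) + 1]] <- a
    }
    counts <- c(counts, cnt)
  }
  list(graphs = reps, counts = counts)
}

# brute-force BH step-up flags, straight from the definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  max_i <- 0
  for (i in seq_len(m)) if (sorted[i] <= i / m * q) max_i <- i
  flags <- rep(FALSE, m)
  if (max_i > 0) flags[ord[seq_len(max_i)]] <- TRUE
  flags
}

# exact two-sided sign-test p by direct pmf summation
oracle_sign_p <- function(k, n) {
  pmf <- dbinom(0:n, n, 0.5)
  min(1, 2 * min(sum(pmf[1:(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
}
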