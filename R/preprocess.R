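# Preprocessing of weighted connectivity matrices into the binarized,
# fixed-density graphs on which all metrics are computed. The three
# steps are applied in order: min-max normalization of off-diagonal
# edge weights, sparsity thresholding retaining the strongest fraction
# of possible edges, and binarization.

#' Min-max normalize the off-diagonal edge weights of a connectivity matrix
#'
#' Affinely rescales the off-diagonal entries so the minimum becomes 0
#' and the maximum 1, removing the influence of per-subject total fiber
#' counts. The diagonal stays zero and symmetry is preserved.
#'
#' @param m Symmetric nonnegative weight matrix with zero diagonal.
#' @return Matrix of the same shape with off-diagonal values spanning
#'   exactly \[0, 1\].
#'
#' @details A constant off-diagonal matrix admits no affine rescaling to
#'   \[0, 1\] and raises an error rather than silently returning a
#'   degenerate graph.
#'
#' @examples
#' m <- matrix(c(0, 5, 10, 5, 0, 0, 10, 0, 0), 3, 3)
#' minmax_normalize(m)
#' @export
minmax_normalize <- function(m) {
  check_connectivity(m)
  off <- upper.tri(m)
  rng <- range(m[off])
  if (rng[1] == rng[2])
    stop("degenerate input: constant off-diagonal weights, no scale exists",
         call. = FALSE)
  out <- (m - rng[1]) / (rng[2] - rng[1])
  out[!off & !lower.tri(m)] <- 0  # diagonal back to 0
  out
}

#' Retain only the strongest fraction of possible edges
#'
#' Keeps exactly `k = floor(s * n * (n - 1) / 2)` off-diagonal edges with
#' the largest weights and zeroes the rest, so every subject's graph ends
#' up with the same number of connections. Ties at the cutoff weight are
#' resolved deterministically by (lower node index, lower partner index).
#'
#' @param m Symmetric nonnegative weight matrix with zero diagonal
#'   (typically normalized first).
#' @param s Sparsity: fraction of all possible node pairs to retain, in
#'   (0, 1]. Default 0.25.
#' @param basis Whether `s` refers to all `n(n-1)/2` possible node pairs
#'   (`"possible"`, the default convention) or to the observed nonzero
#'   edges (`"nonzero"`).
#' @return Thresholded weight matrix, symmetric, zero diagonal.
#' @examples
#' m <- minmax_normalize(matrix(runif(16 * 16), 16, 16) |>
#'   (\(x) {x <- x + t(x); diag(x) <- 0; x})())
#' sum(sparsity_threshold(m, 0.25)[upper.tri(m)] > 0)
#' floor(0.25 * 16 * 15 / 2)
#' @export
sparsity_threshold <- function(m, s = 0.25, basis = c("possible", "nonzero")) {
  basis <- match.arg(basis)
  check_connectivity(m)
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s <= 0 || s > 1)
    stop("sparsity 's' must be a single value in (0, 1]", call. = FALSE)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  n_basis <- if (basis == "possible") upper_pairs(n) else sum(w > 0)
  k <- floor(s * n_basis)
  # strongest k edges; ties broken by (row, col) ascending
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  out[cbind(ut[keep, 1], ut[keep, 2])] <- w[keep]
  out <- out + t(out)
  out
}

#' Binarize a thresholded connectivity matrix
#'
#' Sets every nonzero remaining edge weight to 1, yielding an
#' undirected, binarized graph.
#'
#' @param m Symmetric nonnegative weight matrix with zero diagonal.
#' @return A `binary_graph` object: a list with `adjacency` (0/1
#'   symmetric matrix, zero diagonal), `density` (realized fraction of
#'   possible edges), `n_edges`, and `labels` (node labels, if any).
#' @examples
#' g <- binarize(matrix(c(0, 2, 2, 0), 2, 2))
#' g$n_edges
#' @export
binarize <- function(m) {
  check_connectivity(m)
  a <- (m > 0) * 1
  n <- nrow(a)
  n_edges <- sum(a[upper.tri(a)])
  structure(
    list(
      adjacency = a,
      density = if (n > 1) n_edges / upper_pairs(n) else 0,
      n_edges = n_edges,
      labels = rownames(m)
    ),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binarized undirected graph: %d nodes, %d edges (density %.4f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

#' Preprocess a weighted connectivity matrix into a binary graph
#'
#' Composition of [minmax_normalize()], [sparsity_threshold()] and
#' [binarize()], in that order. The result is invariant to any positive
#' affine rescaling of the raw fiber counts.
#'
#' @inheritParams sparsity_threshold
#' @return A `binary_graph` (see [binarize()]) with density at most `s`.
#' @examples
#' w <- matrix(rpois(10 * 10, 20), 10, 10)
#' w <- w + t(w); diag(w) <- 0
#' preprocess(w, s = 0.25)
#' @export
preprocess <- function(m, s = 0.25, basis = c("possible", "nonzero")) {
  binarize(sparsity_threshold(minmax_normalize(m), s = s, basis = basis))
}
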