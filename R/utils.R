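# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL leaves the
# global stream untouched (and consumes from it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive `n` reproducible sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Accept either a binary_graph or a plain adjacency matrix.
as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) return(g$adjacency)
  if (is.matrix(g)) {
    storage.mode(g) <- "double"
    return(g)
  }
  stop("expected a 'binary_graph' or an adjacency matrix", call. = FALSE)
}

# Validate a weighted connectivity matrix: square, symmetric,
# nonnegative, finite, zero diagonal.
check_connectivity <- function(m, what = "connectivity matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (!all(is.finite(m)))
    stop(what, " must be finite", call. = FALSE)
  if (any(m < 0))
    stop(what, " must be nonnegative", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10, check.attributes = FALSE)))
    stop(what, " must be symmetric", call. = FALSE)
  if (any(diag(m) != 0))
    stop(what, " must have a zero diagonal", call. = FALSE)
  invisible(m)
}

# Signal that a metric is undefined for this graph: NA plus a
# condition-classed warning, so callers can record missingness.
undefined_metric <- function(metric, reason) {
  warning(warningCondition(
    sprintf("%s undefined: %s", metric, reason),
    class = "undefined_metric"
  ))
  NA_real_
}

upper_pairs <- function(n) n * (n - 1) / 2
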