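# Permutation-based group inference: two-sample permutation t-tests,
# Benjamini-Hochberg FDR control, univariate metric comparisons,
# regional degree-centrality comparisons, and clinical correlations.

# Pooled- or Welch-variance two-sample t statistic and p-value,
# vectorized over columns of a value matrix split by a fixed group size.
two_sample_t <- function(sum1, sumsq1, n1, total, totalsq, n,
                         var_equal = TRUE) {
  n2 <- n - n1
  sum2 <- total - sum1
  sumsq2 <- totalsq - sumsq1
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  ss1 <- pmax(0, sumsq1 - n1 * m1^2)
  ss2 <- pmax(0, sumsq2 - n2 * m2^2)
  if (var_equal) {
    sp2 <- (ss1 + ss2) / (n - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n - 2
  } else {
    v1 <- ss1 / (n1 - 1)
    v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, p = p, df = df)
}

#' Permutation two-sample t-test
#'
#' Computes the classical two-sample two-tailed t-test on the observed
#' grouping, then compares it against `n_perm` random shuffles of the
#' group labels: the permutation p-value is the fraction of shuffles
#' whose t-test p-value is at most the observed one. The default
#' estimator adds one to numerator and denominator so p can never be
#' exactly zero; `estimator = "raw"` gives the plain proportion.
#'
#' @param x,y Numeric value vectors for the two groups (each length
#'   >= 2).
#' @param n_perm Number of label shuffles (default 100000).
#' @param seed Optional integer seed; identical seeds give identical
#'   p-values.
#' @param var_equal Pooled-variance t-test (default TRUE); FALSE for
#'   Welch.
#' @param estimator `"add_one"` (default) or `"raw"`.
#' @return Object of class `permutation_test`: observed `t`, parametric
#'   `p_parametric`, permutation `p`, `n_perm`, `seed`.
#' @examples
#' set.seed(1)
#' permutation_t(rnorm(10), rnorm(10, 3), n_perm = 999, seed = 7)$p
#' @export
permutation_t <- function(x, y, n_perm = 100000, seed = NULL,
                          var_equal = TRUE,
                          estimator = c("add_one", "raw")) {
  estimator <- match.arg(estimator)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(c(x, y))))
  z <- c(x, y)
  n1 <- length(x); n <- length(z)
  if (stats::var(z) == 0) {
    warning("zero pooled variance; t statistic undefined", call. = FALSE)
    return(structure(list(t = NA_real_, p_parametric = NA_real_,
                          p = NA_real_, n_perm = n_perm, seed = seed),
                     class = "permutation_test"))
  }
  total <- sum(z); totalsq <- sum(z^2)
  obs <- two_sample_t(sum(x), sum(x^2), n1, total, totalsq, n, var_equal)
  perm <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                  integer(n1))
    zi <- matrix(z[idx], nrow = n1)
    two_sample_t(colSums(zi), colSums(zi^2), n1, total, totalsq, n,
                 var_equal)
  })
  perm_p <- perm$p
  perm_p[!is.finite(perm_p)] <- 1  # degenerate shuffles can't beat obs
  hits <- sum(perm_p <= obs$p)
  p_out <- if (estimator == "add_one") (hits + 1) / (n_perm + 1)
           else hits / n_perm
  structure(list(t = obs$t, p_parametric = obs$p, p = p_out,
                 n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation two-sample t-test: t = %.3f, p = %.4g (%d shuffles)\n",
              x$t, x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure: sort the p-values ascending, find the largest
#' rank i with `p(i) <= (i / m) * q`, and flag all hypotheses at ranks
#' up to i.
#'
#' @param pvals Numeric p-values in \[0, 1\] (`NA` allowed, never
#'   flagged).
#' @param q Target false discovery rate (default 0.05).
#' @return Logical flags aligned with `pvals`.
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.8))
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), q > 0, q < 1)
  adj <- stats::p.adjust(pvals, method = "BH")
  flags <- adj <= q
  flags[is.na(flags)] <- FALSE
  flags
}

#' Univariate permutation comparisons of all global graph metrics
#'
#' One permutation t-test per metric between the two groups, with
#' Benjamini-Hochberg FDR control across the nine tests.
#'
#' @param features Feature table (data frame from
#'   [compute_feature_table()] or a matrix with the nine metric
#'   columns).
#' @param y Group labels, -1 (patient) / +1 (control), one per row.
#' @param n_perm Shuffles per test (default 100000).
#' @param seed Optional master seed; per-metric sub-seeds are derived.
#' @param q FDR level (default 0.05).
#' @return Data frame with one row per metric: group means/SDs
#'   (`ctl_*` for +1, `mdd_*` for -1), `t`, permutation `p`, and the
#'   FDR `significant` flag.
#' @export
univariate_metric_tests <- function(features, y, n_perm = 100000,
                                    seed = NULL, q = 0.05) {
  y <- check_labels(y)
  cols <- intersect(global_metric_names(), colnames(features))
  if (length(cols) == 0)
    cols <- colnames(features)[vapply(as.data.frame(features), is.numeric,
                                      logical(1))]
  seeds <- derive_seeds(seed, length(cols))
  rows <- lapply(seq_along(cols), function(j) {
    v <- as.numeric(features[[cols[j]]])
    ok <- is.finite(v)
    pt <- if (sum(ok & y == -1) >= 2 && sum(ok & y == 1) >= 2) {
      suppressWarnings(
        permutation_t(v[ok & y == -1], v[ok & y == 1],
                      n_perm = n_perm, seed = seeds[[j]]))
    } else list(t = NA_real_, p = NA_real_)
    data.frame(metric = cols[j],
               ctl_mean = mean(v[y == 1], na.rm = TRUE),
               ctl_sd = stats::sd(v[y == 1], na.rm = TRUE),
               mdd_mean = mean(v[y == -1], na.rm = TRUE),
               mdd_sd = stats::sd(v[y == -1], na.rm = TRUE),
               t = pt$t, p = pt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p, q)
  out
}

#' Regional degree-centrality group comparison
#'
#' Compares the binarized degree of every region between groups with
#' permutation t-tests (one test per region) and controls the false
#' discovery rate across regions at level `q`.
#'
#' @param graphs Named list of preprocessed `binary_graph` objects, one
#'   per subject.
#' @param y Group labels, -1 (patient) / +1 (control).
#' @param n_perm Shuffles per region (default 100000).
#' @param seed Optional master seed.
#' @param q FDR level (default 0.05).
#' @return Data frame with one row per region, atlas-aligned:
#'   `region`, `ctl_mean`, `ctl_sd`, `mdd_mean`, `mdd_sd`, `p`,
#'   `significant`.
#' @export
regional_degree_tests <- function(graphs, y, n_perm = 100000,
                                  seed = NULL, q = 0.05) {
  y <- check_labels(y)
  stopifnot(length(graphs) == length(y))
  deg <- t(vapply(graphs, degree_centrality,
                  numeric(nrow(as_adjacency(graphs[[1]])))))
  n_regions <- ncol(deg)
  labels <- colnames(deg)
  if (is.null(labels)) labels <- node_labels(n_regions)
  seeds <- derive_seeds(seed, n_regions)
  p <- numeric(n_regions)
  for (r in seq_len(n_regions)) {
    p[r] <- suppressWarnings(
      permutation_t(deg[y == -1, r], deg[y == 1, r],
                    n_perm = n_perm, seed = seeds[[r]])$p)
  }
  data.frame(
    region = labels,
    ctl_mean = colMeans(deg[y == 1, , drop = FALSE]),
    ctl_sd = apply(deg[y == 1, , drop = FALSE], 2, stats::sd),
    mdd_mean = colMeans(deg[y == -1, , drop = FALSE]),
    mdd_sd = apply(deg[y == -1, , drop = FALSE], 2, stats::sd),
    p = p,
    significant = fdr_bh(p, q),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Pearson correlations between a metric and clinical covariates
#'
#' One correlation per covariate column, dropping incomplete pairs.
#'
#' @param values Numeric vector (e.g. one metric's per-subject values).
#' @param covariates Data frame of numeric covariates, same row order.
#' @return Data frame with `covariate`, `n` (complete pairs), `r`, `p`.
#'   Covariates with fewer than 3 complete pairs or zero variance give
#'   `NA` with a warning.
#' @export
clinical_correlations <- function(values, covariates) {
  values <- as.numeric(values)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(values))
  rows <- lapply(names(covariates), function(nm) {
    cv <- as.numeric(covariates[[nm]])
    ok <- is.finite(values) & is.finite(cv)
    if (sum(ok) < 3 || stats::sd(values[ok]) == 0 || stats::sd(cv[ok]) == 0) {
      warning(sprintf("correlation with '%s' undefined (n < 3 or zero variance)",
                      nm), call. = FALSE)
      return(data.frame(covariate = nm, n = sum(ok),
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(values[ok], cv[ok], method = "pearson")
    data.frame(covariate = nm, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
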