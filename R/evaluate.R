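# Exhaustive feature-subset evaluation: one cross-validated SVM per
# nonempty subset of the nine graph-metric features, per-subset exact
# sign tests, an across-subset binomial test, and per-metric accuracy
# aggregation.

#' Enumerate all nonempty feature subsets
#'
#' @param d Number of features.
#' @return Logical matrix with `2^d - 1` rows (one mask per subset) in
#'   deterministic binary-counter order: row j selects the features
#'   whose bit is set in j.
#' @examples
#' nrow(enumerate_subsets(9))  # 511
#' @export
enumerate_subsets <- function(d) {
  stopifnot(d >= 1)
  n_sets <- 2L^d - 1L
  masks <- matrix(FALSE, n_sets, d)
  for (bit in seq_len(d))
    masks[, bit] <- bitwAnd(seq_len(n_sets), bitwShiftL(1L, bit - 1L)) > 0L
  masks
}

#' Exact two-sided sign test p-value
#'
#' Probability, under chance classification (success probability 0.5),
#' of a fold-success count at least as extreme as `k` out of `n`:
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param k Number of correctly classified folds.
#' @param n Total folds.
#' @return Exact two-sided p-value.
#' @examples
#' sign_test_p(22, 32)  # 0.0501
#' @export
sign_test_p <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Smallest fold-success count reaching sign-test significance
#'
#' Finds the smallest `k` whose two-sided sign-test p-value is at most
#' `alpha`. By default the p-value is rounded to 2 decimals first: at
#' `n = 32` the exact p at `k = 22` is 0.0501, so the conventional
#' 22-of-32 criterion is reached only under rounding; pass
#' `round_digits = NULL` for the strict unrounded threshold (23 of 32).
#'
#' @param n Number of folds.
#' @param alpha Significance level (default 0.05).
#' @param round_digits Decimal places to round the p-value to before
#'   comparison, or `NULL` for no rounding. Default 2.
#' @return The smallest significant success count.
#' @examples
#' sign_test_threshold(32)                       # 22
#' sign_test_threshold(32, round_digits = NULL)  # 23
#' @export
sign_test_threshold <- function(n, alpha = 0.05, round_digits = 2) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  for (k in seq(ceiling(n / 2), n)) {
    p <- sign_test_p(k, n)
    if (!is.null(round_digits)) p <- round(p, round_digits)
    if (p <= alpha) return(k)
  }
  n + 1L  # no attainable count is significant
}

#' Exhaustively evaluate every feature subset with cross-validated SVMs
#'
#' Runs one leave-one-out cross-validation per nonempty subset of the
#' feature columns (511 subsets for 9 features), flags each subset whose
#' fold-success count reaches the sign-test threshold, and tests the
#' total number of significant subsets against the chance expectation
#' that only `alpha` of them would reach significance (two-sided
#' binomial test).
#'
#' @inheritParams loocv
#' @param alpha Per-subset sign-test level and across-subset chance
#'   rate (default 0.05).
#' @param round_digits Sign-test rounding policy, see
#'   [sign_test_threshold()].
#' @return An object of class `subset_evaluation`: a data frame
#'   `evaluations` (mask bitstring, n_correct, accuracy, significant),
#'   the `threshold`, `significant_count`, the across-set `binomial_p`,
#'   and bookkeeping fields.
#' @export
run_exhaustive <- function(x, y, scale = TRUE, alpha = 0.05,
                           round_digits = 2, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- check_labels(y)
  d <- ncol(x)
  n <- nrow(x)
  masks <- enumerate_subsets(d)
  threshold <- sign_test_threshold(n, alpha, round_digits)
  n_sets <- nrow(masks)
  n_correct <- integer(n_sets)
  for (j in seq_len(n_sets)) {
    cv <- loocv(x, y, feature_mask = masks[j, ], scale = scale,
                tol = tol, max_iter = max_iter)
    n_correct[j] <- cv$n_correct
  }
  evaluations <- data.frame(
    mask = apply(masks, 1, function(m) paste(as.integer(m), collapse = "")),
    n_correct = n_correct,
    accuracy = n_correct / n,
    significant = n_correct >= threshold,
    stringsAsFactors = FALSE
  )
  sig_count <- sum(evaluations$significant)
  structure(list(
    evaluations = evaluations,
    masks = masks,
    feature_names = colnames(x),
    n_folds = n,
    threshold = threshold,
    alpha = alpha,
    significant_count = sig_count,
    binomial_p = stats::binom.test(sig_count, n_sets, alpha)$p.value
  ), class = "subset_evaluation")
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat(sprintf(
    "Exhaustive subset evaluation: %d subsets, %d significant (threshold %d/%d folds)\n",
    nrow(x$evaluations), x$significant_count, x$threshold, x$n_folds))
  cat(sprintf("  across-set binomial test vs %.0f%% chance: p = %.3g\n",
              100 * x$alpha, x$binomial_p))
  invisible(x)
}

#' Histogram of subset accuracies
#' @param x A `subset_evaluation`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.subset_evaluation <- function(x, ...) {
  graphics::hist(x$evaluations$accuracy,
                 main = "Cross-validated accuracy over feature subsets",
                 xlab = "accuracy", ...)
  graphics::abline(v = x$threshold / x$n_folds, lty = 2)
  invisible(x)
}

#' Aggregate subset accuracies by the metrics they contain
#'
#' For each feature, summarizes the cross-validated accuracies of all
#' `2^(d-1)` subsets containing it: mean, SD, and the count of subsets
#' reaching sign-test significance.
#'
#' @param evals A complete `subset_evaluation` from [run_exhaustive()].
#' @return Data frame with one row per feature: `metric`,
#'   `mean_accuracy`, `sd_accuracy`, `n_subsets`, `n_significant`.
#' @export
aggregate_by_metric <- function(evals) {
  stopifnot(inherits(evals, "subset_evaluation"))
  masks <- evals$masks
  d <- ncol(masks)
  if (nrow(masks) != 2^d - 1)
    stop("incomplete subset evaluation: expected all 2^d - 1 subsets",
         call. = FALSE)
  nm <- evals$feature_names
  if (is.null(nm)) nm <- paste0("feature_", seq_len(d))
  out <- lapply(seq_len(d), function(j) {
    sel <- masks[, j]
    acc <- evals$evaluations$accuracy[sel]
    data.frame(metric = nm[j],
               mean_accuracy = mean(acc),
               sd_accuracy = stats::sd(acc),
               n_subsets = sum(sel),
               n_significant = sum(evals$evaluations$significant[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation comparison of two metrics' subset accuracies
#'
#' Two-sample permutation t-test between the accuracy lists of subsets
#' containing one metric vs another; delegates to [permutation_t()].
#'
#' @param a,b Numeric accuracy vectors.
#' @param n_perm Number of label shuffles.
#' @param seed Optional seed.
#' @return The permutation p-value.
#' @export
compare_metric_accuracies <- function(a, b, n_perm = 10000, seed = NULL) {
  permutation_t(a, b, n_perm = n_perm, seed = seed)$p
}

#' One-sample t-test of subset accuracies against chance
#'
#' Tests whether a metric's aggregate accuracies exceed the 50% chance
#' level of a binary decision.
#'
#' @param accs Numeric vector of accuracies (length >= 2).
#' @return List with `t`, `df` (`length(accs) - 1`) and two-sided `p`.
#'   With zero variance in `accs` the statistic is undefined and `t`/`p`
#'   are `NA` with a warning.
#' @export
accuracy_vs_chance <- function(accs) {
  stopifnot(length(accs) >= 2)
  if (stats::sd(accs) == 0) {
    warning("zero variance in accuracies; t statistic undefined",
            call. = FALSE)
    return(list(t = NA_real_, df = length(accs) - 1, p = NA_real_))
  }
  ht <- stats::t.test(accs, mu = 0.5)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
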