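# End-to-end orchestration: simulate or load a cohort, preprocess,
# compute features, run univariate and multivariate analyses, and the
# regional comparison, writing every stage's table plus a
# machine-readable summary.

#' Configuration for a full pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or
#'   `"matrix-directory"` (read one written by [write_cohort()]).
#' @param cohort A [cohort_config()] (synthetic mode); its seed is
#'   overridden by `seed` so a run is a pure function of this
#'   configuration.
#' @param input_dir Directory of matrices (matrix-directory mode).
#' @param sparsity Sparsity threshold (default 0.25).
#' @param n_null Null graphs for small-worldness (default 10).
#' @param n_iter Modularity optimization runs (default 10).
#' @param n_perm Label shuffles per permutation test (default 100000).
#' @param alpha Sign-test / binomial significance level (default 0.05).
#' @param q FDR level (default 0.05).
#' @param scale Standardize features inside cross-validation folds
#'   (default TRUE).
#' @param seed Master seed; all stochastic stages derive sub-seeds from
#'   it.
#' @param out_dir Optional output directory; when given, every stage's
#'   CSV and a `summary.json` are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "matrix-directory"),
                       cohort = cohort_config(), input_dir = NULL,
                       sparsity = 0.25, n_null = 10, n_iter = 10,
                       n_perm = 100000, alpha = 0.05, q = 0.05,
                       scale = TRUE, seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "matrix-directory" && is.null(input_dir))
    stop("matrix-directory mode requires 'input_dir'", call. = FALSE)
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 sparsity = sparsity, n_null = n_null, n_iter = n_iter,
                 n_perm = n_perm, alpha = alpha, q = q, scale = scale,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full connectome classification pipeline
#'
#' Stages, in order: cohort (simulated or loaded), preprocessing to
#' fixed-density binary graphs, the nine-metric feature table,
#' univariate permutation tests with FDR, full-model leave-one-out SVM
#' with feature-weight ranks, exhaustive 511-subset evaluation with
#' sign and binomial tests, per-metric accuracy aggregation, and the
#' regional degree-centrality comparison. A fixed master seed makes the
#' whole run deterministic.
#'
#' @param config A [run_config()].
#' @return An object of class `connectome_run` containing the cohort,
#'   `features`, `univariate`, `cv_full` (a `cwsvm_cv`), `subsets`
#'   (a `subset_evaluation`), `aggregates`, `regional`, and `summary`
#'   (the list serialized to `summary.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4)

  cohort <- if (config$mode == "synthetic") {
    cc <- config$cohort
    cc$seed <- seeds[[1]]
    generate_cohort(cc)
  } else {
    read_cohort(config$input_dir)
  }

  graphs <- lapply(cohort$matrices, preprocess, s = config$sparsity)
  features <- compute_feature_table(graphs, n_iter = config$n_iter,
                                    n_null = config$n_null,
                                    seed = seeds[[2]])
  univariate <- univariate_metric_tests(features, cohort$y,
                                        n_perm = config$n_perm,
                                        seed = seeds[[3]], q = config$q)
  xmat <- as.matrix(features[, global_metric_names()])
  cv_full <- loocv(xmat, cohort$y, scale = config$scale)
  subsets <- run_exhaustive(xmat, cohort$y, scale = config$scale,
                            alpha = config$alpha)
  aggregates <- aggregate_by_metric(subsets)
  aggregates$mean_rank_full_model <-
    cv_full$mean_ranks[aggregates$metric]
  regional <- regional_degree_tests(graphs, cohort$y,
                                    n_perm = config$n_perm,
                                    seed = seeds[[4]], q = config$q)

  summary_list <- list(
    seed = config$seed,
    n_subjects = length(cohort$y),
    n_control = sum(cohort$y == 1),
    n_mdd = sum(cohort$y == -1),
    sparsity = config$sparsity,
    edges_per_graph = graphs[[1]]$n_edges,
    full_model = list(
      accuracy = cv_full$accuracy,
      sensitivity = cv_full$sensitivity,
      specificity = cv_full$specificity,
      n_correct = cv_full$n_correct,
      sign_test_p = sign_test_p(cv_full$n_correct, cv_full$n_folds),
      mean_feature_ranks = as.list(cv_full$mean_ranks)
    ),
    subset_evaluation = list(
      n_subsets = nrow(subsets$evaluations),
      threshold = subsets$threshold,
      significant_count = subsets$significant_count,
      binomial_p = subsets$binomial_p
    ),
    univariate_significant = sum(univariate$significant),
    regional_significant = sum(regional$significant),
    regional_significant_regions =
      regional$region[regional$significant]
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(config$out_dir, name),
                       row.names = FALSE)
    wr(features, "features.csv")
    wr(univariate, "univariate.csv")
    wr(data.frame(subject_id = features$subject_id,
                  truth = cv_full$truth,
                  predicted = cv_full$predicted), "cv_full_model.csv")
    wr(subsets$evaluations, "subsets.csv")
    wr(aggregates, "metric_aggregates.csv")
    wr(regional, "regional.csv")
    jsonlite::write_json(summary_list,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(cohort = cohort, graphs = graphs, features = features,
                 univariate = univariate, cv_full = cv_full,
                 subsets = subsets, aggregates = aggregates,
                 regional = regional, summary = summary_list,
                 config = config),
            class = "connectome_run")
}

#' @export
print.connectome_run <- function(x, ...) {
  s <- x$summary
  cat("Connectome classification run\n")
  cat(sprintf("  cohort          : %d controls + %d patients, %d edges/graph\n",
              s$n_control, s$n_mdd, s$edges_per_graph))
  cat(sprintf("  full model      : %.2f%% accuracy (%d/%d; sign test p = %.4f)\n",
              100 * s$full_model$accuracy, s$full_model$n_correct,
              s$n_subjects, s$full_model$sign_test_p))
  cat(sprintf("  subsets         : %d of %d significant (binomial p = %.3g)\n",
              s$subset_evaluation$significant_count,
              s$subset_evaluation$n_subsets,
              s$subset_evaluation$binomial_p))
  cat(sprintf("  univariate FDR  : %d of 9 metrics significant\n",
              s$univariate_significant))
  cat(sprintf("  regional FDR    : %d regions significant\n",
              s$regional_significant))
  invisible(x)
}
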