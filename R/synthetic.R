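# Synthetic two-group cohorts of fiber-count connectivity matrices with
# known planted effects. A single degree-heterogeneous weighted template
# (Chung-Lu-style skeleton with log-normal weights) is shared by all
# subjects; group effects perturb the template before subject-level
# multiplicative log-normal noise is applied, so every effect size has a
# single interpretable unit (template weight mass).

#' Configuration for a synthetic cohort
#'
#' @param n_control,n_mdd Group sizes (each >= 2). Defaults 18 and 14,
#'   the cohort sizes this analysis design targets.
#' @param n_nodes Number of network nodes (default 68; the bilateral
#'   cortical atlas is attached when `n_nodes == 68`).
#' @param base_density Fraction of possible edges present in the
#'   template skeleton, in (0, 1]. Default 0.40, comfortably above the
#'   0.25 sparsity threshold applied downstream.
#' @param weight_scale Median fiber count per present template edge
#'   (default 50).
#' @param subject_noise_sd SD of the multiplicative log-normal
#'   subject-level noise on edge weights (default 0.25).
#' @param nodal_effect Optional data frame with columns `region` (index
#'   or label) and `effect` (signed fractional change of template
#'   weight mass on edges incident to that region, applied to the MDD
#'   group; +0.4 means +40%).
#' @param global_effect Fraction of MDD-template edges randomly rewired
#'   (degree-destroying), perturbing global topology of one group.
#'   Default 0.
#' @param covariate_coupling Coupling strength between a subject's
#'   overall noise level and the BDI-II covariate (default 0, no
#'   coupling; nonzero values support correlation power tests).
#' @param seed Integer seed; the cohort is a pure function of this
#'   configuration including the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 18, n_mdd = 14, n_nodes = 68,
                          base_density = 0.4, weight_scale = 50,
                          subject_noise_sd = 0.25, nodal_effect = NULL,
                          global_effect = 0, covariate_coupling = 0,
                          seed = 1) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok))
      stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
           call. = FALSE)
  }
  chk(is.numeric(n_control) && n_control >= 2, "n_control", "must be >= 2")
  chk(is.numeric(n_mdd) && n_mdd >= 2, "n_mdd", "must be >= 2")
  chk(is.numeric(n_nodes) && n_nodes >= 4, "n_nodes", "must be >= 4")
  chk(is.numeric(base_density) && base_density > 0 && base_density <= 1,
      "base_density", "must be in (0, 1]")
  chk(is.numeric(weight_scale) && weight_scale > 0, "weight_scale",
      "must be positive")
  chk(is.numeric(subject_noise_sd) && subject_noise_sd >= 0,
      "subject_noise_sd", "must be nonnegative")
  chk(is.numeric(global_effect) && global_effect >= 0 && global_effect < 1,
      "global_effect", "must be in [0, 1)")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be a finite number")
  if (!is.null(nodal_effect)) {
    chk(is.data.frame(nodal_effect) &&
          all(c("region", "effect") %in% names(nodal_effect)),
        "nodal_effect", "must be a data frame with columns region, effect")
    chk(all(is.finite(nodal_effect$effect)) &&
          all(nodal_effect$effect > -1),
        "nodal_effect", "effect sizes must be finite and > -1")
  }
  structure(list(
    n_control = as.integer(n_control), n_mdd = as.integer(n_mdd),
    n_nodes = as.integer(n_nodes), base_density = base_density,
    weight_scale = weight_scale, subject_noise_sd = subject_noise_sd,
    nodal_effect = nodal_effect, global_effect = global_effect,
    covariate_coupling = covariate_coupling, seed = as.integer(seed)
  ), class = "cohort_config")
}

resolve_regions <- function(region, labels) {
  if (is.numeric(region)) {
    idx <- as.integer(region)
    if (any(idx < 1 | idx > length(labels)))
      stop("invalid cohort configuration: field 'nodal_effect' region index out of range",
           call. = FALSE)
    return(idx)
  }
  idx <- match(region, labels)
  if (anyNA(idx))
    stop("invalid cohort configuration: field 'nodal_effect' has unknown region label",
         call. = FALSE)
  idx
}

#' Generate a synthetic two-group cohort of connectivity matrices
#'
#' Builds a shared weighted template (degree-heterogeneous skeleton,
#' log-normal weights), applies the configured group effects to the MDD
#' copy of the template, then draws each subject's matrix by
#' multiplicative log-normal noise on the group template. Covariates
#' are drawn uniformly within clinically realistic ranges (BDI-II 22-43
#' / GAF 35-60 / onset age 3-26 / years since onset 3-39 for the MDD
#' group; BDI-II 0-11 / GAF 75-99 for controls, onset fields absent).
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: named list `matrices` (one
#'   symmetric nonnegative zero-diagonal matrix per subject), label
#'   vector `y` (+1 control, -1 MDD), data frame `covariates`, `labels`
#'   (node labels) and the resolved `config`. Identical configurations
#'   (including seed) yield bit-identical cohorts.
#' @examples
#' ch <- generate_cohort(cohort_config(n_control = 4, n_mdd = 4,
#'                                     n_nodes = 20, seed = 7))
#' length(ch$matrices); table(ch$y)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_nodes
  labels <- node_labels(n)
  with_seed(config$seed, {
    # template skeleton: Chung-Lu style heterogeneous expected degrees
    attract <- stats::rlnorm(n, 0, 0.6)
    p_edge <- config$base_density * outer(attract, attract) / mean(attract)^2
    p_edge <- pmin(p_edge, 0.95)
    ut <- upper.tri(p_edge)
    skel <- matrix(0, n, n)
    skel[ut] <- (stats::runif(sum(ut)) < p_edge[ut]) * 1
    skel <- skel + t(skel)
    edge_idx <- which(ut & skel > 0)
    m_edges <- length(edge_idx)
    if (m_edges < 2)
      stop("template skeleton degenerate; increase base_density or n_nodes",
           call. = FALSE)
    w_ctl <- matrix(0, n, n)
    w_ctl[edge_idx] <- stats::rlnorm(m_edges, log(config$weight_scale), 1)
    w_ctl <- w_ctl + t(w_ctl)
    rownames(w_ctl) <- colnames(w_ctl) <- labels

    # MDD template: global rewiring, then nodal weight-mass shifts
    w_mdd <- w_ctl
    if (config$global_effect > 0) {
      k <- round(config$global_effect * m_edges)
      if (k > 0) {
        non_edges <- which(ut & skel == 0)
        k <- min(k, length(non_edges), m_edges)
        drop_idx <- sample(edge_idx, k)
        add_idx <- sample(non_edges, k)
        moved <- w_mdd[drop_idx]
        w_mdd[drop_idx] <- 0
        w_mdd[add_idx] <- moved
        low <- lower.tri(w_mdd)
        w_mdd[low] <- t(w_mdd)[low]
      }
    }
    if (!is.null(config$nodal_effect)) {
      idx <- resolve_regions(config$nodal_effect$region, labels)
      for (j in seq_along(idx)) {
        r <- idx[j]
        w_mdd[r, ] <- w_mdd[r, ] * (1 + config$nodal_effect$effect[j])
        w_mdd[, r] <- w_mdd[r, ]
      }
    }

    ids <- c(sprintf("ctl_%02d", seq_len(config$n_control)),
             sprintf("mdd_%02d", seq_len(config$n_mdd)))
    y <- c(rep(1, config$n_control), rep(-1, config$n_mdd))
    noise_level <- numeric(length(y))
    matrices <- lapply(seq_along(y), function(i) {
      tmpl <- if (y[i] == 1) w_ctl else w_mdd
      eps <- matrix(0, n, n)
      eps[ut] <- stats::rnorm(sum(ut), 0, config$subject_noise_sd)
      eps <- eps + t(eps)
      noise_level[i] <<- mean(eps[ut][tmpl[ut] > 0])
      out <- tmpl * exp(eps)
      rownames(out) <- colnames(out) <- labels
      out
    })
    names(matrices) <- ids

    is_mdd <- y == -1
    covariates <- data.frame(
      subject_id = ids,
      bdi_ii = ifelse(is_mdd, stats::runif(length(y), 22, 43),
                      stats::runif(length(y), 0, 11)),
      gaf = ifelse(is_mdd, stats::runif(length(y), 35, 60),
                   stats::runif(length(y), 75, 99)),
      age_onset = ifelse(is_mdd, stats::runif(length(y), 3, 26), NA_real_),
      years_since_onset = ifelse(is_mdd, stats::runif(length(y), 3, 39),
                                 NA_real_),
      stringsAsFactors = FALSE
    )
    if (config$covariate_coupling != 0 && stats::sd(noise_level) > 0) {
      covariates$bdi_ii <- covariates$bdi_ii +
        config$covariate_coupling * scale(noise_level)[, 1]
    }
    structure(list(matrices = matrices, y = y, covariates = covariates,
                   labels = labels, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic connectome cohort: %d controls + %d patients, %d nodes (seed %d)\n",
    sum(x$y == 1), sum(x$y == -1), x$config$n_nodes, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk as delimited text
#'
#' One tab-delimited matrix file per subject (with region labels as
#' header row and column) plus a `manifest.csv` listing subject id,
#' group and clinical covariates.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$matrices)) {
    utils::write.table(cohort$matrices[[id]],
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  manifest <- cbind(cohort$covariates[, "subject_id", drop = FALSE],
                    group = cohort$y,
                    cohort$covariates[, -1, drop = FALSE])
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and one `<id>.tsv`
#'   matrix per subject.
#' @return A `cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  matrices <- lapply(manifest$subject_id, function(id) {
    path <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(path))
      stop(sprintf("matrix file missing for subject '%s': %s", id, path),
           call. = FALSE)
    m <- as.matrix(utils::read.delim(path, row.names = 1,
                                     check.names = FALSE))
    colnames(m) <- rownames(m)
    check_connectivity(m, what = sprintf("matrix for subject '%s'", id))
    m
  })
  names(matrices) <- manifest$subject_id
  covariates <- manifest[, setdiff(names(manifest), "group"), drop = FALSE]
  structure(list(matrices = matrices, y = manifest$group,
                 covariates = covariates,
                 labels = rownames(matrices[[1]]), config = NULL),
            class = "cohort")
}
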