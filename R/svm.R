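# Class-weighted squared-slack (L2) linear support vector machine,
# fitted by a damped Newton method on the convex piecewise-quadratic
# primal objective
#   0.5 <w, w> + sum_i D_i * max(0, 1 - y_i (<w, x_i> + b))^2 ,
# with per-sample penalties D_i = N / (2 * N_G(i)) so each class
# contributes equal total penalty mass regardless of group size.

#' Per-sample class-balancing penalty weights
#'
#' Computes `D_i = N / (2 * N_G(i))`, where `N` is the total sample
#' count and `N_G(i)` the size of sample i's group. Summed within each
#' class, the weights equal `N / 2`, so the two classes carry equal
#' total penalty mass in the SVM objective.
#'
#' @param y Label vector with values -1 and +1 (both present).
#' @return Numeric vector of penalties, one per sample.
#' @examples
#' y <- rep(c(1, -1), c(18, 14))
#' unique(penalty_weights(y))  # 32/36 for the larger, 32/28 for the smaller
#' @export
penalty_weights <- function(y) {
  y <- check_labels(y)
  n <- length(y)
  n_pos <- sum(y == 1)
  n_neg <- n - n_pos
  ifelse(y == 1, n / (2 * n_pos), n / (2 * n_neg))
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be -1 or +1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  y
}

#' Fit a class-weighted squared-slack linear SVM
#'
#' Minimizes `0.5 ||w||^2 + sum_i D_i v_i^2` subject to
#' `y_i (<w, x_i> + b) >= 1 - v_i`, `v_i >= 0` - a squared (L2) slack
#' penalty, not the more common hinge loss - with class-balancing
#' penalties `D_i` from [penalty_weights()] unless `weights` is given.
#' The solver is a deterministic damped Newton iteration on the
#' differentiable piecewise-quadratic primal; no randomness is involved.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param y Labels, -1 / +1.
#' @param weights Optional per-sample penalties `D_i`; defaults to
#'   [penalty_weights()] of `y`.
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param max_iter Iteration budget for the Newton loop.
#' @return An object of class `cwsvm`: weight vector `w`, bias `b`,
#'   slack `v`, `objective`, KKT residuals (`kkt_stationarity`,
#'   `kkt_bias`), `iterations` and `converged`.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' fit <- cwsvm(x, c(-1, 1))
#' coef(fit)
#' @export
cwsvm <- function(x, y, weights = NULL, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- check_labels(y)
  n <- nrow(x); d <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  dd <- if (is.null(weights)) penalty_weights(y) else as.numeric(weights)
  if (any(dd <= 0)) stop("penalty weights must be positive", call. = FALSE)

  u <- cbind(x, 1) * y                  # u_i = y_i [x_i, 1]
  pmat <- diag(c(rep(1, d), 0))         # regularizes w, not b
  objective <- function(z) {
    v <- pmax(0, 1 - drop(u %*% z))
    0.5 * sum(z[seq_len(d)]^2) + sum(dd * v^2)
  }
  z <- numeric(d + 1)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    margins <- drop(u %*% z)
    act <- margins < 1
    grad <- drop(pmat %*% z)
    if (any(act))
      grad <- grad + drop(2 * crossprod(u[act, , drop = FALSE],
                                        dd[act] * (margins[act] - 1)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    hess <- pmat
    if (any(act))
      hess <- hess + 2 * crossprod(u[act, , drop = FALSE] *
                                     sqrt(dd[act])) * 1
    dir <- tryCatch(-solve(hess, grad),
                    error = function(e)
                      -solve(hess + diag(1e-10, d + 1), grad))
    # backtracking line search (full Newton step is exact once the
    # active set settles)
    f0 <- objective(z)
    step <- 1
    repeat {
      znew <- z + step * dir
      if (objective(znew) <= f0 - 1e-12 * step * sum(grad * -dir) ||
          step < 1e-12) break
      step <- step / 2
    }
    if (step < 1e-12) break
    z <- znew
  }
  if (!converged && iter > max_iter)
    stop(sprintf(
      "SVM solver did not converge in %d iterations (grad inf-norm %.3g)",
      max_iter, max(abs(grad))), call. = FALSE)

  w <- z[seq_len(d)]
  names(w) <- colnames(x)
  b <- z[d + 1]
  margins <- drop(u %*% z)
  v <- pmax(0, 1 - margins)
  # KKT stationarity: w = sum_i 2 D_i v_i y_i x_i ; sum_i 2 D_i v_i y_i = 0
  alpha <- 2 * dd * v
  r_w <- w - drop(crossprod(x, alpha * y))
  r_b <- sum(alpha * y)
  structure(list(
    w = w, b = b, v = v, objective = objective(z),
    weights = dd, y = y,
    kkt_stationarity = max(abs(r_w)), kkt_bias = abs(r_b),
    iterations = iter, converged = converged
  ), class = "cwsvm")
}

#' @export
print.cwsvm <- function(x, ...) {
  cat("Class-weighted squared-slack linear SVM\n")
  cat(sprintf("  features: %d, samples: %d, objective: %.6g\n",
              length(x$w), length(x$v), x$objective))
  cat("  w:", format(x$w, digits = 4), "\n")
  cat("  b:", format(x$b, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.cwsvm <- function(object, ...) {
  c("(bias)" = object$b, object$w)
}

#' @export
fitted.cwsvm <- function(object, ...) object$y * (1 - object$v)

#' Residuals of a fitted `cwsvm`: the slack values v_i
#' @param object A fitted `cwsvm`.
#' @param ... Unused.
#' @export
residuals.cwsvm <- function(object, ...) object$v

#' Predict group labels from a fitted `cwsvm`
#'
#' @param object A fitted `cwsvm`.
#' @param newdata Feature matrix (columns in training order).
#' @param type `"class"` for -1/+1 labels (ties at the boundary go to
#'   +1), `"decision"` for the signed distance `<w, x> + b`.
#' @param ... Unused.
#' @export
predict.cwsvm <- function(object, newdata,
                          type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$w))
  f <- drop(newdata %*% object$w) + object$b
  if (type == "decision") return(f)
  ifelse(f >= 0, 1, -1)
}

#' @export
summary.cwsvm <- function(object, ...) {
  cat("Class-weighted squared-slack linear SVM\n")
  cat(sprintf("  objective          : %.6g\n", object$objective))
  cat(sprintf("  KKT stationarity   : %.3g\n", object$kkt_stationarity))
  cat(sprintf("  KKT bias residual  : %.3g\n", object$kkt_bias))
  cat(sprintf("  active slacks      : %d of %d\n",
              sum(object$v > 0), length(object$v)))
  cat(sprintf("  Newton iterations  : %d\n", object$iterations))
  print(data.frame(feature = names(coef(object)),
                   coefficient = unname(coef(object)),
                   row.names = NULL))
  invisible(object)
}

#' Leave-one-out cross-validation of the class-weighted linear SVM
#'
#' Fits one SVM per fold, holding out each subject in turn; the held-out
#' subject never influences training, including feature standardization,
#' which is re-estimated on each fold's training subjects only.
#'
#' @param x Feature matrix, one row per subject.
#' @param y Labels, -1 (patient) / +1 (control); each class needs at
#'   least 2 members.
#' @param feature_mask Optional logical or integer selection of feature
#'   columns.
#' @param scale Standardize each feature to zero mean / unit variance
#'   using training-fold statistics (default TRUE). Features constant in
#'   a training fold are centered only.
#' @param tol,max_iter Passed to [cwsvm()].
#' @return An object of class `cwsvm_cv`: per-fold `predicted` and
#'   `truth`, `n_correct`, `accuracy`, `sensitivity` (correct fraction
#'   among y = -1), `specificity` (among y = +1), the per-fold
#'   `rank_matrix` of |w| ranks (1 = largest) and `mean_ranks`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' loocv(x, rep(c(-1, 1), each = 10))$accuracy
#' @export
loocv <- function(x, y, feature_mask = NULL, scale = TRUE,
                  tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- check_labels(y)
  if (!is.null(feature_mask)) x <- x[, feature_mask, drop = FALSE]
  n <- nrow(x); d <- ncol(x)
  if (n < 4) stop("need at least 4 subjects for LOOCV", call. = FALSE)
  if (min(sum(y == 1), sum(y == -1)) < 2)
    stop("each class needs at least 2 subjects", call. = FALSE)
  predicted <- numeric(n)
  ranks <- matrix(NA_real_, n, d,
                  dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    xte <- x[i, , drop = FALSE]
    if (scale) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    fit <- cwsvm(xtr, ytr, tol = tol, max_iter = max_iter)
    predicted[i] <- predict(fit, xte)
    ranks[i, ] <- rank(-abs(fit$w), ties.method = "average")
  }
  correct <- predicted == y
  structure(list(
    predicted = predicted, truth = y,
    n_folds = n, n_correct = sum(correct),
    accuracy = mean(correct),
    sensitivity = mean(correct[y == -1]),
    specificity = mean(correct[y == 1]),
    rank_matrix = ranks,
    mean_ranks = colMeans(ranks)
  ), class = "cwsvm_cv")
}

#' @export
print.cwsvm_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out CV: %d/%d correct (accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%)\n",
    x$n_correct, x$n_folds, 100 * x$accuracy,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Mean |w|-based feature ranks across cross-validation folds
#'
#' Ranks features within each fold by the absolute SVM weight |w|
#' (rank 1 = largest weight = most important; ties receive average
#' ranks) and averages the ranks across folds. Lower mean rank means a
#' more consistently important feature.
#'
#' @param models A list of fitted `cwsvm` objects with a common feature
#'   space, or a `cwsvm_cv` object.
#' @return Named numeric vector of mean ranks.
#' @export
feature_weight_ranks <- function(models) {
  if (inherits(models, "cwsvm_cv")) return(models$mean_ranks)
  stopifnot(is.list(models), length(models) >= 1)
  rk <- vapply(models, function(m) rank(-abs(m$w), ties.method = "average"),
               numeric(length(models[[1]]$w)))
  rk <- matrix(rk, nrow = length(models[[1]]$w))
  out <- rowMeans(rk)
  names(out) <- names(models[[1]]$w)
  out
}
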