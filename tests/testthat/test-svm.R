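test_that("penalty weights balance total class mass", {
  y <- rep(c(1, -1), c(18, 14))
  d <- penalty_weights(y)
  expect_equal(unique(d[y == 1]), 32 / 36)
  expect_equal(unique(d[y == -1]), 32 / 28)
  # each class carries total penalty mass N/2
  expect_equal(sum(d[y == 1]), 16)
  expect_equal(sum(d[y == -1]), 16)
  # balanced groups: all weights 1
  expect_equal(penalty_weights(rep(c(-1, 1), 5)), rep(1, 10))
  expect_error(penalty_weights(rep(1, 6)), "both classes")
  expect_error(penalty_weights(c(0, 1, 1, -1)), "labels")
})

test_that("the two-point problem matches its closed form", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c(-1, 1)
  # soft version, D = 1: minimize w^2/2 + 2 (1 - w)^2 -> w = 4/5, b = 0
  fit <- cwsvm(x, y)
  expect_equal(unname(fit$w), 0.8, tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  # separable limit (huge penalty): margin planes through the points
  hard <- cwsvm(x, y, weights = c(1e8, 1e8))
  expect_equal(unname(hard$w), 1, tolerance = 1e-4)
  expect_equal(hard$b, 0, tolerance = 1e-6)
})

test_that("fitted models satisfy the KKT conditions within tolerance", {
  set.seed(10)
  for (i in 1:10) {
    x <- matrix(rnorm(14 * 3), 14, 3)
    y <- sample(rep(c(-1, 1), 7))
    fit <- cwsvm(x, y)
    expect_lt(fit$kkt_stationarity, 1e-6)
    expect_lt(fit$kkt_bias, 1e-6)
    expect_true(all(fit$v >= 0))
    # constraints: y_i (w x_i + b) >= 1 - v_i
    margins <- y * (drop(x %*% fit$w) + fit$b)
    expect_true(all(margins >= 1 - fit$v - 1e-8))
  }
})

test_that("the primal Newton solution matches an interior-point QP oracle", {
  set.seed(11)
  for (i in 1:8) {
    x <- matrix(rnorm(10 * 3), 10, 3)
    y <- sample(rep(c(-1, 1), 5))
    fit <- cwsvm(x, y)
    d <- penalty_weights(y)
    # dual: min 1/2 a' (K.yy' + diag(1/2D)) a - 1'a, a >= 0, y'a = 0
    h <- (x %*% t(x)) * (y %o% y) + diag(1 / (2 * d))
    qp <- kernlab::ipop(c = matrix(-1, 10), H = h, A = matrix(y, 1),
                        b = 0, l = matrix(0, 10), u = matrix(1e7, 10),
                        r = 0)
    alpha <- kernlab::primal(qp)
    w_oracle <- drop(t(x) %*% (alpha * y))
    sv <- which.max(alpha)
    b_oracle <- y[sv] * (1 - alpha[sv] / (2 * d[sv])) - sum(w_oracle * x[sv, ])
    expect_equal(unname(fit$w), w_oracle, tolerance = 1e-3)
    expect_equal(fit$b, b_oracle, tolerance = 1e-3)
    # objective agreement is much tighter than parameter agreement
    obj_oracle <- 0.5 * sum(w_oracle^2) +
      sum(d * pmax(0, 1 - y * (drop(x %*% w_oracle) + b_oracle))^2)
    expect_equal(fit$objective, obj_oracle, tolerance = 1e-5)
    expect_lte(fit$objective, obj_oracle + 1e-7)
  }
})

test_that("negating all labels negates the decision function", {
  set.seed(12)
  x <- matrix(rnorm(12 * 4), 12, 4)
  y <- sample(rep(c(-1, 1), 6))
  f1 <- cwsvm(x, y)
  f2 <- cwsvm(x, -y)
  expect_equal(f2$w, -f1$w, tolerance = 1e-8)
  expect_equal(f2$b, -f1$b, tolerance = 1e-8)
})

test_that("duplicating every training point rescales the objective as expected", {
  set.seed(13)
  x <- matrix(rnorm(10 * 2), 10, 2)
  y <- sample(rep(c(-1, 1), 5))
  f1 <- cwsvm(x, y)
  d <- penalty_weights(y)
  # exact identity: duplicating the data doubles the slack mass, so
  # halving the per-sample penalties restores the original objective
  # and therefore the original boundary
  f2 <- cwsvm(rbind(x, x), c(y, y), weights = rep(d / 2, 2))
  expect_equal(f2$w, f1$w, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  # under the group-size rule D = N/(2 N_G) the weights are unchanged
  # by duplication (N and N_G both double), so the slack term gains
  # weight relative to the margin term and the boundary only drifts
  # slightly toward the hard-margin solution
  f3 <- cwsvm(rbind(x, x), c(y, y))
  expect_equal(f3$w, f1$w, tolerance = 0.1)
  expect_equal(f3$b, f1$b, tolerance = 0.1)
})

test_that("prediction is invariant to feature permutation", {
  set.seed(14)
  x <- matrix(rnorm(12 * 5), 12, 5)
  y <- sample(rep(c(-1, 1), 6))
  perm <- sample(5)
  f1 <- cwsvm(x, y)
  f2 <- cwsvm(x[, perm], y)
  expect_equal(unname(f2$w), unname(f1$w[perm]), tolerance = 1e-8)
  xt <- matrix(rnorm(5), 1)
  expect_equal(predict(f2, xt[, perm, drop = FALSE]), predict(f1, xt))
})

test_that("LOOCV is structurally sound and separates a planted effect", {
  set.seed(15)
  x <- rbind(matrix(rnorm(20, -3), 10), matrix(rnorm(20, 3), 10))
  y <- rep(c(-1, 1), each = 10)
  cv <- loocv(x, y)
  expect_equal(cv$n_folds, 20)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$n_correct,
               sum(cv$predicted == cv$truth))
  # ranks per fold are permutations of 1..d
  expect_true(all(apply(cv$rank_matrix, 1, sort) == c(1, 2)))
  expect_error(loocv(x[c(1, 2, 11), ], y[c(1, 2, 11)]), "at least 4")
})

test_that("LOOCV accuracy brackets chance on label-permuted null data", {
  set.seed(16)
  accs <- replicate(30, {
    x <- matrix(rnorm(16 * 4), 16, 4)
    y <- sample(rep(c(-1, 1), 8))
    loocv(x, y)$accuracy
  })
  # mean fold accuracy over 480 null folds: generous binomial band
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("standardization statistics never leak from the held-out subject", {
  set.seed(17)
  x <- matrix(rnorm(12 * 3), 12, 3)
  y <- sample(rep(c(-1, 1), 6))
  cv1 <- loocv(x, y)
  # replace subject 1's features by an extreme outlier: fold-1 training
  # scaling must not change, so all other folds may shift but the
  # fold-1 model itself is trained identically
  x_out <- x
  x_out[1, ] <- c(1e6, -1e6, 1e6)
  xtr <- x[-1, , drop = FALSE]
  mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
  fit_clean <- cwsvm(sweep(sweep(xtr, 2, mu), 2, sg, "/"), y[-1])
  cv2 <- loocv(x_out, y)
  # reconstruct fold-1 decision for the outlier under training-only scaling
  xte <- sweep(sweep(x_out[1, , drop = FALSE], 2, mu), 2, sg, "/")
  expect_equal(cv2$predicted[1], unname(predict(fit_clean, xte)))
})

test_that("feature-weight ranks identify a planted informative feature", {
  set.seed(18)
  n <- 24
  x <- cbind(matrix(rnorm(n * 4), n, 4), c(rnorm(n / 2, 2), rnorm(n / 2, -2)))
  y <- rep(c(1, -1), each = n / 2)
  cv <- loocv(x, y)
  expect_equal(which.min(cv$mean_ranks), 5)
  expect_true(all(cv$mean_ranks >= 1 & cv$mean_ranks <= 5))
  # one-dimensional model: rank is always 1
  cv1 <- loocv(x[, 5, drop = FALSE], y)
  expect_equal(unname(cv1$mean_ranks), 1)
  # standalone helper agrees with the cv object
  expect_equal(feature_weight_ranks(cv), cv$mean_ranks)
})
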