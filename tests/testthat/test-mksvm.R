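test_that("linear kernels are trace-normalized, symmetric, and PSD", {
  set.seed(2)
  for (k in 1:100) {
    x <- matrix(rnorm(12 * sample(2:8, 1)), 12)
    kk <- build_kernel(x, train = 1:9, test = 10:12)
    expect_equal(sum(diag(kk$train)), 9, tolerance = 1e-9)
    expect_equal(kk$train, t(kk$train), tolerance = 1e-12)
    ev <- eigen(kk$train, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  # orthonormal rows give the identity Gram after normalization
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  kk <- build_kernel(q, train = 1:5)
  # rows are centred/scaled first, so only check on raw orthonormal input
  raw <- tcrossprod(q) * 5 / sum(diag(tcrossprod(q)))
  expect_equal(raw, diag(5), tolerance = 1e-9)
  # duplicated subjects give identical kernel rows
  x <- matrix(rnorm(6 * 4), 6)
  x[2, ] <- x[1, ]
  kk2 <- build_kernel(x, train = 1:6)
  expect_equal(kk2$train[1, ], kk2$train[2, ], tolerance = 1e-12)
})

test_that("combined kernels stay on the simplex and preserve PSD", {
  set.seed(6)
  make_psd <- function(n) { a <- matrix(rnorm(n * n), n); tcrossprod(a) / n }
  for (k in 1:30) {
    ks <- list(make_psd(8), make_psd(8), make_psd(8))
    b <- stats::runif(3); b <- b / sum(b)
    kc <- combine_kernels(ks, b)
    ev <- eigen(kc, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  ks <- list(make_psd(5), make_psd(5), make_psd(5))
  expect_equal(combine_kernels(ks, c(1, 0, 0)), ks[[1]])
  expect_equal(combine_kernels(list(ks[[1]], ks[[1]]), c(0.5, 0.5)), ks[[1]])
  expect_error(combine_kernels(ks, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("two-point separable toy has symmetric decisions", {
  x <- matrix(c(1, -1), ncol = 1)
  y <- c(1, -1)
  kk <- build_kernel(x, 1:2)
  m <- train_mksvm(kk$train, y, C = 10)
  expect_equal(sign(m$decision), y)
  expect_equal(m$decision[1], -m$decision[2], tolerance = 1e-9)
})

test_that("SMO solution satisfies the dual constraints and matches a projected-gradient oracle", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(8:16, 1)
    x <- matrix(rnorm(n * 4), n)
    y <- sample(c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2))))
    C <- stats::runif(1, 0.1, 5)
    kk <- build_kernel(x, seq_len(n))
    m <- train_mksvm(kk$train, y, C)
    expect_true(all(m$alpha >= -1e-9 & m$alpha <= C + 1e-9))
    expect_lt(abs(sum(m$alpha * y)), 1e-6)
    if (k <= 10) {  # objective comparison on a subsample (oracle is slow)
      a_or <- oracle_svm_dual(kk$train, y, C)
      obj <- function(a) sum(a) - 0.5 * drop(t(a * y) %*% kk$train %*% (a * y))
      expect_gte(obj(m$alpha), obj(a_or) - 1e-4)
    }
  }
})

test_that("a simplex vertex reproduces the single-kernel SVM decisions", {
  set.seed(23)
  x1 <- matrix(rnorm(20 * 5), 20)
  x2 <- matrix(rnorm(20 * 3), 20)
  y <- rep(c(1, -1), 10)
  k1 <- build_kernel(x1, 1:20)$train
  k2 <- build_kernel(x2, 1:20)$train
  for (C in c(0.5, 2)) {
    mk <- train_mksvm(combine_kernels(list(k1, k2), c(1, 0)), y, C)
    single <- train_mksvm(k1, y, C)
    expect_lt(max(abs(mk$decision - single$decision)), 1e-6)
  }
})

test_that("simplex grid enumerates compositions correctly", {
  g3 <- simplex_grid(3, 0.1)
  expect_equal(nrow(g3), 66)          # C(12, 2)
  expect_true(all(abs(rowSums(g3) - 1) < 1e-12))
  expect_true(all(g3 >= 0))
  expect_equal(nrow(simplex_grid(2, 0.1)), 11)
  expect_equal(simplex_grid(1), matrix(1, 1, 1))
})

test_that("performance metrics follow the printed confusion formulas", {
  # the confusion matrix consistent with the headline two-group study
  pm <- performance_metrics(labels = c(rep(1, 20), rep(-1, 22)),
                            predicted = c(rep(1, 18), rep(-1, 2),
                                          rep(-1, 17), rep(1, 5)))
  expect_equal(pm$TP, 18); expect_equal(pm$FN, 2)
  expect_equal(pm$TN, 17); expect_equal(pm$FP, 5)
  expect_equal(round(100 * pm$accuracy, 2), 83.33)
  expect_equal(round(100 * pm$sensitivity, 2), 90)
  expect_equal(round(100 * pm$specificity, 2), 77.27)
  # AUC extremes
  y <- rep(c(1, -1), each = 5)
  expect_equal(performance_metrics(y, decision = c(2:6, -(1:5)))$auc, 1)
  expect_equal(performance_metrics(y, decision = rep(0.3, 10))$auc, 0.5)
})

test_that("nested LOOCV separates planted signal and never sees the held-out subject", {
  set.seed(1)
  n <- 16; n_roi <- 8
  edge_x <- matrix(rnorm(n * 28), n)
  global_x <- matrix(rnorm(n * 7), n)
  nodal_x <- matrix(rnorm(n * n_roi * 6), n)
  y <- rep(c(1, -1), each = n / 2)
  edge_x[y == 1, 1:4] <- edge_x[y == 1, 1:4] + 2
  nodal_x[y == 1, 1:6] <- nodal_x[y == 1, 1:6] + 2
  groups <- rep(seq_len(n_roi), each = 6)
  res <- mkl_nested_loocv(edge_x, global_x, nodal_x, groups, y,
                          beta_step = 0.5, lambda = 2)
  expect_gt(res$accuracy, 0.8)
  expect_equal(res$TP + res$TN + res$FP + res$FN, n)
  # reported metrics recompute exactly from the stored confusion counts
  expect_equal(res$accuracy, (res$TP + res$TN) / n)
  expect_equal(res$sensitivity, res$TP / (res$TP + res$FN))
  expect_equal(res$specificity, res$TN / (res$TN + res$FP))
  # per-fold hyperparameters recorded on the simplex
  for (f in res$folds) {
    expect_true(f$C %in% 2^(-5:5))
    expect_equal(sum(f$beta), 1, tolerance = 1e-12)
  }
  # leakage audit: corrupting the held-out subject's features must not
  # change its own fold's training artifacts (selection, standardization,
  # hyperparameter choice) -- only the test-kernel row may differ
  edge_x2 <- edge_x; edge_x2[3, ] <- 50
  nodal_x2 <- nodal_x; nodal_x2[3, ] <- -50
  global_x2 <- global_x; global_x2[3, ] <- 9
  res2 <- mkl_nested_loocv(edge_x2, global_x2, nodal_x2, groups, y,
                           beta_step = 0.5, lambda = 2)
  expect_identical(res$folds[[3]], res2$folds[[3]])
})

test_that("single-modality nested LOOCV works and errors are informative", {
  set.seed(4)
  n <- 12
  global_x <- matrix(rnorm(n * 7), n)
  y <- rep(c(1, -1), each = 6)
  global_x[y == 1, ] <- global_x[y == 1, ] + 1.5
  res <- mkl_nested_loocv(global_x = global_x, labels = y, modalities = "G",
                          beta_step = 0.5)
  expect_gt(res$accuracy, 0.7)
  expect_error(mkl_nested_loocv(global_x = global_x, labels = rep(1, n),
                                modalities = "G"), "3 subjects per class")
  expect_error(mkl_nested_loocv(labels = y, modalities = "C"), "edge_x required")
})
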