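#' @useDynLib mkconnectome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Build a linear kernel for one feature modality
#'
#' Standardizes the features on the training rows, drops zero-variance
#' training columns with a warning, and returns the linear Gram matrix
#' trace-normalized so that the training block has trace n_train.  The
#' test-vs-train block uses the training standardization and the same
#' normalization factor, so nothing about the held-out rows influences
#' the kernel geometry.
#'
#' @param x Subjects x features matrix (all rows).
#' @param train Training row indices.
#' @param test Test row indices (default none).
#' @return List: \code{train} (n_train x n_train), \code{test}
#'   (n_test x n_train), \code{scale_factor}.
#' @export
build_kernel <- function(x, train, test = integer(0)) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) {
    warning("empty feature set; returning zero kernel")
    return(list(train = matrix(0, length(train), length(train)),
                test = matrix(0, length(test), length(train)),
                scale_factor = 1))
  }
  std <- standardize_train(x, train)
  if (length(std$constant) > 0L) {
    warning(length(std$constant), " zero-variance training feature(s) dropped")
    std$x <- std$x[, -std$constant, drop = FALSE]
  }
  if (ncol(std$x) == 0L)
    return(list(train = matrix(0, length(train), length(train)),
                test = matrix(0, length(test), length(train)),
                scale_factor = 1))
  xtr <- std$x[train, , drop = FALSE]
  ktr <- tcrossprod(xtr)
  tr <- sum(diag(ktr))
  fac <- if (tr > 0) length(train) / tr else 1
  kte <- if (length(test) > 0L)
    std$x[test, , drop = FALSE] %*% t(xtr) * fac
  else matrix(0, 0, length(train))
  list(train = ktr * fac, test = kte, scale_factor = fac)
}

#' Convex combination of modality kernels
#'
#' @param kernels List of kernel matrices of identical dimension.
#' @param beta Nonnegative weights summing to 1, one per kernel.
#' @return The weighted-sum kernel (positive semidefinite when the
#'   inputs are).
#' @export
combine_kernels <- function(kernels, beta) {
  stopifnot(length(kernels) == length(beta), all(beta >= -1e-12))
  if (abs(sum(beta) - 1) > 1e-8) stop("kernel weights must sum to 1")
  dims <- vapply(kernels, dim, integer(2))
  if (any(dims != dims[, 1])) stop("kernel dimension mismatch")
  out <- matrix(0, dims[1, 1], dims[2, 1])
  for (m in seq_along(kernels)) out <- out + beta[m] * kernels[[m]]
  out
}

#' Train a (multi-)kernel SVM from a precomputed kernel
#'
#' Solves the box-constrained dual (soft-margin C-SVM) by sequential
#' minimal optimisation to a KKT-violation tolerance, with the bias taken
#' from margin support vectors (averaged) or the KKT interval midpoint
#' when none are free.
#'
#' @param K n x n combined kernel (training block).
#' @param y +1/-1 labels.
#' @param C Box constraint (> 0).
#' @param tol KKT tolerance (default 1e-6).
#' @return List of class \code{mksvm}: \code{alpha}, \code{b},
#'   \code{y}, \code{C}, \code{support} (indices with alpha > 0),
#'   \code{decision} (training decision values).
#' @export
train_mksvm <- function(K, y, C, tol = 1e-6) {
  if (!is_binary_label(y)) stop("training labels must contain both +1 and -1")
  stopifnot(C > 0, nrow(K) == length(y))
  fit <- svm_smo(K, as.numeric(y), C, tol = tol)
  coef <- fit$alpha * y
  dec <- drop(K %*% coef) + fit$b
  structure(list(alpha = fit$alpha, b = fit$b, y = y, C = C,
                 support = which(fit$alpha > 1e-9),
                 iterations = fit$iterations, decision = dec),
            class = "mksvm")
}

#' Decision values for new subjects
#'
#' @param object A trained \code{mksvm}.
#' @param k_test n_test x n_train kernel block (test rows vs training rows).
#' @param ... Unused.
#' @return Numeric decision values; the predicted label is their sign.
#' @export
predict.mksvm <- function(object, k_test, ...) {
  drop(k_test %*% (object$alpha * object$y)) + object$b
}

#' Simplex grid of kernel weights
#'
#' All compositions of 1/step into \code{n_modalities} nonnegative parts;
#' with 3 modalities and step 0.1 this is the 66-point grid.
#'
#' @param n_modalities Number of kernels.
#' @param step Grid resolution (default 0.1).
#' @return Matrix with one weight vector per row, rows summing to 1.
#' @export
simplex_grid <- function(n_modalities, step = 0.1) {
  k <- round(1 / step)
  if (n_modalities == 1L) return(matrix(1, 1, 1))
  parts <- function(total, m) {
    if (m == 1L) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(a)
      cbind(a, parts(total - a, m - 1L))))
  }
  g <- parts(k, n_modalities) / k
  dimnames(g) <- NULL
  g
}

#' Classification performance from confusion counts and decision values
#'
#' Accuracy = (TP+TN)/(TP+FP+TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP); AUC is the Mann-Whitney probability that a
#' positive subject's decision value exceeds a negative one's, ties
#' counted one half.
#'
#' @param labels True +1/-1 labels.
#' @param decision Real decision values (sign rule at 0 gives the
#'   predicted label) or NULL to use \code{predicted} only for counts.
#' @param predicted Optional predicted labels; default sign of decision.
#' @return List: \code{TP}, \code{TN}, \code{FP}, \code{FN},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{auc}
#'   (NA sentinels on zero denominators).
#' @export
performance_metrics <- function(labels, decision = NULL, predicted = NULL) {
  if (is.null(predicted)) {
    if (is.null(decision)) stop("need decision values or predicted labels")
    predicted <- ifelse(decision > 0, 1L, -1L)
  }
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == -1 & predicted == -1)
  fp <- sum(labels == -1 & predicted == 1)
  fn <- sum(labels == 1 & predicted == -1)
  tot <- tp + tn + fp + fn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (!is.null(decision)) auc_mann_whitney(decision, labels) else NA_real_
  list(TP = tp, TN = tn, FP = fp, FN = fn, accuracy = acc,
       sensitivity = sens, specificity = spec, auc = auc)
}

#' Nested leave-one-out cross-validated multi-kernel classification
#'
#' For each outer fold (one held-out subject): edge t-test selection,
#' group-LASSO nodal selection and feature standardization are re-run on
#' the outer-training rows only; an inner leave-one-out grid search over
#' C in \code{c_grid} and kernel weights beta on the simplex grid picks
#' the hyperparameters maximizing inner accuracy (ties: smaller C, then
#' beta closest to uniform); the model is retrained on all outer-training
#' rows and applied to the held-out subject.
#'
#' @param edge_x Subjects x edges matrix (connection modality, "C").
#' @param global_x Subjects x 7 global metric AUC matrix ("G").
#' @param nodal_x Subjects x (n_roi * 6) nodal metric AUC matrix ("N").
#' @param nodal_groups ROI group id per column of \code{nodal_x}.
#' @param labels +1/-1 labels.
#' @param modalities Subset of c("C","G","N") to combine.
#' @param alpha Edge t-test threshold (default 0.05).
#' @param lambda Group-LASSO penalty (default 1).
#' @param c_grid SVM cost grid (default 2^(-5:5)).
#' @param beta_step Simplex grid resolution (default 0.1).
#' @param fisher_rz Fisher r-to-z transform edge weights before testing.
#' @return List of class \code{classification_result}: per-subject
#'   \code{decision} and \code{predicted}, confusion counts and metrics
#'   (via [performance_metrics()]), \code{folds} (per-fold selected C,
#'   beta, feature counts), \code{consensus_edges}, \code{modalities}.
#' @export
mkl_nested_loocv <- function(edge_x = NULL, global_x = NULL, nodal_x = NULL,
                             nodal_groups = NULL, labels,
                             modalities = c("C", "G", "N"),
                             alpha = 0.05, lambda = 1,
                             c_grid = 2^(-5:5), beta_step = 0.1,
                             fisher_rz = FALSE) {
  n <- length(labels)
  if (n < 6L || sum(labels == 1) < 3L || sum(labels == -1) < 3L)
    stop("need n >= 6 with at least 3 subjects per class")
  modalities <- match.arg(modalities, c("C", "G", "N"), several.ok = TRUE)
  if ("C" %in% modalities && is.null(edge_x)) stop("edge_x required for modality C")
  if ("G" %in% modalities && is.null(global_x)) stop("global_x required for modality G")
  if ("N" %in% modalities && (is.null(nodal_x) || is.null(nodal_groups)))
    stop("nodal_x and nodal_groups required for modality N")
  betas <- simplex_grid(length(modalities), beta_step)
  decision <- numeric(n)
  folds <- vector("list", n)
  edge_selections <- if ("C" %in% modalities) vector("list", n) else NULL
  uniform <- rep(1 / length(modalities), length(modalities))
  for (hold in seq_len(n)) {
    train <- setdiff(seq_len(n), hold)
    ktr <- list(); kte <- list()
    fold_info <- list(hold = hold)
    for (m in modalities) {
      feats <- switch(m,
        C = {
          sel <- edge_ttest_select(edge_x, labels, train, alpha = alpha,
                                   fisher_rz = fisher_rz)
          edge_selections[[hold]] <- sel$selected
          fold_info$n_edges <- length(sel$selected)
          edge_x[, sel$selected, drop = FALSE]
        },
        G = global_x,
        N = {
          std <- standardize_train(nodal_x, train)
          gl <- fit_group_lasso(std$x[train, , drop = FALSE], labels[train],
                                nodal_groups, lambda = lambda)
          cols <- which(gl$w != 0)
          fold_info$n_nodal <- length(cols)
          if (length(cols) == 0L) {
            warning("fold ", hold, ": group-LASSO selected nothing; using all nodal features")
            cols <- seq_len(ncol(nodal_x))
          }
          nodal_x[, cols, drop = FALSE]
        })
      kk <- suppressWarnings(build_kernel(feats, train, hold))
      ktr[[m]] <- kk$train
      kte[[m]] <- kk$test
    }
    acc <- mkl_inner_cv(unname(ktr), as.numeric(labels[train]), betas,
                        as.numeric(c_grid))
    # ties: highest accuracy, then smaller C, then beta closest to uniform
    best <- which(acc == max(acc), arr.ind = TRUE)
    cand_c <- c_grid[best[, 2]]
    best <- best[cand_c == min(cand_c), , drop = FALSE]
    d_unif <- apply(betas[best[, 1], , drop = FALSE], 1L,
                    function(b) sum((b - uniform)^2))
    pick <- best[order(d_unif, best[, 1])[1L], ]
    beta_star <- betas[pick[1L], ]
    c_star <- c_grid[pick[2L]]
    model <- train_mksvm(combine_kernels(unname(ktr), beta_star),
                         labels[train], c_star)
    decision[hold] <- predict(model,
                              combine_kernels(unname(kte), beta_star))
    fold_info$C <- c_star
    fold_info$beta <- stats::setNames(beta_star, modalities)
    fold_info$inner_accuracy <- max(acc)
    folds[[hold]] <- fold_info
  }
  predicted <- ifelse(decision > 0, 1L, -1L)
  perf <- performance_metrics(labels, decision)
  res <- c(perf, list(
    decision = decision, predicted = predicted, labels = labels,
    folds = folds, modalities = modalities,
    consensus_edges = if (!is.null(edge_selections))
      tryCatch(consensus_edges(edge_selections), warning = function(w) integer(0))
    else NULL))
  class(res) <- "classification_result"
  res
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Multi-kernel SVM nested LOOCV (", paste(x$modalities, collapse = "+"),
      ")\n", sep = "")
  cat(sprintf("  n = %d  TP=%d TN=%d FP=%d FN=%d\n",
              length(x$labels), x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.3f\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity, x$auc))
  invisible(x)
}
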