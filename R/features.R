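#' Stack per-subject connectivity matrices into an edge feature table
#'
#' @param conns List of N x N connectivity matrices (one per subject).
#' @return subjects x M matrix, M = N(N-1)/2, columns in the row-major
#'   upper-triangle order of [edge_index_map()].
#' @export
edge_feature_table <- function(conns) {
  do.call(rbind, lapply(conns, edge_vector))
}

#' Edge-wise two-sample t-test selection
#'
#' Pooled-variance Student's t for every edge, computed on the training
#' rows only; edges with p below \code{alpha} are selected.  Edges whose
#' pooled variance is zero are excluded with a warning (no test is
#' possible).  Optionally the edge weights are Fisher r-to-z transformed
#' first.
#'
#' @param x Subjects x edges matrix.
#' @param labels +1 / -1 group labels, one per row of \code{x}.
#' @param train Row indices to use (default all rows).
#' @param alpha Selection threshold on the two-sided p-value.
#' @param fisher_rz Apply atanh to the weights before testing (default FALSE).
#' @return List: \code{selected} (edge indices), \code{t}, \code{p}
#'   (length-M vectors, NA where untestable), \code{alpha}.
#' @export
edge_ttest_select <- function(x, labels, train = seq_len(nrow(x)),
                              alpha = 0.05, fisher_rz = FALSE) {
  xt <- x[train, , drop = FALSE]
  yt <- labels[train]
  if (fisher_rz) xt <- atanh(pmin(xt, 1 - 1e-12))
  n1 <- sum(yt == 1); n2 <- sum(yt == -1)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 training subjects per group")
  x1 <- xt[yt == 1, , drop = FALSE]
  x2 <- xt[yt == -1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2L, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  tstat[se == 0] <- NA_real_
  if (any(se == 0))
    warning(sum(se == 0), " edge(s) with zero pooled variance excluded")
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  list(selected = which(!is.na(p) & p < alpha), t = unname(tstat),
       p = unname(p), alpha = alpha)
}

#' Consensus edges across cross-validation folds
#'
#' The intersection of the per-fold edge selections: an edge is a
#' consensus connection only if every training fold selected it.
#'
#' @param selections List of integer vectors (per-fold selected indices),
#'   or list of [edge_ttest_select()] results.
#' @return Sorted integer vector of consensus edge indices (possibly
#'   empty, with a warning).
#' @export
consensus_edges <- function(selections) {
  if (length(selections) == 0L) stop("need at least one fold")
  sets <- lapply(selections, function(s) if (is.list(s)) s$selected else s)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0L) warning("empty consensus edge set")
  out
}

#' Standardize columns using training rows only
#'
#' @param x Feature matrix.
#' @param train Training row indices.
#' @return List: \code{x} (all rows standardized with the training
#'   parameters), \code{center}, \code{scale}, \code{constant} (columns
#'   with zero training variance; scaled by 1).
#' @export
standardize_train <- function(x, train = seq_len(nrow(x))) {
  ctr <- colMeans(x[train, , drop = FALSE])
  scl <- apply(x[train, , drop = FALSE], 2L, stats::sd)
  constant <- which(scl == 0 | !is.finite(scl))
  scl[constant] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  list(x = xs, center = ctr, scale = scl, constant = constant)
}

logistic_loss <- function(w, c0, x, y) {
  eta <- drop(x %*% w) + c0
  sum(log1p(exp(-y * eta)))
}

logistic_grad <- function(w, c0, x, y) {
  eta <- drop(x %*% w) + c0
  s <- -y * stats::plogis(-y * eta)     # d/d_eta log(1+exp(-y eta))
  list(w = drop(crossprod(x, s)), c = sum(s))
}

group_penalty <- function(w, groups, lambda) {
  lambda * sum(vapply(split(w, groups), function(wg)
    sqrt(sum(wg^2)), numeric(1)))
}

# block soft-threshold: the proximal operator of the group-L2 penalty
prox_group <- function(w, groups, thr) {
  for (g in unique(groups)) {
    idx <- which(groups == g)
    nrm <- sqrt(sum(w[idx]^2))
    w[idx] <- if (nrm <= thr) 0 else w[idx] * (1 - thr / nrm)
  }
  w
}

#' Smallest penalty that zeroes every group
#'
#' With all weights at zero the optimal intercept is log(n+/n-); the
#' solution stays at w = 0 exactly when every group's gradient-block norm
#' is at most lambda.  This returns that critical value.
#'
#' @param x Standardized feature matrix (training rows).
#' @param y +1/-1 labels.
#' @param groups Group id per column.
#' @return Numeric lambda_max.
#' @export
group_lasso_lambda_max <- function(x, y, groups) {
  c0 <- log(sum(y == 1) / sum(y == -1))
  g <- logistic_grad(numeric(ncol(x)), c0, x, y)$w
  max(vapply(split(g, groups), function(gg) sqrt(sum(gg^2)), numeric(1)))
}

#' Group-LASSO logistic regression
#'
#' Minimizes the summed logistic loss plus \code{lambda} times the sum of
#' per-group Euclidean norms of the weights (intercept unpenalized), by
#' accelerated proximal gradient (FISTA) with backtracking line search
#' and a monotone restart.  Zero groups are exactly zero (block
#' soft-thresholding), which is what makes the fit a feature selector:
#' all metrics of a non-informative ROI are dropped jointly.
#'
#' @param x Feature matrix; should be standardized (training rows).
#' @param y +1/-1 labels.
#' @param groups Group id per column (e.g. ROI index, 6 metric columns
#'   per ROI).
#' @param lambda Penalty level (default 1).
#' @param max_iter Iteration cap (default 10000).
#' @param tol Relative objective-change convergence tolerance (1e-8).
#' @return List of class \code{group_lasso}: \code{w}, \code{intercept},
#'   \code{groups}, \code{lambda}, \code{objective} (final value),
#'   \code{objective_trace}, \code{iterations}, \code{converged}.
#' @export
fit_group_lasso <- function(x, y, groups, lambda = 1, max_iter = 10000L,
                            tol = 1e-8) {
  if (any(!is.finite(x))) stop("non-finite feature values")
  stopifnot(length(y) == nrow(x), length(groups) == ncol(x), lambda >= 0)
  p <- ncol(x)
  w <- numeric(p)
  c0 <- log(sum(y == 1) / sum(y == -1))
  # Lipschitz bound of the summed logistic loss gradient: ||X~||_2^2 / 4
  xa <- cbind(x, 1)
  lip <- (norm(xa, "2")^2) / 4
  step <- 1 / lip
  obj <- function(w, c0) logistic_loss(w, c0, x, y) +
    group_penalty(w, groups, lambda)
  f_old <- obj(w, c0)
  trace <- f_old
  zw <- w; zc <- c0; tk <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- logistic_grad(zw, zc, x, y)
    # backtracking from the global bound (loss is smooth; bound is valid,
    # but try larger steps first for speed)
    st <- step * 4
    repeat {
      w_new <- prox_group(zw - st * g$w, groups, st * lambda)
      c_new <- zc - st * g$c
      lhs <- logistic_loss(w_new, c_new, x, y)
      dw <- c(w_new - zw, c_new - zc)
      rhs <- logistic_loss(zw, zc, x, y) + sum(c(g$w, g$c) * dw) +
        sum(dw^2) / (2 * st)
      if (lhs <= rhs + 1e-10 || st <= step) break
      st <- st / 2
    }
    f_new <- obj(w_new, c_new)
    if (f_new > f_old) {           # monotone restart: fall back to plain step
      w_new <- prox_group(w - step * logistic_grad(w, c0, x, y)$w,
                          groups, step * lambda)
      c_new <- c0 - step * logistic_grad(w, c0, x, y)$c
      f_new <- obj(w_new, c_new)
      tk <- 1; zw <- w_new; zc <- c_new
    } else {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      zw <- w_new + ((tk - 1) / t_new) * (w_new - w)
      zc <- c_new + ((tk - 1) / t_new) * (c_new - c0)
      tk <- t_new
    }
    rel <- abs(f_old - f_new) / max(1, abs(f_old))
    w <- w_new; c0 <- c_new; f_old <- f_new
    trace <- c(trace, f_new)
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(w = w, intercept = c0, groups = groups, lambda = lambda,
                 objective = f_old, objective_trace = trace,
                 iterations = it, converged = converged),
            class = "group_lasso")
}

#' Rank ROIs and features from a fitted group-LASSO model
#'
#' ROIs are ranked by the Euclidean norm of their weight block; individual
#' (ROI, metric) features by absolute weight.
#'
#' @param model A [fit_group_lasso()] result.
#' @param top_k How many entries to return (default 20); truncated to the
#'   number of nonzero entries.
#' @return List: \code{roi_rank} (data.frame group, norm) and
#'   \code{feature_rank} (data.frame column, group, weight).
#' @export
select_groups <- function(model, top_k = 20L) {
  norms <- vapply(split(model$w, model$groups), function(wg)
    sqrt(sum(wg^2)), numeric(1))
  gids <- unique(model$groups)[order(unique(model$groups))]
  nz_g <- which(norms > 0)
  if (length(nz_g) == 0L) {
    warning("all groups are zero; nothing to rank")
    return(list(roi_rank = data.frame(group = integer(), norm = numeric()),
                feature_rank = data.frame(column = integer(),
                                          group = integer(),
                                          weight = numeric())))
  }
  ord_g <- order(-norms, seq_along(norms))
  ord_g <- ord_g[norms[ord_g] > 0]
  roi_rank <- data.frame(group = gids[ord_g], norm = unname(norms[ord_g]))
  roi_rank <- utils::head(roi_rank, top_k)
  nz_f <- which(model$w != 0)
  ord_f <- nz_f[order(-abs(model$w[nz_f]), nz_f)]
  feature_rank <- data.frame(column = ord_f, group = model$groups[ord_f],
                             weight = model$w[ord_f])
  feature_rank <- utils::head(feature_rank, top_k)
  list(roi_rank = roi_rank, feature_rank = feature_rank)
}
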