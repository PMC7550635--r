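# Independent brute-force oracles for graph metrics, kept deliberately
# naive: they share no code with the package implementations.

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(stats::runif(length(up)) < p)
  a + t(a)
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# per-node clustering by explicit neighbour-pair enumeration
oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(a[v, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (x in nb) for (y in nb) if (x < y && a[x, y] != 0) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

# betweenness by explicit enumeration of all shortest paths (small n only)
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  bt <- numeric(n)
  all_shortest <- function(s, t) {
    # returns list of node sequences realising d(s, t)
    if (!is.finite(d[s, t])) return(list())
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) return(list(path))
      nxt <- which(a[last, ] != 0 & d[, t] == d[last, t] - 1)
      out <- list()
      for (v in nxt) out <- c(out, grow(c(path, v)))
      out
    }
    grow(s)
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_shortest(s, t)
    if (length(paths) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bt[v] <- bt[v] + through / length(paths)
    }
  }
  bt
}

oracle_global_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracle_distances(a)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(a[v, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(a[nb, nb, drop = FALSE])
  })
}

oracle_nodal_efficiency <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sapply(seq_len(n), function(v) {
    s <- 0
    for (u in seq_len(n)) if (u != v && is.finite(d[v, u])) s <- s + 1 / d[v, u]
    s / (n - 1)
  })
}

oracle_nodal_shortest_path <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) 0 else mean(dv)
  })
}

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    k <- length(code)
    if (k == n) { out[[length(out) + 1]] <<- code; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(code, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# exact maximum-modularity Q by exhaustive partition search (n <= 8)
oracle_max_modularity <- function(a) {
  big_l <- sum(a) / 2
  deg <- rowSums(a)
  best <- -Inf
  for (mem in all_partitions(nrow(a))) {
    q <- 0
    for (m in unique(mem)) {
      idx <- mem == m
      l_i <- sum(a[idx, idx]) / 2
      d_i <- sum(deg[idx])
      q <- q + l_i / big_l - (d_i / (2 * big_l))^2
    }
    if (q > best) best <- q
  }
  best
}

# projected-gradient solver for the SVM dual (independent of the SMO path):
# min 1/2 a'Qa - e'a  s.t. 0 <= a <= C, y'a = 0
oracle_svm_dual <- function(K, y, C, iters = 200000, lr = NULL) {
  n <- length(y)
  Q <- (y %*% t(y)) * K
  if (is.null(lr)) lr <- 1 / (norm(Q, "2") + 1e-8)
  project <- function(a) {
    # bisection on the dual variable of the equality constraint
    f <- function(th) sum(pmin(pmax(a - th * y, 0), C) * y)
    lo <- -max(abs(a)) - C - 1; hi <- -lo
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a - ((lo + hi) / 2) * y, 0), C)
  }
  a <- project(rep(C / 2, n))
  for (k in seq_len(iters)) {
    g <- drop(Q %*% a) - 1
    a_new <- project(a - lr * g)
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  a
}

make_ring_with_shortcuts <- function(n, n_short, seed) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a[i, j] <- a[j, i] <- 1
    j2 <- (i + 1) %% n + 1          # second-neighbour lattice edges
    a[i, j2] <- a[j2, i] <- 1
  }
  set.seed(seed)
  for (k in seq_len(n_short)) {
    ij <- sample(n, 2)
    a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- 1
  }
  diag(a) <- 0
  a
}
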