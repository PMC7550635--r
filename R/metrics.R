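#' @importFrom igraph graph_from_adjacency_matrix distances betweenness
#'   rewire keeping_degseq cluster_fast_greedy membership ecount gorder
NULL

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

#' Per-node clustering coefficient
#'
#' For a node v with degree k >= 2, the fraction of realised links among
#' its neighbours, 2 t(v) / (k (k - 1)) with t(v) the triangle count; 0
#' when k < 2.  The global clustering coefficient C_p is the mean over
#' all nodes.
#'
#' @param adj Binary adjacency matrix.
#' @return Numeric vector of per-node values.
#' @export
nodal_clustering <- function(adj) {
  a <- (adj != 0) * 1
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)       # = 2 * triangles(v)
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  unname(cc)
}

#' Shortest-path derived metrics
#'
#' Breadth-first distances feed four quantities.  Disconnected graphs are
#' handled by the dominant connectome convention: path-length averages run
#' over reachable pairs only, while efficiencies use 1/infinity = 0 and
#' need no special-casing.
#'
#' @param adj Binary adjacency matrix.
#' @return List with \code{nodal_shortest_path} (mean distance to
#'   reachable nodes; 0 for isolated nodes), \code{nodal_efficiency},
#'   \code{L_p} (mean over reachable ordered pairs; NA if no edges) and
#'   \code{E_global}.
#' @export
shortest_path_metrics <- function(adj) {
  n <- nrow(adj)
  d <- igraph::distances(as_igraph(adj))
  diag(d) <- NA
  finite <- is.finite(d)
  nsp <- vapply(seq_len(n), function(v) {
    dv <- d[v, finite[v, ]]
    if (length(dv) == 0L) 0 else mean(dv)
  }, numeric(1))
  inv <- 1 / d
  inv[!finite] <- 0
  diag(inv) <- 0
  neff <- rowSums(inv) / (n - 1)
  lp <- if (any(finite, na.rm = TRUE)) mean(d[finite]) else NA_real_
  eg <- sum(inv) / (n * (n - 1))
  list(nodal_shortest_path = unname(nsp), nodal_efficiency = unname(neff),
       L_p = lp, E_global = eg)
}

#' Betweenness centrality (unnormalized)
#'
#' Brandes accumulation over unordered source-target pairs with
#' fractional credit shared among equal-length shortest paths.
#'
#' @param adj Binary adjacency matrix.
#' @return Numeric vector of per-node values.
#' @export
node_betweenness <- function(adj) {
  unname(igraph::betweenness(as_igraph(adj), directed = FALSE))
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbours
#' (the node itself excluded); 0 for nodes of degree < 2.
#'
#' @param adj Binary adjacency matrix.
#' @return Numeric vector of per-node values.
#' @export
nodal_local_efficiency <- function(adj) {
  as.numeric(local_efficiency_cpp((adj != 0) * 1))
}

#' Modularity Q of a given partition
#'
#' Evaluates Q = sum_i [ l_i / L - (d_i / 2L)^2 ] where L is the total
#' edge count, l_i the within-module edge count of module i and d_i the
#' summed degree of module i's members.
#'
#' @param adj Binary adjacency matrix.
#' @param membership Integer module label per node.
#' @return List: \code{Q}, \code{n_modules}, \code{L}, and per-module
#'   \code{l} and \code{d}.
#' @export
modularity_q <- function(adj, membership) {
  a <- (adj != 0) * 1
  big_l <- sum(a) / 2
  if (big_l == 0) stop("modularity undefined on an edgeless graph")
  mods <- sort(unique(membership))
  deg <- rowSums(a)
  l_i <- vapply(mods, function(m) {
    idx <- membership == m
    sum(a[idx, idx, drop = FALSE]) / 2
  }, numeric(1))
  d_i <- vapply(mods, function(m) sum(deg[membership == m]), numeric(1))
  q <- sum(l_i / big_l - (d_i / (2 * big_l))^2)
  list(Q = q, n_modules = length(mods), L = big_l, l = l_i, d = d_i)
}

#' Greedy agglomerative modularity optimisation
#'
#' Starts from singleton modules and repeatedly merges the pair of
#' modules giving the largest modularity increase until no merge
#' improves Q (fast greedy agglomeration).  Q of the final partition is
#' evaluated with [modularity_q()].
#'
#' @param adj Binary adjacency matrix with at least one edge.
#' @return A [modularity_q()] list plus \code{membership}.
#' @export
modularity_greedy <- function(adj) {
  if (sum(adj != 0) == 0) stop("modularity undefined on an edgeless graph")
  g <- as_igraph(adj)
  mem <- as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
  out <- modularity_q(adj, mem)
  out$membership <- mem
  out
}

#' Degree-preserving null ensemble
#'
#' Maslov-Sneppen double-edge-swap randomisation: each null graph is the
#' source graph rewired with 10 |E| attempted swaps, preserving the
#' degree sequence exactly.  Stores the mean clustering coefficient and
#' mean characteristic path length across the ensemble.
#'
#' @param adj Binary adjacency matrix.
#' @param n_random Ensemble size (default 100).
#' @param seed Integer seed; graph r uses seed + r.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return List: \code{mean_Cp}, \code{mean_Lp}, \code{Cp}, \code{Lp},
#'   \code{n_random}, \code{seed}.
#' @export
null_ensemble <- function(adj, n_random = 100L, seed = 1L, swap_factor = 10L) {
  g <- as_igraph(adj)
  ne <- igraph::ecount(g)
  cps <- numeric(n_random)
  lps <- numeric(n_random)
  for (r in seq_len(n_random)) {
    set.seed(seed + r)
    gr <- if (ne >= 2L)
      igraph::rewire(g, igraph::keeping_degseq(niter = swap_factor * ne))
    else g
    # local transitivity with zero isolates matches nodal_clustering();
    # mean_distance averages over reachable ordered pairs, matching L_p
    cps[r] <- mean(igraph::transitivity(gr, type = "local",
                                        isolates = "zero"))
    lp <- suppressWarnings(igraph::mean_distance(gr, unconnected = TRUE))
    lps[r] <- if (is.finite(lp)) lp else NA_real_
  }
  list(mean_Cp = mean(cps), mean_Lp = mean(lps, na.rm = TRUE),
       Cp = cps, Lp = lps, n_random = n_random, seed = seed)
}

#' Small-world normalisation
#'
#' gamma = C_p / mean random C_p, lambda = L_p / mean random L_p,
#' sigma = gamma / lambda.  A small-world network has gamma > 1 with
#' lambda close to 1, hence sigma > 1.
#'
#' Degenerate sparse graphs can have zero clustering in both the observed
#' and the null graphs; the ratio 0/0 is taken as 1 (the observed value
#' is exactly what the null predicts).  A positive observed value over a
#' zero null mean is genuinely undefined and yields an NA sentinel.
#'
#' @param c_p,l_p Observed global clustering and path length.
#' @param ens A [null_ensemble()].
#' @return Named vector c(gamma, lambda, sigma); NA sentinels when the
#'   null means are degenerate.
#' @export
small_world_normalize <- function(c_p, l_p, ens) {
  gam <- if (is.finite(ens$mean_Cp) && ens$mean_Cp > 0) c_p / ens$mean_Cp
         else if (isTRUE(c_p == 0) && isTRUE(ens$mean_Cp == 0)) 1
         else NA_real_
  lam <- if (is.finite(ens$mean_Lp) && ens$mean_Lp > 0) l_p / ens$mean_Lp else NA_real_
  sig <- if (is.finite(gam) && is.finite(lam) && lam > 0) gam / lam else NA_real_
  c(gamma = gam, lambda = lam, sigma = sig)
}

GLOBAL_METRICS <- c("Cp", "Lp", "gamma", "lambda", "sigma", "E_global", "Q")
NODAL_METRICS <- c("betweenness", "degree", "clustering", "efficiency",
                   "local_efficiency", "shortest_path")

#' All global and nodal metrics of one binary graph
#'
#' @param adj Binary adjacency matrix.
#' @param ens Optional [null_ensemble()] for the normalized metrics; when
#'   NULL, gamma/lambda/sigma are NA.
#' @return List: \code{global} (named 7-vector: Cp, Lp, gamma, lambda,
#'   sigma, E_global, Q) and \code{nodal} (N x 6 matrix: betweenness,
#'   degree, clustering, efficiency, local_efficiency, shortest_path).
#' @export
graph_metrics <- function(adj, ens = NULL) {
  cc <- nodal_clustering(adj)
  sp <- shortest_path_metrics(adj)
  bt <- node_betweenness(adj)
  le <- nodal_local_efficiency(adj)
  deg <- rowSums(adj != 0)
  q <- if (sum(adj != 0) > 0) modularity_greedy(adj)$Q else NA_real_
  cp <- mean(cc)
  sw <- if (is.null(ens)) c(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
        else small_world_normalize(cp, sp$L_p, ens)
  global <- c(Cp = cp, Lp = sp$L_p, sw, E_global = sp$E_global, Q = q)
  names(global) <- GLOBAL_METRICS
  nodal <- cbind(betweenness = bt, degree = unname(deg), clustering = cc,
                 efficiency = sp$nodal_efficiency, local_efficiency = le,
                 shortest_path = sp$nodal_shortest_path)
  list(global = global, nodal = nodal)
}

#' Area under the sparsity curve
#'
#' Threshold-free aggregation of a per-threshold metric: the plain sum of
#' its values over the grid (no step-width weighting), one number per
#' metric.  A metric constant at v over the default 49-value grid gives
#' 49 v.
#'
#' @param values Numeric vector, one value per grid threshold.
#' @param n_expected Expected length (optional check).
#' @return Sum of the values.
#' @export
metric_auc <- function(values, n_expected = NULL) {
  if (!is.null(n_expected) && length(values) != n_expected)
    stop("expected ", n_expected, " threshold values, got ", length(values))
  if (any(!is.finite(values)))
    stop("missing or non-finite threshold value; cannot aggregate")
  sum(values)
}

#' Metrics for one subject across the sparsity grid
#'
#' Computes global and nodal metrics at every threshold and their
#' area-under-the-sparsity-curve aggregates.  The small-world null
#' ensemble is rebuilt per threshold from that threshold's graph.
#'
#' @param conn Connectivity matrix.
#' @param grid Sparsity grid.
#' @param n_random Null ensemble size per threshold (0 skips the
#'   normalized metrics, leaving gamma/lambda/sigma NA).
#' @param seed Seed for the null ensembles.
#' @return List: \code{global} (n_thresholds x 7), \code{nodal}
#'   (array N x 6 x n_thresholds), \code{auc_global} (7-vector),
#'   \code{auc_nodal} (N x 6 matrix).
#' @export
subject_metrics <- function(conn, grid = sparsity_grid(), n_random = 100L,
                            seed = 1L) {
  graphs <- threshold_series(conn, grid)
  n <- nrow(conn)
  nt <- length(grid)
  glob <- matrix(NA_real_, nt, length(GLOBAL_METRICS),
                 dimnames = list(names(graphs), GLOBAL_METRICS))
  nod <- array(NA_real_, c(n, length(NODAL_METRICS), nt),
               dimnames = list(rownames(conn), NODAL_METRICS, names(graphs)))
  for (t in seq_len(nt)) {
    ens <- if (n_random > 0L)
      null_ensemble(graphs[[t]], n_random = n_random,
                    seed = derive_seed(seed, t))
    else NULL
    gm <- graph_metrics(graphs[[t]], ens)
    glob[t, ] <- gm$global
    nod[, , t] <- gm$nodal
  }
  keep <- if (n_random > 0L) GLOBAL_METRICS else setdiff(GLOBAL_METRICS,
                                                         c("gamma", "lambda", "sigma"))
  auc_global <- vapply(GLOBAL_METRICS, function(m)
    if (m %in% keep) metric_auc(glob[, m]) else NA_real_, numeric(1))
  auc_nodal <- apply(nod, c(1, 2), sum)
  list(global = glob, nodal = nod, auc_global = auc_global,
       auc_nodal = auc_nodal)
}

#' Identify hub nodes
#'
#' The top 5 percent of nodes (ceiling) by weight, ties broken by node
#' index so the selection is deterministic.
#'
#' @param weights One weight per node (e.g. group-mean degree AUC).
#' @param prop Proportion defining a hub (default 0.05).
#' @return Integer vector of hub node indices, ordered by decreasing weight.
#' @export
identify_hubs <- function(weights, prop = 0.05) {
  n <- length(weights)
  k <- ceiling(prop * n)
  order(-weights, seq_len(n))[seq_len(k)]
}
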