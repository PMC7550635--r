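`%||%` <- function(x, y) if (is.null(x)) y else x

#' Map between linear edge indices and ROI pairs
#'
#' Enumerates the unordered ROI pairs (i, j), i < j, of an \code{n}-node
#' network in row-major order: (1,2), (1,3), ..., (1,n), (2,3), ...
#' This fixed ordering is used everywhere an edge vector of length
#' n(n-1)/2 appears (edge feature tables, selections, ground truth).
#'
#' @param n Number of nodes.
#' @return A data.frame with columns \code{i}, \code{j} (1-based) and one
#'   row per unordered pair, in row-major order.
#' @export
edge_index_map <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Extract the upper-triangle edge vector of a symmetric matrix
#'
#' @param m Symmetric numeric matrix.
#' @return Numeric vector of length n(n-1)/2 in the row-major pair order
#'   of [edge_index_map()].
#' @export
edge_vector <- function(m) {
  map <- edge_index_map(nrow(m))
  m[cbind(map$i, map$j)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' @param v Edge vector in the order of [edge_index_map()].
#' @param n Number of nodes.
#' @return n x n symmetric matrix with zero diagonal.
#' @export
edge_vector_to_matrix <- function(v, n) {
  map <- edge_index_map(n)
  stopifnot(length(v) == nrow(map))
  m <- matrix(0, n, n)
  m[cbind(map$i, map$j)] <- v
  m[cbind(map$j, map$i)] <- v
  m
}

# round-half-up; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# deterministic 32-bit-safe seed stream derived from a master seed
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + index * 16807) %% 2147483647)
}

is_binary_label <- function(y) all(y %in% c(-1, 1)) && length(unique(y)) == 2L
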