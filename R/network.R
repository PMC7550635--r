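#' Detrend and band-pass filter regional time series
#'
#' Optional convenience preprocessing for real data; the synthetic
#' generator needs neither.  Detrending removes a per-column linear trend.
#' The band-pass is a zero-phase frequency-domain filter with a
#' fourth-order Butterworth magnitude response, applied per column.
#'
#' @param ts T x N time-series matrix.
#' @param detrend Remove per-column linear trend (default TRUE).
#' @param band Numeric c(low, high) in Hz, or NULL for no filtering.
#' @param tr Repetition time in seconds (sampling interval); required when
#'   \code{band} is given.
#' @param order Butterworth order (default 4).
#' @return Filtered matrix of the same dimensions.
#' @export
preprocess_timeseries <- function(ts, detrend = TRUE, band = NULL, tr = NULL,
                                  order = 4L) {
  ts <- as.matrix(ts)
  nt <- nrow(ts)
  if (nt < 3L) stop("need at least 3 time points")
  if (detrend) {
    tt <- seq_len(nt)
    ts <- apply(ts, 2L, function(col) stats::residuals(stats::lm.fit(
      cbind(1, tt), col)))
    ts <- matrix(ts, nrow = nt)
  }
  if (!is.null(band)) {
    if (is.null(tr) || tr <= 0) stop("tr (seconds) must be positive when filtering")
    low <- band[1L]; high <- band[2L]
    nyq <- 1 / (2 * tr)
    if (!(low >= 0 && low < high && high < nyq))
      stop("band must satisfy 0 <= low < high < Nyquist (", signif(nyq, 4), " Hz)")
    freqs <- (seq_len(nt) - 1L) / (nt * tr)
    freqs <- pmin(freqs, 1 / tr - freqs)      # two-sided spectrum
    h <- rep(1, nt)
    if (low > 0) h <- h / sqrt(1 + (low / pmax(freqs, 1e-12))^(2 * order))
    h <- h / sqrt(1 + (freqs / high)^(2 * order))
    ts <- apply(ts, 2L, function(col) Re(stats::fft(stats::fft(col) * h,
                                                    inverse = TRUE)) / nt)
    ts <- matrix(ts, nrow = nt)
  }
  ts
}

#' Pearson connectivity matrix with negative correlations zeroed
#'
#' Computes the Pearson correlation of every ROI pair, sets negative
#' correlations to zero (negative functional correlations are of ambiguous
#' interpretation and are excluded from the network), and forces a zero
#' diagonal.  The result is the subject's weighted functional network.
#'
#' @param ts T x N time-series matrix (columns = ROIs).
#' @return N x N symmetric matrix of edge weights in [0, 1], zero diagonal.
#' @export
compute_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points")
  if (any(!is.finite(ts))) stop("time series contain non-finite values")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("zero-variance ROI column(s): ", paste(bad, collapse = ", "))
  }
  w <- stats::cor(ts)
  w[w < 0] <- 0
  diag(w) <- 0
  # guard against floating-point spill just above 1
  w[w > 1] <- 1
  w
}

#' Sparsity threshold grid
#'
#' @param s_min,s_max,step Grid bounds and step; defaults 0.02, 0.5, 0.01
#'   give the standard 49-value grid.
#' @return Numeric vector of strictly increasing sparsity values in (0, 1].
#' @export
sparsity_grid <- function(s_min = 0.02, s_max = 0.5, step = 0.01) {
  g <- round(seq(s_min, s_max, by = step), 10)
  if (any(g <= 0) || any(g > 1)) stop("sparsity values must lie in (0, 1]")
  g
}

#' Binarize a connectivity matrix at one sparsity level
#'
#' Retains the k = round(s * M) strongest positive edges of the M =
#' N(N-1)/2 candidates (half-up rounding; ties at the cutoff broken by
#' lexicographic (i, j) order so the result is deterministic).  If fewer
#' than k positive edges exist, all positive edges are kept and a warning
#' is raised.
#'
#' @param conn N x N nonnegative symmetric connectivity matrix.
#' @param s Sparsity in (0, 1].
#' @return N x N binary adjacency matrix with attribute \code{"sparsity"}.
#' @export
binarize_at_sparsity <- function(conn, s) {
  if (s <= 0 || s > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(conn)
  ord <- edge_rank_order(conn)
  m_possible <- n * (n - 1L) / 2L
  k <- round_half_up(s * m_possible)
  w <- edge_vector(conn)
  n_pos <- sum(w > 0)
  if (n_pos < k) {
    warning(sprintf("only %d positive edges available for k = %d; keeping all",
                    n_pos, k))
    k <- n_pos
  }
  keep <- ord[seq_len(k)]
  adj <- edge_vector_to_matrix(as.numeric(seq_along(w) %in% keep), n)
  dimnames(adj) <- dimnames(conn)
  attr(adj, "sparsity") <- s
  adj
}

# fixed edge ordering: decreasing weight, ties by (i, j) lexicographic
edge_rank_order <- function(conn) {
  map <- edge_index_map(nrow(conn))
  w <- conn[cbind(map$i, map$j)]
  order(-w, map$i, map$j)
}

#' Binarize across the whole sparsity grid
#'
#' Because all thresholds share one fixed edge ranking, the edge sets are
#' nested: the network at a lower sparsity is a subgraph of the network at
#' any higher sparsity.
#'
#' @param conn Connectivity matrix.
#' @param grid Output of [sparsity_grid()].
#' @return Named list of binary adjacency matrices, one per threshold.
#' @export
threshold_series <- function(conn, grid = sparsity_grid()) {
  n <- nrow(conn)
  map <- edge_index_map(n)
  ord <- edge_rank_order(conn)
  w <- conn[cbind(map$i, map$j)]
  n_pos <- sum(w > 0)
  m_possible <- nrow(map)
  out <- lapply(grid, function(s) {
    k <- round_half_up(s * m_possible)
    if (n_pos < k) {
      warning(sprintf("sparsity %.3f: only %d positive edges for k = %d",
                      s, n_pos, k))
      k <- n_pos
    }
    v <- numeric(m_possible)
    v[ord[seq_len(k)]] <- 1
    adj <- edge_vector_to_matrix(v, n)
    dimnames(adj) <- dimnames(conn)
    attr(adj, "sparsity") <- s
    adj
  })
  names(out) <- formatC(grid, format = "f", digits = 3)
  out
}
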