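#' Group comparison of global metric AUC features
#'
#' Two-sample pooled-variance t-test per global metric with
#' Benjamini-Hochberg false-discovery-rate adjustment across the tested
#' family (the 7 global metrics).  The direction reports the sign of
#' (positive-group mean minus negative-group mean).
#'
#' @param global_x Subjects x metrics matrix of AUC features.
#' @param labels +1/-1 labels.
#' @param q_threshold Significance level on the adjusted q (default 0.05).
#' @return data.frame: metric, mean_pos, mean_neg, direction, t, p, q,
#'   significant.  Zero-variance metrics are excluded from the family and
#'   flagged with NA statistics.
#' @export
compare_global_metrics <- function(global_x, labels, q_threshold = 0.05) {
  stopifnot(nrow(global_x) == length(labels))
  if (sum(labels == 1) < 2L || sum(labels == -1) < 2L)
    stop("need >= 2 subjects per group")
  metrics <- colnames(global_x) %||% paste0("metric", seq_len(ncol(global_x)))
  res <- lapply(seq_len(ncol(global_x)), function(k) {
    a <- global_x[labels == 1, k]
    b <- global_x[labels == -1, k]
    if (stats::sd(c(a, b)) == 0 || any(!is.finite(c(a, b)))) {
      return(data.frame(metric = metrics[k], mean_pos = mean(a),
                        mean_neg = mean(b), direction = 0,
                        t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(metric = metrics[k], mean_pos = mean(a), mean_neg = mean(b),
               direction = sign(mean(a) - mean(b)),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  testable <- !is.na(out$p)
  if (any(!testable)) warning("zero-variance metric(s) excluded from FDR family")
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out
}

#' Group comparison of nodal metric AUC features
#'
#' Per-node two-sample t-tests with Benjamini-Hochberg adjustment applied
#' within each nodal metric (one 90-node family per metric).
#'
#' @param nodal_x Subjects x (n_roi * n_metrics) matrix; columns grouped
#'   by ROI in blocks of \code{length(metric_names)}.
#' @param labels +1/-1 labels.
#' @param metric_names Names of the per-ROI metric columns.
#' @param q_threshold Significance level (default 0.05).
#' @return data.frame: roi, metric, direction, t, p, q, significant.
#' @export
compare_nodal_metrics <- function(nodal_x, labels,
                                  metric_names = NODAL_METRICS,
                                  q_threshold = 0.05) {
  n_metric <- length(metric_names)
  n_roi <- ncol(nodal_x) / n_metric
  stopifnot(n_roi == round(n_roi))
  roi <- rep(seq_len(n_roi), each = n_metric)
  metric <- rep(metric_names, times = n_roi)
  a <- nodal_x[labels == 1, , drop = FALSE]
  b <- nodal_x[labels == -1, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2L, stats::var); v2 <- apply(b, 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), n1 + n2 - 2)
  out <- data.frame(roi = roi, metric = metric,
                    direction = sign(m1 - m2), t = tstat, p = p,
                    q = NA_real_)
  for (mm in metric_names) {
    sel <- out$metric == mm & !is.na(out$p)
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$significant <- !is.na(out$q) & out$q < q_threshold
  rownames(out) <- NULL
  out
}
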