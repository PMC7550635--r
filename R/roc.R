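#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen positive subject's score exceeds a
#' randomly chosen negative subject's, ties counted one half; equal to
#' the area under the empirical ROC curve.
#'
#' @param scores Real-valued scores (larger = more positive-like).
#' @param labels +1/-1 labels.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# per-subject placement values: for each positive, the fraction of
# negatives it outranks (ties 1/2), and vice versa
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  v10 <- vapply(pos, function(s)
    mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s)
    mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same subjects
#' using the DeLong placement-value covariance estimator; the difference
#' divided by its standard error is referred to a standard normal
#' (two-sided).
#'
#' @param scores1,scores2 Score vectors on the same subjects.
#' @param labels +1/-1 labels.
#' @return List: \code{auc1}, \code{auc2}, \code{var_diff}, \code{z},
#'   \code{p}.  Identical score vectors give z = 0, p = 1 by convention.
#' @export
delong_test <- function(scores1, scores2, labels) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(labels))
  if (!any(labels == 1) || !any(labels == -1))
    stop("both classes must be present")
  p1 <- delong_placements(scores1, labels)
  p2 <- delong_placements(scores2, labels)
  if (identical(scores1, scores2))
    return(list(auc1 = p1$auc, auc2 = p2$auc, var_diff = 0, z = 0, p = 1))
  m <- length(p1$v10); n <- length(p1$v01)
  s10 <- stats::var(p1$v10 - p2$v10)
  s01 <- stats::var(p1$v01 - p2$v01)
  var_diff <- s10 / m + s01 / n
  d <- p1$auc - p2$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12)
      return(list(auc1 = p1$auc, auc2 = p2$auc, var_diff = 0, z = 0, p = 1))
    stop("zero DeLong variance with unequal AUCs")
  }
  z <- d / sqrt(var_diff)
  list(auc1 = p1$auc, auc2 = p2$auc, var_diff = var_diff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
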