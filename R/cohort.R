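#' Specify a synthetic two-group cohort of regional time series
#'
#' Describes a stationary multivariate-Gaussian cohort whose population
#' correlation structure carries a block-community ("module") organisation,
#' with a planted group difference concentrated on a designated set of
#' edges.  The defaults emulate a small clinical resting-state fMRI study:
#' 22 patient-like and 20 control-like subjects, 90 regions, 230 usable
#' time points.
#'
#' @param n_group_pos Number of patient-like subjects (label +1).
#' @param n_group_neg Number of control-like subjects (label -1).
#' @param n_roi Number of regions (network nodes).
#' @param n_timepoints Time points per subject.
#' @param module_sizes Integer vector partitioning the ROIs into
#'   communities; must sum to \code{n_roi}.  Default: six near-equal
#'   modules, the scale of canonical resting-state networks.
#' @param within_module_weight Population correlation between two ROIs of
#'   the same module (dimensionless, default 0.4).
#' @param between_module_weight Population correlation between ROIs of
#'   different modules (default 0.05).
#' @param effect_edges Two-column matrix (or data.frame) of ROI index
#'   pairs (1-based, i != j) carrying the group effect, or \code{NULL}.
#' @param effect_delta Signed correlation change added on each effect edge
#'   in the positive group.
#' @param noise_sd Standard deviation of i.i.d. observation noise added to
#'   each sample (signal has unit variance).
#' @param ar_phi Optional AR(1) temporal smoothing coefficient in [0, 1);
#'   0 (default) draws temporally independent rows.
#' @param seed Master RNG seed; per-subject seeds are derived from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_group_pos = 22L, n_group_neg = 20L,
                        n_roi = 90L, n_timepoints = 230L,
                        module_sizes = NULL,
                        within_module_weight = 0.4,
                        between_module_weight = 0.05,
                        effect_edges = NULL, effect_delta = 0,
                        noise_sd = 0.5, ar_phi = 0, seed = 1L) {
  if (is.null(module_sizes)) {
    k <- min(6L, n_roi)
    cuts <- round(seq(0, n_roi, length.out = k + 1L))
    module_sizes <- as.integer(diff(cuts))
  }
  if (sum(module_sizes) != n_roi)
    stop("module_sizes must sum to n_roi")
  if (!is.null(effect_edges)) {
    effect_edges <- as.matrix(effect_edges)
    storage.mode(effect_edges) <- "integer"
    if (ncol(effect_edges) != 2L || any(effect_edges[, 1L] == effect_edges[, 2L]))
      stop("effect_edges must be two-column pairs with i != j")
    if (any(effect_edges < 1L) || any(effect_edges > n_roi))
      stop("effect_edges indices out of range")
    # canonical unordered form i < j
    effect_edges <- t(apply(effect_edges, 1L, sort))
    effect_edges <- unique(effect_edges)
  }
  if (n_group_pos < 1L || n_group_neg < 1L) stop("both groups need >= 1 subject")
  if (ar_phi < 0 || ar_phi >= 1) stop("ar_phi must be in [0, 1)")
  if (n_timepoints < n_roi)
    warning("n_timepoints < n_roi: sample correlation matrices will be rank-deficient")
  structure(list(
    n_group_pos = as.integer(n_group_pos), n_group_neg = as.integer(n_group_neg),
    n_roi = as.integer(n_roi), n_timepoints = as.integer(n_timepoints),
    module_sizes = as.integer(module_sizes),
    within_module_weight = within_module_weight,
    between_module_weight = between_module_weight,
    effect_edges = effect_edges, effect_delta = effect_delta,
    noise_sd = noise_sd, ar_phi = ar_phi, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Module assignment implied by a cohort specification
#' @param spec A [cohort_spec()].
#' @return Integer vector of length \code{n_roi} mapping each ROI to its module.
#' @export
module_assignment <- function(spec) {
  rep.int(seq_along(spec$module_sizes), spec$module_sizes)
}

#' Build the population correlation matrix for one group
#'
#' The base matrix is block structured: \code{within_module_weight} inside
#' module blocks, \code{between_module_weight} elsewhere, unit diagonal.
#' For the positive group, \code{effect_delta} is added on each effect
#' edge; if the result is not positive definite it is repaired by adding
#' \code{(|lambda_min| + 1e-6) I} and rescaling back to unit diagonal.
#' The repair slightly shrinks all off-diagonal entries, so the realised
#' (post-repair) deltas are what the ground truth records.
#'
#' @param spec A [cohort_spec()].
#' @param group Either \code{"pos"} or \code{"neg"}.
#' @return Symmetric positive-definite correlation matrix (unit diagonal).
#' @export
build_population_covariance <- function(spec, group = c("pos", "neg")) {
  group <- match.arg(group)
  mods <- module_assignment(spec)
  n <- spec$n_roi
  sigma <- matrix(spec$between_module_weight, n, n)
  same <- outer(mods, mods, "==")
  sigma[same] <- spec$within_module_weight
  diag(sigma) <- 1
  if (group == "pos" && !is.null(spec$effect_edges) && spec$effect_delta != 0) {
    for (r in seq_len(nrow(spec$effect_edges))) {
      i <- spec$effect_edges[r, 1L]; j <- spec$effect_edges[r, 2L]
      sigma[i, j] <- sigma[i, j] + spec$effect_delta
      sigma[j, i] <- sigma[i, j]
    }
    if (any(abs(sigma[upper.tri(sigma)]) > 1))
      stop("effect_delta pushes a correlation outside [-1, 1]; reduce |effect_delta|")
  }
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    sigma <- sigma + (abs(ev_min) + 1e-6) * diag(n)
    sigma <- stats::cov2cor(sigma)
  }
  rownames(sigma) <- colnames(sigma) <- paste0("ROI_", seq_len(n))
  sigma
}

#' Simulate one subject's regional time series
#'
#' Draws \code{n_timepoints} rows from a zero-mean multivariate normal
#' with the given covariance (optionally AR(1)-smoothed in time while
#' preserving the stationary covariance) and adds independent Gaussian
#' observation noise.  Deterministic given \code{seed}.
#'
#' @param cov Symmetric positive-definite covariance matrix.
#' @param n_timepoints Number of rows to draw.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Integer seed.
#' @param ar_phi AR(1) coefficient in [0, 1); default 0.
#' @return \code{n_timepoints x n} matrix; column names taken from \code{cov}.
#' @export
simulate_subject <- function(cov, n_timepoints, noise_sd = 0, seed = 1L,
                             ar_phi = 0) {
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance is not positive definite"))
  n <- ncol(cov)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  x <- z %*% ch
  if (ar_phi > 0) {
    # x_t = phi x_{t-1} + sqrt(1 - phi^2) e_t keeps the stationary covariance
    s <- sqrt(1 - ar_phi^2)
    for (t in 2:n_timepoints) x[t, ] <- ar_phi * x[t - 1L, ] + s * x[t, ]
  }
  if (noise_sd > 0)
    x <- x + noise_sd * matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  colnames(x) <- colnames(cov)
  x
}

#' Generate a full synthetic cohort
#'
#' Simulates all subjects of a [cohort_spec()], optionally writing each
#' time series as TSV plus a manifest CSV and a ground-truth JSON to
#' \code{dir}.  Per-subject seeds are derived deterministically from
#' \code{spec$seed}, so any subject can be regenerated independently.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory, or \code{NULL} (default) to keep
#'   everything in memory.
#' @return List with elements \code{manifest} (data.frame: subject_id,
#'   path, label, group_name), \code{timeseries} (named list of matrices),
#'   and \code{ground_truth} (population covariances, differential edge
#'   set, module assignment, spec echo).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  cov_pos <- build_population_covariance(spec, "pos")
  cov_neg <- build_population_covariance(spec, "neg")
  # differential edges = where the two post-repair covariances disagree
  diff_mask <- abs(cov_pos - cov_neg) > 1e-12
  map <- edge_index_map(spec$n_roi)
  diff_edges <- map[diff_mask[cbind(map$i, map$j)], , drop = FALSE]

  n_tot <- spec$n_group_pos + spec$n_group_neg
  labels <- c(rep(1L, spec$n_group_pos), rep(-1L, spec$n_group_neg))
  ids <- sprintf("sub%03d", seq_len(n_tot))
  ts <- vector("list", n_tot)
  names(ts) <- ids
  for (k in seq_len(n_tot)) {
    sigma <- if (labels[k] == 1L) cov_pos else cov_neg
    ts[[k]] <- simulate_subject(sigma, spec$n_timepoints, spec$noise_sd,
                                seed = derive_seed(spec$seed, k),
                                ar_phi = spec$ar_phi)
  }
  manifest <- data.frame(
    subject_id = ids,
    path = NA_character_,
    label = labels,
    group_name = ifelse(labels == 1L, "pos", "neg"),
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    cov_pos = cov_pos, cov_neg = cov_neg,
    differential_edges = as.matrix(diff_edges),
    module_assignment = module_assignment(spec),
    spec = unclass(spec)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_tot)) {
      p <- file.path(dir, paste0(ids[k], ".tsv"))
      write_timeseries(ts[[k]], p)
      manifest$path[k] <- p
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    gt_json <- list(
      differential_edges_0based = unname(ground_truth$differential_edges - 1L),
      module_assignment = ground_truth$module_assignment,
      spec = lapply(unclass(spec), function(x)
        if (is.matrix(x)) unname(x) else unname(x))
    )
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(manifest = manifest, timeseries = ts, ground_truth = ground_truth)
}

#' Write a time-series matrix as TSV (rows = time points, ROI header)
#' @param x Time-series matrix with ROI column names.
#' @param path Output file path.
#' @export
write_timeseries <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a time-series matrix written by [write_timeseries()]
#' @param path TSV path (header row of ROI names).
#' @return Numeric matrix, rows = time points.
#' @export
read_timeseries <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  as.matrix(x)
}

#' Read a cohort manifest CSV
#' @param path CSV with columns subject_id, path, label, group_name.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m
}
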