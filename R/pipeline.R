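#' Pipeline run configuration
#'
#' Bundles every tunable of the full analysis so a run is reproducible
#' from its config echo alone.
#'
#' @param s_min,s_max,s_step Sparsity grid (defaults 0.02, 0.5, 0.01).
#' @param alpha Edge t-test selection threshold (default 0.05).
#' @param lambda Group-LASSO penalty (default 1).
#' @param c_exponents Integer exponents of the SVM cost grid 2^e
#'   (default -5:5).
#' @param beta_step Kernel-weight simplex resolution (default 0.1).
#' @param n_random Null-model ensemble size per threshold (default 100).
#' @param seed Master seed (default 1).
#' @param positive_class Manifest label value treated as +1 (default 1).
#' @param fisher_rz Fisher r-to-z transform edge weights before the
#'   t-tests (default FALSE).
#' @param combinations Modality combinations to classify; default all 7.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(s_min = 0.02, s_max = 0.5, s_step = 0.01,
                       alpha = 0.05, lambda = 1, c_exponents = -5:5,
                       beta_step = 0.1, n_random = 100L, seed = 1L,
                       positive_class = 1, fisher_rz = FALSE,
                       combinations = list("C", "G", "N", c("C", "G"),
                                           c("C", "N"), c("G", "N"),
                                           c("C", "G", "N"))) {
  structure(list(s_min = s_min, s_max = s_max, s_step = s_step,
                 alpha = alpha, lambda = lambda, c_exponents = c_exponents,
                 beta_step = beta_step, n_random = as.integer(n_random),
                 seed = as.integer(seed), positive_class = positive_class,
                 fisher_rz = fisher_rz, combinations = combinations),
            class = "run_config")
}

combo_name <- function(m) paste(m, collapse = "+")

#' Run the full connectome classification pipeline
#'
#' Network construction, graph metrics over the sparsity grid, feature
#' selection, multi-kernel classification of every configured modality
#' combination, DeLong comparisons of all combination pairs, and
#' group-level metric comparisons with FDR correction.
#'
#' @param timeseries Named list of subject time-series matrices, or NULL
#'   to read them from \code{manifest$path}.
#' @param labels Subject labels (coerced to +1/-1 via
#'   \code{config$positive_class}).
#' @param config A [run_config()].
#' @param manifest Optional manifest data.frame (subject_id, path, label);
#'   used when \code{timeseries} is NULL.
#' @param out_dir Optional output directory for artifacts (TSV/CSV/JSON
#'   and a run log); NULL keeps everything in memory.
#' @param progress Print stage progress (default FALSE).
#' @return List of class \code{report_bundle}: \code{connectivity},
#'   \code{metrics} (global/nodal AUC tables), \code{results} (one
#'   \code{classification_result} per combination), \code{delong}
#'   (pairwise comparison table), \code{global_comparison},
#'   \code{nodal_comparison}, \code{hubs}, \code{config}.
#' @export
run_pipeline <- function(timeseries = NULL, labels = NULL,
                         config = run_config(), manifest = NULL,
                         out_dir = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  log_lines <- character(0)
  logit <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }
  if (is.null(timeseries)) {
    if (is.null(manifest)) stop("provide timeseries or a manifest")
    timeseries <- lapply(seq_len(nrow(manifest)), function(k) {
      p <- manifest$path[k]
      if (!file.exists(p))
        stop("cannot read time series for subject ", manifest$subject_id[k],
             ": ", p)
      read_timeseries(p)
    })
    names(timeseries) <- manifest$subject_id
    labels <- manifest$label
  }
  if (is.null(labels)) stop("labels are required")
  y <- ifelse(labels == config$positive_class, 1L, -1L)
  if (!is_binary_label(y)) stop("labels must yield two classes")
  n <- length(timeseries)
  ids <- names(timeseries) %||% sprintf("sub%03d", seq_len(n))
  grid <- sparsity_grid(config$s_min, config$s_max, config$s_step)

  logit("stage connectivity: %d subjects", n)
  conns <- lapply(seq_len(n), function(k) {
    tryCatch(compute_connectivity(timeseries[[k]]),
             error = function(e) stop("stage connectivity, subject ",
                                      ids[k], ": ", conditionMessage(e)))
  })
  names(conns) <- ids
  n_roi <- nrow(conns[[1]])

  logit("stage metrics: %d thresholds, %d null graphs", length(grid),
        config$n_random)
  mets <- lapply(seq_len(n), function(k) {
    tryCatch(subject_metrics(conns[[k]], grid, n_random = config$n_random,
                             seed = derive_seed(config$seed, k)),
             error = function(e) stop("stage metrics, subject ", ids[k],
                                      ": ", conditionMessage(e)))
  })
  global_x <- do.call(rbind, lapply(mets, `[[`, "auc_global"))
  rownames(global_x) <- ids
  nodal_x <- do.call(rbind, lapply(mets, function(m) as.vector(t(m$auc_nodal))))
  rownames(nodal_x) <- ids
  nodal_groups <- rep(seq_len(n_roi), each = length(NODAL_METRICS))
  edge_x <- edge_feature_table(conns)

  logit("stage comparisons")
  global_cmp <- compare_global_metrics(global_x, y)
  nodal_cmp <- compare_nodal_metrics(nodal_x, y)
  deg_cols <- which(rep(NODAL_METRICS, n_roi) == "degree")
  deg_auc <- nodal_x[, deg_cols, drop = FALSE]
  hubs <- list(
    pos = identify_hubs(colMeans(deg_auc[y == 1, , drop = FALSE])),
    neg = identify_hubs(colMeans(deg_auc[y == -1, , drop = FALSE])))

  results <- list()
  for (combo in config$combinations) {
    logit("stage classification: %s", combo_name(combo))
    results[[combo_name(combo)]] <- mkl_nested_loocv(
      edge_x = edge_x, global_x = global_x, nodal_x = nodal_x,
      nodal_groups = nodal_groups, labels = y, modalities = combo,
      alpha = config$alpha, lambda = config$lambda,
      c_grid = 2^config$c_exponents, beta_step = config$beta_step,
      fisher_rz = config$fisher_rz)
  }

  combos <- names(results)
  delong <- NULL
  if (length(combos) >= 2L) {
    pairs <- utils::combn(combos, 2L)
    delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      dl <- delong_test(results[[a]]$decision, results[[b]]$decision, y)
      data.frame(combo1 = a, combo2 = b, auc1 = dl$auc1, auc2 = dl$auc2,
                 z = dl$z, p = dl$p)
    }))
  }
  logit("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- structure(list(
    subject_ids = ids, labels = y, connectivity = conns,
    metrics = list(global = global_x, nodal = nodal_x,
                   nodal_groups = nodal_groups, per_subject = mets),
    results = results, delong = delong,
    global_comparison = global_cmp, nodal_comparison = nodal_cmp,
    hubs = hubs, config = config, log = log_lines
  ), class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write pipeline artifacts to disk
#'
#' Connectivity TSVs, metric and comparison CSVs, a results JSON (with
#' the config echoed for provenance) and the run log.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "connectivity"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in bundle$subject_ids)
    utils::write.table(bundle$connectivity[[id]],
                       file.path(out_dir, "connectivity", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(subject_id = bundle$subject_ids,
                              bundle$metrics$global, check.names = FALSE),
                   file.path(out_dir, "global_auc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = bundle$subject_ids,
                              bundle$metrics$nodal, check.names = FALSE),
                   file.path(out_dir, "nodal_auc.csv"), row.names = FALSE)
  utils::write.csv(bundle$global_comparison,
                   file.path(out_dir, "global_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$nodal_comparison,
                   file.path(out_dir, "nodal_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$delong))
    utils::write.csv(bundle$delong, file.path(out_dir, "delong.csv"),
                     row.names = FALSE)
  js <- list(
    config = unclass(bundle$config),
    labels = bundle$labels,
    hubs = bundle$hubs,
    results = lapply(bundle$results, function(r) list(
      modalities = r$modalities,
      TP = r$TP, TN = r$TN, FP = r$FP, FN = r$FN,
      accuracy = r$accuracy, sensitivity = r$sensitivity,
      specificity = r$specificity, auc = r$auc,
      decision = r$decision, predicted = r$predicted,
      consensus_edges = r$consensus_edges,
      folds = lapply(r$folds, function(f)
        list(hold = f$hold, C = f$C, beta = as.list(f$beta))))))
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
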