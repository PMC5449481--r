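#' Per-cluster medians for one cell
#'
#' Parameter distributions are skewed and close to log-normal, so the median
#' (not the mean) characterises their central value.
#'
#' @param events Retained event table.
#' @param clustering Optional `density_result` for these events; when absent
#'   the whole cell is summarised as one cluster.
#' @return Data frame: `cluster`, `n`, `median_amplitude_pA`,
#'   `median_rise_10_90_ms`, `median_decay_ms`.
#' @export
summarize_cell <- function(events, clustering = NULL) {
  labels <- if (is.null(clustering)) rep(1L, nrow(events)) else clustering$labels
  do.call(rbind, lapply(sort(unique(labels)), function(k) {
    e <- events[labels == k, , drop = FALSE]
    data.frame(cluster = k, n = nrow(e),
               median_amplitude_pA = stats::median(e$amplitude_pA),
               median_rise_10_90_ms = stats::median(e$rise_10_90_ms),
               median_decay_ms = stats::median(e$decay_ms))
  }))
}

#' Pearson correlation with Student-t p-value
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need two vectors of equal length >= 3")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the ranks, with average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation `rho`.
#' @export
spearman_rho <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}

#' Bonferroni threshold for a family of correlation tests
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests in the family (e.g. 9 pairwise parameter
#'   correlations: 0.05/9 = 0.0056, i.e. 0.56%).
#' @return Per-test threshold `alpha / n_tests`.
#' @export
family_threshold <- function(alpha = 0.05, n_tests = 9) {
  if (alpha <= 0 || n_tests <= 0) stop("alpha and n_tests must be positive")
  alpha / n_tests
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration; all defaults are the standard
#' protocol values.
#'
#' @param preprocess A [preprocess_config()].
#' @param detection A [detection_config()].
#' @param fit A [fit_config()].
#' @param rules A [plausibility_rules()].
#' @param outlier An [outlier_screen_config()].
#' @param alpha Family-wise level for the stationarity gate.
#' @param n_params,n_cells Stationarity Bonferroni family factors.
#' @param exclude_segments Named list: per cell id, a list of
#'   `c(start_s, end_s)` intervals to drop (manual non-stationary stretches).
#' @param cluster_percentiles Swept dc percentiles.
#' @param min_cluster_share Minimum per-cluster share of points.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            detection = detection_config(),
                            fit = fit_config(),
                            rules = plausibility_rules(),
                            outlier = outlier_screen_config(),
                            alpha = 0.05, n_params = 3, n_cells = 1,
                            exclude_segments = list(),
                            cluster_percentiles = c(0.5, 1, 2, 4),
                            min_cluster_share = 0.05) {
  structure(list(preprocess = preprocess, detection = detection, fit = fit,
                 rules = rules, outlier = outlier, alpha = alpha,
                 n_params = n_params, n_cells = n_cells,
                 exclude_segments = exclude_segments,
                 cluster_percentiles = cluster_percentiles,
                 min_cluster_share = min_cluster_share),
            class = "pipeline_config")
}

#' Analyse one trace end to end
#'
#' preprocess -> robust threshold -> detection -> refractory rule -> model
#' fitting -> plausibility filter -> PCA outlier screen -> segment exclusion
#' -> stationarity gate -> (if stationary) density-peak clustering ->
#' per-cluster medians. Every stage's count is recorded; given the same
#' trace and configuration the result is deterministic.
#'
#' @param tr An `mepsc_trace` (raw).
#' @param config A [pipeline_config()].
#' @return An `mepsc_cell_result` list: `cell_id`, `group`, `counts` (named,
#'   non-increasing along the pipeline), `threshold_pA`, `events` (final
#'   table, with `cluster` labels when clustered), `rejected`,
#'   `stationarity`, `clustering` (`NULL` when the cell is non-stationary),
#'   `summary`, `log`.
#' @export
analyze_trace <- function(tr, config = pipeline_config()) {
  stopifnot(is_trace(tr))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  clean <- preprocess(tr, config$preprocess)
  thr <- robust_threshold(clean, config$detection)
  note("threshold %.3f pA (mean - %g trimmed SD)", thr, config$detection$k_sd)
  cand <- detect_events(clean, thr, edge_margin = config$detection$refractory)
  kept_cand <- enforce_refractory(cand, config$detection$refractory)
  fitted <- fit_events(clean, kept_cand, config$fit)
  pf <- plausibility_filter(fitted, config$rules)
  counts <- c(detected = nrow(cand), after_refractory = nrow(kept_cand),
              fit_converged = sum(fitted$fit_status == "ok"),
              plausible = nrow(pf$kept))

  events <- pf$kept
  pca <- NULL
  if (nrow(events) > config$outlier$n_components) {
    mat <- align_snippets(clean, events, config$fit)
    pca <- pca_outlier_removal(mat, config$outlier)
    events <- events[pca$kept_indices, , drop = FALSE]
    note("PCA outlier screen: removed %d of %d in %d iteration(s)",
         length(pca$removed_indices), nrow(pf$kept), pca$n_iterations)
  }
  counts["after_pca"] <- nrow(events)

  iv <- config$exclude_segments[[tr$cell_id]]
  if (!is.null(iv)) {
    events <- exclude_segments(events, iv)
    note("excluded %d configured segment(s)", length(iv))
  }
  counts["after_exclusion"] <- nrow(events)

  stat <- if (nrow(events) >= 3L)
    assess_cell(events, config$alpha, config$n_params, config$n_cells)
  else NULL
  if (!is.null(stat)) log <- c(log, stat$log)

  clustering <- NULL
  if (!is.null(stat) && stat$stationary) {
    clustering <- cluster_cell(events, config$cluster_percentiles,
                               config$min_cluster_share)
    events$cluster <- clustering$labels
    note("clustering: %d cluster(s) at dc percentile %g",
         clustering$n_clusters, clustering$dc_percentile)
  } else {
    note("cell not clustered (non-stationary or too few events)")
  }

  structure(list(cell_id = tr$cell_id, group = tr$group, counts = counts,
                 threshold_pA = as.numeric(thr), events = events,
                 rejected = pf$rejected, pca = pca, stationarity = stat,
                 clustering = clustering,
                 summary = if (nrow(events)) summarize_cell(events, clustering),
                 log = log),
            class = "mepsc_cell_result")
}

#' @export
print.mepsc_cell_result <- function(x, ...) {
  cat(sprintf("mepsc_cell_result: cell '%s'%s\n", x$cell_id,
              if (is.na(x$group)) "" else sprintf(" [%s]", x$group)))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$stationarity))
    cat(sprintf("  stationary: %s\n", x$stationarity$stationary))
  if (!is.null(x$clustering))
    cat(sprintf("  clusters: %d\n", x$clustering$n_clusters))
  invisible(x)
}

cell_result_row <- function(res) {
  data.frame(
    cell_id = res$cell_id, group = res$group,
    n_detected = unname(res$counts["detected"]),
    n_final = unname(res$counts["after_exclusion"]),
    stationary = if (is.null(res$stationarity)) NA else res$stationarity$stationary,
    n_clusters = if (is.null(res$clustering)) NA_integer_ else res$clustering$n_clusters,
    stringsAsFactors = FALSE)
}

#' Run the pipeline over a set of trace files
#'
#' Reads each delimited-text trace, analyses it with [analyze_trace()], and
#' (optionally) writes per-cell outputs: the final event table
#' (tab-delimited) and a JSON summary with stage counts, stationarity tests
#' and clustering. A failure on one cell is recorded and the run continues.
#'
#' @param paths Character vector of trace files, or a directory containing
#'   them.
#' @param config A [pipeline_config()].
#' @param output_dir Optional output directory for per-cell files and the
#'   cross-cell table.
#' @return A list: `results` (per-cell `mepsc_cell_result` or error message),
#'   `table` (cross-cell summary data frame), `errors` (named character).
#' @export
run_pipeline <- function(paths, config = pipeline_config(), output_dir = NULL) {
  if (length(paths) == 1L && (dir.exists(paths) || !file.exists(paths)))
    paths <- list.files(paths, pattern = "\\.(txt|tsv|csv)$", full.names = TRUE)
  if (!length(paths)) warning("no input traces found")
  results <- list()
  errors <- character(0)
  rows <- list()
  for (p in paths) {
    res <- tryCatch(analyze_trace(read_trace(p), config),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[p] <- res
      next
    }
    results[[res$cell_id]] <- res
    rows[[res$cell_id]] <- cell_result_row(res)
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(res$events,
                         file.path(output_dir, paste0(res$cell_id, "_events.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(cell_id = res$cell_id, group = res$group,
             counts = as.list(res$counts),
             threshold_pA = res$threshold_pA,
             stationary = if (!is.null(res$stationarity)) res$stationarity$stationary,
             n_clusters = if (!is.null(res$clustering)) res$clustering$n_clusters,
             cluster_medians = res$summary, log = res$log),
        file.path(output_dir, paste0(res$cell_id, "_summary.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), group = character(0),
               n_detected = integer(0), n_final = integer(0),
               stationary = logical(0), n_clusters = integer(0))
  rownames(table) <- NULL
  if (!is.null(output_dir) && nrow(table))
    utils::write.table(table, file.path(output_dir, "cells_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(results = results, table = table, errors = errors)
}
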