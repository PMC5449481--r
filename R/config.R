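#' Read a pipeline configuration from a key=value text file
#'
#' Plain-text format: `[section]` headers followed by `key = value` lines
#' (`#` comments allowed). Sections and keys mirror the constructor
#' arguments, e.g.
#'
#' ```
#' [preprocess]
#' highpass_fc = 5
#' notch_n_max = 80
#' [detection]
#' k_sd = 4
#' [stationarity]
#' alpha = 0.05
#' n_cells = 45
#' [clustering]
#' percentiles = 0.5, 1, 2, 4
#' min_cluster_share = 0.05
#' ```
#'
#' Unset keys keep their defaults.
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  vals <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    raw <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(raw, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!anyNA(num)) num else if (raw %in% c("true", "TRUE")) TRUE
      else if (raw %in% c("false", "FALSE")) FALSE else raw
    vals[[section]][[key]] <- val
  }
  build <- function(ctor, section) do.call(ctor, vals[[section]] %||% list())
  scalar <- function(section, key, default)
    (vals[[section]] %||% list())[[key]] %||% default
  pipeline_config(
    preprocess = build(preprocess_config, "preprocess"),
    detection = build(detection_config, "detection"),
    fit = build(fit_config, "fit"),
    rules = build(plausibility_rules, "plausibility"),
    outlier = build(outlier_screen_config, "outlier"),
    alpha = scalar("stationarity", "alpha", 0.05),
    n_params = scalar("stationarity", "n_params", 3),
    n_cells = scalar("stationarity", "n_cells", 1),
    cluster_percentiles = scalar("clustering", "percentiles", c(0.5, 1, 2, 4)),
    min_cluster_share = scalar("clustering", "min_cluster_share", 0.05))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
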