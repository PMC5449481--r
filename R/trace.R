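#' Construct a current trace
#'
#' A trace is a uniformly sampled whole-cell current recording in picoamperes
#' together with its sampling rate and cell metadata. All pipeline stages
#' accept and return this container.
#'
#' @param samples Numeric vector of current samples (pA). Inward synaptic
#'   currents are negative deflections.
#' @param sampling_rate Sampling rate in Hz.
#' @param cell_id Character identifier of the recorded cell.
#' @param group Optional group label (e.g. a cell class); carried through
#'   unchanged.
#' @return An object of class `mepsc_trace`: a list with elements `samples`,
#'   `sampling_rate`, `cell_id`, `group`.
#' @export
#' @examples
#' tr <- trace(rnorm(2000), sampling_rate = 20000, cell_id = "demo")
#' tr
trace <- function(samples, sampling_rate, cell_id = "cell", group = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         cell_id = as.character(cell_id),
         group = as.character(group)),
    class = "mepsc_trace")
}

#' @export
print.mepsc_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("mepsc_trace: cell '%s'%s, %d samples @ %g Hz (%.3f s)\n",
              x$cell_id,
              if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
              length(x$samples), x$sampling_rate, dur))
  cat(sprintf("  range [%.2f, %.2f] pA\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.mepsc_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param tr An `mepsc_trace`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_times <- function(tr) {
  stopifnot(inherits(tr, "mepsc_trace"))
  (seq_along(tr$samples) - 1) / tr$sampling_rate
}

is_trace <- function(x) inherits(x, "mepsc_trace")

#' Write a trace as delimited text
#'
#' The format is plain text: comment header lines
#' `# sampling_rate_hz=...`, `# cell_id=...`, `# group=...` followed by a
#' single column `current_pA`, one sample per line.
#'
#' @param tr An `mepsc_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(tr, path) {
  stopifnot(is_trace(tr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz=%.10g", tr$sampling_rate),
    sprintf("# cell_id=%s", tr$cell_id),
    sprintf("# group=%s", tr$group),
    "current_pA"), con)
  writeLines(format(tr$samples, digits = 10, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read a delimited-text trace
#'
#' @param path File written by [write_trace()] (or any file with the same
#'   header convention).
#' @return An `mepsc_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^#\\s*", key, "="), "", m[1L])
  }
  fs <- suppressWarnings(as.numeric(get_field("sampling_rate_hz")))
  if (is.na(fs)) stop("trace file is missing a sampling_rate_hz header: ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "" & body != "current_pA"]
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) stop("non-numeric samples in trace file: ", path)
  trace(samples, fs, cell_id = get_field("cell_id"), group = get_field("group"))
}
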