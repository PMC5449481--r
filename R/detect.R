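#' Event-detection configuration
#'
#' @param k_sd Threshold depth in trimmed SDs below the trimmed mean.
#' @param trim_low,trim_high Percentile bounds (0-100); only samples between
#'   them enter the mean/SD estimate, limiting artifact influence.
#' @param refractory Minimum spacing (ms) between retained event peaks;
#'   a candidate closer than this to the last retained one is removed, since
#'   its parameters would be biased by the preceding decay.
#' @return A `detection_config` list.
#' @export
detection_config <- function(k_sd = 4, trim_low = 1, trim_high = 99,
                             refractory = 3) {
  if (k_sd <= 0) stop("k_sd must be positive")
  if (!(trim_low >= 0 && trim_low < trim_high && trim_high <= 100))
    stop("need 0 <= trim_low < trim_high <= 100")
  if (refractory < 0) stop("refractory must be non-negative")
  structure(list(k_sd = k_sd, trim_low = trim_low, trim_high = trim_high,
                 refractory = refractory),
            class = "detection_config")
}

#' Robust detection threshold
#'
#' Threshold = trimmed mean minus `k_sd` trimmed SDs, where the trim keeps
#' samples whose values lie between the `trim_low` and `trim_high`
#' percentiles of the trace (linear-interpolation percentile convention).
#'
#' @param tr An `mepsc_trace` (preprocessed).
#' @param config A [detection_config()].
#' @return Threshold in pA. If the trace is degenerate (zero trimmed SD) the
#'   threshold equals the mean and the result carries attribute
#'   `degenerate = TRUE`.
#' @export
robust_threshold <- function(tr, config = detection_config()) {
  stopifnot(is_trace(tr))
  x <- tr$samples
  if (length(x) < 100L) stop("need at least 100 samples for a threshold")
  q <- stats::quantile(x, c(config$trim_low, config$trim_high) / 100,
                       names = FALSE, type = 7)
  trimmed <- x[x >= q[1L] & x <= q[2L]]
  m <- mean(trimmed)
  s <- stats::sd(trimmed)
  if (!is.finite(s) || s == 0) {
    thr <- m
    attr(thr, "degenerate") <- TRUE
    return(thr)
  }
  m - config$k_sd * s
}

#' Detect candidate events by threshold crossing
#'
#' One candidate per maximal contiguous run of samples below `threshold`;
#' the candidate peak is the minimum sample of the run. Candidates whose
#' excursion touches the first or last `edge_margin` ms of the record are
#' dropped (incomplete snippets cannot be fitted).
#'
#' @param tr An `mepsc_trace` (preprocessed).
#' @param threshold Detection threshold (pA), e.g. from [robust_threshold()].
#' @param edge_margin Edge exclusion window (ms).
#' @return A data frame of candidates ordered by peak time: `peak_time_s`,
#'   `peak_pA`, `onset_idx`, `offset_idx`, `peak_idx`.
#' @export
detect_events <- function(tr, threshold, edge_margin = 3) {
  stopifnot(is_trace(tr))
  x <- tr$samples
  fs <- tr$sampling_rate
  below <- x < as.numeric(threshold)
  empty <- data.frame(peak_time_s = numeric(0), peak_pA = numeric(0),
                      onset_idx = integer(0), offset_idx = integer(0),
                      peak_idx = integer(0))
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  peak_idx <- mapply(function(a, b) a - 1L + which.min(x[a:b]), starts, ends)
  out <- data.frame(peak_time_s = (peak_idx - 1L) / fs,
                    peak_pA = x[peak_idx],
                    onset_idx = starts, offset_idx = ends,
                    peak_idx = as.integer(peak_idx))
  margin_samples <- edge_margin / 1000 * fs
  ok <- out$onset_idx > margin_samples &
    out$offset_idx <= length(x) - margin_samples
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enforce the refractory rule on candidates
#'
#' Sequential scan in time order: a candidate is removed when its peak falls
#' less than `refractory` ms after the peak of the last retained candidate.
#' Comparing to the last *retained* event preserves the first event of a
#' burst, the one whose decay is uncontaminated.
#'
#' @param candidates Candidate table from [detect_events()], time-ordered.
#' @param refractory Minimum peak spacing (ms).
#' @return The retained subset of `candidates`.
#' @export
enforce_refractory <- function(candidates, refractory = 3) {
  n <- nrow(candidates)
  if (n <= 1L || refractory <= 0) return(candidates)
  t <- candidates$peak_time_s
  if (is.unsorted(t)) stop("candidates must be ordered by peak time")
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- t[1L]
  for (i in 2L:n) {
    if ((t[i] - last) * 1000 >= refractory) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
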