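#' Plausibility rules for fitted events
#'
#' Bounds selecting correctly fitted, biologically plausible events:
#' `R^2 > 0.3`, `0.1 < Decay < 15` ms, `0.05 < 10-90% rise time < 10` ms,
#' `Amplitude < 200` pA. All bounds are strict inequalities; boundary events
#' are vanishingly rare in practice.
#'
#' @param r2_min Minimum coefficient of determination.
#' @param decay_min,decay_max Decay time-constant bounds (ms).
#' @param rise_min,rise_max 10-90% rise-time bounds (ms).
#' @param amplitude_max Maximum amplitude (pA).
#' @return A `plausibility_rules` list.
#' @export
plausibility_rules <- function(r2_min = 0.3, decay_min = 0.1, decay_max = 15,
                               rise_min = 0.05, rise_max = 10,
                               amplitude_max = 200) {
  if (decay_min >= decay_max || rise_min >= rise_max)
    stop("each interval needs min < max")
  structure(list(r2_min = r2_min, decay_min = decay_min, decay_max = decay_max,
                 rise_min = rise_min, rise_max = rise_max,
                 amplitude_max = amplitude_max),
            class = "plausibility_rules")
}

#' Filter fitted events by the plausibility rules
#'
#' Events must satisfy every rule strictly; each rejected event carries the
#' first violated rule as its reason (failed fits are rejected with their
#' fit status). The kept and rejected sets partition the input exactly.
#'
#' @param events Event table from [fit_events()].
#' @param rules A [plausibility_rules()].
#' @return A list: `kept` (event table), `rejected` (event table with an
#'   extra `reason` column).
#' @export
plausibility_filter <- function(events, rules = plausibility_rules()) {
  n <- nrow(events)
  reason <- rep(NA_character_, n)
  bad_fit <- events$fit_status != "ok"
  reason[bad_fit] <- events$fit_status[bad_fit]
  check <- function(fail, why) {
    hit <- is.na(reason) & fail
    reason[hit] <<- why
  }
  check(!(events$r2 > rules$r2_min), "r2 bound")
  check(!(events$decay_ms > rules$decay_min &
            events$decay_ms < rules$decay_max), "decay bound")
  check(!(events$rise_10_90_ms > rules$rise_min &
            events$rise_10_90_ms < rules$rise_max), "rise bound")
  check(!(events$amplitude_pA < rules$amplitude_max), "amplitude bound")
  kept <- events[is.na(reason), , drop = FALSE]
  rejected <- events[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Outlier-screen configuration
#'
#' @param sd_multiplier Removal band half-width in SDs of each component
#'   score (default 6).
#' @param n_components Number of leading principal components screened.
#' @param max_iterations Safety cap on screening iterations; one iteration
#'   typically suffices on clean data.
#' @return An `outlier_screen_config` list.
#' @export
outlier_screen_config <- function(sd_multiplier = 6, n_components = 2,
                                  max_iterations = 50) {
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive")
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(sd_multiplier = sd_multiplier,
                 n_components = as.integer(n_components),
                 max_iterations = as.integer(max_iterations)),
            class = "outlier_screen_config")
}

#' Extract the aligned snippet matrix for PCA screening
#'
#' One row per event, aligned at the fitted t0 (nearest sample) with a fixed
#' window equal to the fit window; events are positive deflections; samples
#' beyond the record bounds are zero-padded.
#'
#' @param tr Preprocessed `mepsc_trace`.
#' @param events Event table rows with `event_time_s` (fitted events).
#' @param config A [fit_config()] defining the window.
#' @return Numeric matrix, `nrow(events)` x window length.
#' @export
align_snippets <- function(tr, events, config = fit_config()) {
  stopifnot(is_trace(tr))
  fs <- tr$sampling_rate
  pre <- round(config$window_pre_ms / 1000 * fs)
  post <- round(config$window_post_ms / 1000 * fs)
  len <- pre + post + 1L
  n <- length(tr$samples)
  mat <- matrix(0, nrow(events), len)
  for (i in seq_len(nrow(events))) {
    ctr <- round(events$event_time_s[i] * fs) + 1L
    idx <- (ctr - pre):(ctr + post)
    ok <- idx >= 1L & idx <= n
    mat[i, ok] <- -tr$samples[idx[ok]]
  }
  mat
}

#' Iterated principal-component outlier removal
#'
#' PCA is applied to the matrix of event time signals (one event per row,
#' time points as variables, mean-centered per time point, no variance
#' scaling). Events whose score on at least one of the first
#' `n_components` components lies strictly beyond the component mean
#' +/- `sd_multiplier` SD are removed, and the analysis is iterated on the
#' remaining events until no new event is selected.
#'
#' @param snippet_matrix Matrix from [align_snippets()].
#' @param config An [outlier_screen_config()].
#' @return A list: `kept_indices`, `removed_indices` (row indices of the
#'   input matrix), `n_iterations`.
#' @export
pca_outlier_removal <- function(snippet_matrix, config = outlier_screen_config()) {
  n <- nrow(snippet_matrix)
  if (n <= config$n_components) {
    warning("fewer snippets than screened components; outlier screen skipped")
    return(list(kept_indices = seq_len(n), removed_indices = integer(0),
                n_iterations = 0L))
  }
  active <- seq_len(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    k <- min(config$n_components, length(active) - 1L, ncol(snippet_matrix))
    pc <- stats::prcomp(snippet_matrix[active, , drop = FALSE],
                        center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
    out <- rep(FALSE, length(active))
    for (j in seq_len(ncol(scores))) {
      m <- mean(scores[, j])
      s <- stats::sd(scores[, j])
      out <- out | abs(scores[, j] - m) > config$sd_multiplier * s
    }
    if (!any(out) || iter >= config$max_iterations) break
    active <- active[!out]
    if (length(active) <= config$n_components) break
  }
  list(kept_indices = active,
       removed_indices = setdiff(seq_len(n), active),
       n_iterations = iter)
}
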