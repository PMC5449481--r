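#' Fitting configuration
#'
#' @param window_pre_ms Snippet length before the detected peak (ms). Must
#'   accommodate the longest plausible rise (10 ms 10-90% bound).
#' @param window_post_ms Snippet length after the peak (ms); accommodates
#'   decays up to the 15 ms plausibility bound.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return A `fit_config` list.
#' @export
fit_config <- function(window_pre_ms = 5, window_post_ms = 25, max_iter = 200) {
  if (window_pre_ms <= 0 || window_post_ms <= 0) stop("windows must be positive")
  structure(list(window_pre_ms = window_pre_ms, window_post_ms = window_post_ms,
                 max_iter = as.integer(max_iter)),
            class = "fit_config")
}

#' Piecewise mEPSC model waveform
#'
#' Four-parameter event model: zero before the onset, a linear ramp from 0 to
#' `amplitude` over the `rise` interval ending at `t0` (the time of maximum
#' amplitude), then exponential decay with time constant `decay`:
#' \deqn{EPSC(t) = A (t - t_0 + R)/R \textrm{ for } t_0 - R < t \le t_0;
#'       \quad A e^{-(t - t_0)/D} \textrm{ for } t > t_0.}
#' The waveform is continuous at `t0` and written as a positive deflection;
#' recorded inward currents are its negation.
#'
#' @param params List or named vector with `amplitude` (pA), `rise` (ms),
#'   `t0` (ms) and `decay` (ms); `rise` and `decay` must be positive.
#' @param t_ms Numeric vector of evaluation times (ms).
#' @return Model values at `t_ms` (pA).
#' @export
#' @examples
#' model_waveform(list(amplitude = 60, rise = 0.5, t0 = 5, decay = 2),
#'                seq(0, 20, by = 0.05))
model_waveform <- function(params, t_ms) {
  p <- as.list(params)
  if (p$rise <= 0 || p$decay <= 0) stop("rise and decay must be positive")
  v <- numeric(length(t_ms))
  ramp <- t_ms > (p$t0 - p$rise) & t_ms <= p$t0
  v[ramp] <- p$amplitude * (t_ms[ramp] - p$t0 + p$rise) / p$rise
  dec <- t_ms > p$t0
  v[dec] <- p$amplitude * exp(-(t_ms[dec] - p$t0) / p$decay)
  v
}

#' Initial parameter guess for one snippet
#'
#' From a positive-deflection snippet: amplitude from the peak sample, t0
#' from its time, rise from 1.25x the empirical 10-90% span of the rising
#' flank, decay from a log-linear regression of the post-peak tail down to
#' 20% of the peak.
#'
#' @param snippet Numeric vector, event as a positive deflection, baseline 0.
#' @param sampling_rate Hz.
#' @return A list: `ok` (logical), and on success `params` (amplitude, rise,
#'   t0, decay); on failure `reason`.
#' @export
initial_guess <- function(snippet, sampling_rate) {
  n <- length(snippet)
  dt <- 1000 / sampling_rate
  if (n < 5L || !all(is.finite(snippet)) || max(snippet) <= 0)
    return(list(ok = FALSE, reason = "no identifiable peak"))
  ipk <- which.max(snippet)
  peak <- snippet[ipk]
  if (ipk == 1L)
    return(list(ok = FALSE, reason = "no rising flank"))
  if (ipk == n)
    return(list(ok = FALSE, reason = "no decay tail"))
  t_ms <- (seq_len(n) - 1) * dt

  cross_before <- function(frac) {
    # last time before the peak at which the flank crosses frac*peak
    below <- which(snippet[1:ipk] <= frac * peak)
    if (!length(below)) return(t_ms[1L])
    j <- max(below)
    if (j == ipk) return(t_ms[ipk])
    # linear interpolation between samples j and j+1
    y0 <- snippet[j]; y1 <- snippet[j + 1L]
    t_ms[j] + (frac * peak - y0) / (y1 - y0) * dt
  }
  t10 <- cross_before(0.1)
  t90 <- cross_before(0.9)
  rise0 <- 1.25 * (t90 - t10)
  if (!is.finite(rise0) || rise0 <= 0) rise0 <- 2 * dt

  tail_idx <- which(seq_len(n) > ipk & snippet > 0.2 * peak)
  decay0 <- NA_real_
  if (length(tail_idx) >= 3L) {
    y <- log(snippet[tail_idx])
    x <- t_ms[tail_idx]
    slope <- stats::cov(x, y) / stats::var(x)
    if (is.finite(slope) && slope < 0) decay0 <- -1 / slope
  }
  if (!is.finite(decay0) || decay0 <= 0) {
    # fallback: time for the tail to fall to 1/e of the peak
    under <- which(seq_len(n) > ipk & snippet < exp(-1) * peak)
    decay0 <- if (length(under)) t_ms[min(under)] - t_ms[ipk] else 5 * dt
    if (decay0 <= 0) decay0 <- 5 * dt
  }
  list(ok = TRUE,
       params = list(amplitude = peak, rise = rise0, t0 = t_ms[ipk],
                     decay = decay0))
}

#' Fit one event snippet by Levenberg-Marquardt least squares
#'
#' Fits the four-parameter model of [model_waveform()] to a positive-going
#' snippet (baseline fixed at 0 after preprocessing; no offset parameter).
#' Goodness of fit is the coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` over the fit window; the 10-90% rise time is
#' `0.8 * Rise`, exact for a linear ramp. Parameters are bounded positive and
#' `t0` is confined to the snippet, which together with the single-exponential
#' decay avoids the multiple-local-minima pathology of double-exponential
#' event models.
#'
#' @param snippet Numeric vector, event as a positive deflection.
#' @param sampling_rate Hz.
#' @param config A [fit_config()].
#' @param init Optional initial parameter list; default [initial_guess()].
#' @return A one-row data frame: `amplitude_pA`, `rise_ms`, `t0_ms`,
#'   `decay_ms`, `rise_10_90_ms`, `r2`, `fit_status` (`"ok"` or a failure
#'   reason; failures are recorded, never silently dropped).
#' @export
fit_event <- function(snippet, sampling_rate, config = fit_config(),
                      init = NULL) {
  failure <- function(reason) data.frame(
    amplitude_pA = NA_real_, rise_ms = NA_real_, t0_ms = NA_real_,
    decay_ms = NA_real_, rise_10_90_ms = NA_real_, r2 = NA_real_,
    fit_status = reason, stringsAsFactors = FALSE)
  if (is.null(init)) {
    g <- initial_guess(snippet, sampling_rate)
    if (!g$ok) return(failure(g$reason))
    init <- g$params
  }
  n <- length(snippet)
  t_ms <- (seq_len(n) - 1) * 1000 / sampling_rate
  span <- t_ms[n]
  par0 <- pmin(pmax(unlist(init[c("amplitude", "rise", "t0", "decay")]),
                    c(1e-6, 1e-3, 0, 1e-3)),
               c(Inf, span, span, 1e3))
  resid_fn <- function(p) {
    model_waveform(list(amplitude = p[1L], rise = p[2L], t0 = p[3L],
                        decay = p[4L]), t_ms) - snippet
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       lower = c(1e-6, 1e-3, 0, 1e-3),
                       upper = c(1e4, span, span, 1e3),
                       control = minpack.lm::nls.lm.control(
                         maxiter = config$max_iter,
                         ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(failure("solver error"))
  if (!(fit$info %in% 1:4)) return(failure("solver non-convergence"))
  p <- fit$par
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((snippet - mean(snippet))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  data.frame(amplitude_pA = p[1L], rise_ms = p[2L], t0_ms = p[3L],
             decay_ms = p[4L], rise_10_90_ms = 0.8 * p[2L], r2 = r2,
             fit_status = "ok", stringsAsFactors = FALSE)
}

# Snippet bounds (sample indices) for one candidate: window_pre_ms before the
# peak to window_post_ms after, truncated at the record bounds, at the next
# candidate's onset, and at the previous candidate's offset (so a candidate
# riding the decay of its predecessor cannot re-fit the predecessor's peak).
snippet_bounds <- function(candidates, i, n_samples, fs, config) {
  pre <- round(config$window_pre_ms / 1000 * fs)
  post <- round(config$window_post_ms / 1000 * fs)
  i0 <- max(1L, candidates$peak_idx[i] - pre)
  i1 <- min(n_samples, candidates$peak_idx[i] + post)
  if (i > 1L) i0 <- max(i0, candidates$offset_idx[i - 1L] + 1L)
  if (i < nrow(candidates)) i1 <- min(i1, candidates$onset_idx[i + 1L] - 1L)
  c(i0, i1)
}

#' Fit all retained candidates of a trace
#'
#' Extracts a snippet around each candidate peak (negated so events are
#' positive), fits it with [fit_event()], and assembles the per-event table.
#'
#' @param tr Preprocessed `mepsc_trace`.
#' @param candidates Candidate table after [enforce_refractory()].
#' @param config A [fit_config()].
#' @return Data frame, one row per candidate: `event_time_s` (absolute fitted
#'   t0), the fitted parameters and `r2` as in [fit_event()], plus `peak_idx`,
#'   `snippet_start_idx` and `fit_status`.
#' @export
fit_events <- function(tr, candidates, config = fit_config()) {
  stopifnot(is_trace(tr))
  fs <- tr$sampling_rate
  n <- length(tr$samples)
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    b <- snippet_bounds(candidates, i, n, fs, config)
    snippet <- -tr$samples[b[1L]:b[2L]]
    row <- fit_event(snippet, fs, config)
    row$peak_idx <- candidates$peak_idx[i]
    row$snippet_start_idx <- b[1L]
    row$event_time_s <- (b[1L] - 1L) / fs + row$t0_ms / 1000
    rows[[i]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amplitude_pA = numeric(0), rise_ms = numeric(0),
               t0_ms = numeric(0), decay_ms = numeric(0),
               rise_10_90_ms = numeric(0), r2 = numeric(0),
               fit_status = character(0), peak_idx = integer(0),
               snippet_start_idx = integer(0), event_time_s = numeric(0))
  rownames(out) <- NULL
  out
}
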