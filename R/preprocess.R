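#' Preprocessing configuration
#'
#' Trace conditioning ahead of event detection: high-pass de-trending,
#' low-pass de-noising, and a cascade of band-stop filters removing mains
#' interference at `notch_base` Hz and its harmonics (stopbands
#' `k*notch_base +/- notch_halfwidth` Hz, `k = 1..notch_n_max`). All stages
#' are Butterworth filters of order `filter_order`, applied forward-backward
#' (zero phase) by default so that event timing is preserved.
#'
#' @param highpass_fc High-pass cutoff (Hz); removes DC and slow drift.
#' @param lowpass_fc Low-pass cutoff (Hz).
#' @param notch_base Mains fundamental (Hz).
#' @param notch_halfwidth Half-width of each stopband (Hz).
#' @param notch_n_max Highest harmonic index removed.
#' @param filter_order Butterworth order per stage. Kept low (default 2): a
#'   cascade of 80 narrow notches demands well-conditioned low-order stages.
#' @param zero_phase Apply each filter forward and backward.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(highpass_fc = 5, lowpass_fc = 4000,
                              notch_base = 50, notch_halfwidth = 1,
                              notch_n_max = 80, filter_order = 2,
                              zero_phase = TRUE) {
  if (!(highpass_fc > 0 && highpass_fc < lowpass_fc))
    stop("need 0 < highpass_fc < lowpass_fc")
  if (notch_base * notch_n_max > lowpass_fc)
    stop("notch cascade must not extend beyond lowpass_fc")
  if (notch_halfwidth <= 0 || notch_halfwidth >= notch_base / 2)
    stop("notch_halfwidth must lie in (0, notch_base/2)")
  if (filter_order < 1) stop("filter_order must be >= 1")
  structure(list(highpass_fc = highpass_fc, lowpass_fc = lowpass_fc,
                 notch_base = notch_base, notch_halfwidth = notch_halfwidth,
                 notch_n_max = as.integer(notch_n_max),
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

# Factor a transfer function (coefficients in increasing powers of z^-1)
# into real second-order sections plus a scalar gain. Direct high-order
# recursions with poles crowding the unit circle (narrow notches) lose
# precision; biquad cascades do not.
arma_to_sos <- function(b, a) {
  split_sections <- function(coefs) {
    n <- length(coefs) - 1L
    if (n <= 2L) return(list(gain = 1, sections = list(coefs)))
    r <- polyroot(coefs)
    used <- logical(n)
    sections <- list()
    ang <- abs(Arg(r))
    for (i in order(ang)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-8 * max(1, Mod(r[i]))) {
        j <- which(!used & abs(Im(r)) < 1e-8 * pmax(1, Mod(r)))[1L]
      } else {
        cand <- which(!used)
        j <- cand[which.min(Mod(r[cand] - Conj(r[i])))]
      }
      used[j] <- TRUE
      # (x - r_i)(x - r_j) with x = z^-1, constant term first
      sections[[length(sections) + 1L]] <-
        c(Re(r[i] * r[j]), -Re(r[i] + r[j]), 1)
    }
    list(gain = coefs[n + 1L], sections = sections)
  }
  nb <- split_sections(b)
  na <- split_sections(a)
  stopifnot(length(nb$sections) == length(na$sections))
  list(gain = nb$gain / na$gain,
       sos = Map(function(bs, as) list(b = bs, a = as),
                 nb$sections, na$sections))
}

# Apply one designed filter with odd-reflection padding of `npad` samples at
# each end (transients settle in the padding, not in the data), forward and
# optionally backward for zero phase. Filters above order 2 run as a cascade
# of second-order sections.
apply_filter <- function(x, flt, npad, zero_phase = TRUE) {
  n <- length(x)
  npad <- min(as.integer(npad), n - 1L)
  if (npad > 0L) {
    left <- 2 * x[1L] - x[(npad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(left, x, right)
  } else xp <- x
  dec <- arma_to_sos(flt$b, flt$a)
  run <- function(v) {
    for (s in dec$sos) v <- signal::filter(signal::Arma(b = s$b, a = s$a), v)
    v
  }
  y <- dec$gain * run(xp)
  if (zero_phase) y <- dec$gain * rev(run(rev(y)))
  as.numeric(y[(npad + 1L):(npad + n)])
}

check_nyquist <- function(fc, fs) {
  if (fc >= fs / 2)
    stop(sprintf("cutoff %g Hz is at or above the Nyquist frequency (%g Hz)",
                 fc, fs / 2))
}

#' High-pass de-trend a trace
#'
#' Removes the DC component and slow baseline drift with a Butterworth
#' high-pass filter.
#'
#' @param tr An `mepsc_trace`.
#' @param config A [preprocess_config()].
#' @return The filtered trace (same length).
#' @export
highpass_detrend <- function(tr, config = preprocess_config()) {
  stopifnot(is_trace(tr))
  fs <- tr$sampling_rate
  check_nyquist(config$highpass_fc, fs)
  flt <- signal::butter(config$filter_order, config$highpass_fc / (fs / 2),
                        type = "high")
  npad <- ceiling(6 * fs / config$highpass_fc)
  tr$samples <- apply_filter(tr$samples, flt, npad, config$zero_phase)
  tr
}

#' Low-pass de-noise a trace
#'
#' @inheritParams highpass_detrend
#' @return The filtered trace (same length).
#' @export
lowpass_denoise <- function(tr, config = preprocess_config()) {
  stopifnot(is_trace(tr))
  fs <- tr$sampling_rate
  check_nyquist(config$lowpass_fc, fs)
  flt <- signal::butter(config$filter_order, config$lowpass_fc / (fs / 2),
                        type = "low")
  npad <- ceiling(6 * fs / config$lowpass_fc) + 60L
  tr$samples <- apply_filter(tr$samples, flt, npad, config$zero_phase)
  tr
}

#' Remove mains interference and harmonics
#'
#' Applies one Butterworth band-stop filter per harmonic, sequentially
#' (a cascade of independent stages), with stopbands
#' `k*notch_base +/- notch_halfwidth` Hz for `k = 1..notch_n_max`.
#' Frequencies between the stopbands pass near unity.
#'
#' @inheritParams highpass_detrend
#' @return The filtered trace (same length).
#' @export
notch_cascade <- function(tr, config = preprocess_config()) {
  stopifnot(is_trace(tr))
  fs <- tr$sampling_rate
  top <- config$notch_n_max * config$notch_base + config$notch_halfwidth
  check_nyquist(top, fs)
  npad <- ceiling(fs / config$notch_halfwidth)
  x <- tr$samples
  for (k in seq_len(config$notch_n_max)) {
    band <- c(k * config$notch_base - config$notch_halfwidth,
              k * config$notch_base + config$notch_halfwidth) / (fs / 2)
    flt <- signal::butter(config$filter_order, band, type = "stop")
    x <- apply_filter(x, flt, npad, config$zero_phase)
  }
  tr$samples <- x
  tr
}

#' Condition a raw trace for event detection
#'
#' Composition, in fixed order: [highpass_detrend()], then
#' [lowpass_denoise()], then [notch_cascade()].
#'
#' @inheritParams highpass_detrend
#' @return The conditioned trace.
#' @export
#' @examples
#' rec <- render_recording(recording_spec(duration = 1, seed = 7))
#' clean <- preprocess(rec$trace)
preprocess <- function(tr, config = preprocess_config()) {
  tr <- highpass_detrend(tr, config)
  tr <- lowpass_denoise(tr, config)
  notch_cascade(tr, config)
}
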