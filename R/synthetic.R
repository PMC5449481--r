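#' Describe one quantal event population
#'
#' Event amplitudes, rise durations and decay time constants of miniature
#' EPSCs are approximately log-normal; a population is parameterised by the
#' median of each quantity and the standard deviation of its natural
#' logarithm, plus a Poisson event rate.
#'
#' @param median_amplitude Median peak amplitude magnitude (pA).
#' @param sigma_log_amplitude SD of the natural-log amplitude (dimensionless).
#' @param median_rise Median full linear-rise duration (ms).
#' @param sigma_log_rise SD of the natural-log rise.
#' @param median_decay Median decay time constant (ms).
#' @param sigma_log_decay SD of the natural-log decay.
#' @param rate Event rate (events/s) of the homogeneous Poisson process.
#' @return A `population_spec` list.
#' @export
population_spec <- function(median_amplitude = 60, sigma_log_amplitude = 0.3,
                            median_rise = 0.5, sigma_log_rise = 0.3,
                            median_decay = 2, sigma_log_decay = 0.3,
                            rate = 2) {
  if (any(c(median_amplitude, median_rise, median_decay) <= 0))
    stop("all medians must be positive")
  if (any(c(sigma_log_amplitude, sigma_log_rise, sigma_log_decay) < 0))
    stop("all log-SDs must be non-negative")
  if (rate < 0) stop("`rate` must be non-negative")
  structure(list(median_amplitude = median_amplitude,
                 sigma_log_amplitude = sigma_log_amplitude,
                 median_rise = median_rise, sigma_log_rise = sigma_log_rise,
                 median_decay = median_decay, sigma_log_decay = sigma_log_decay,
                 rate = rate),
            class = "population_spec")
}

#' Describe recording noise and interference
#'
#' @param gaussian_sd SD of white Gaussian background noise (pA).
#' @param line_amplitude Amplitude of the 50 Hz mains fundamental (pA).
#' @param n_harmonics Number of mains harmonics rendered (fundamental included).
#' @param harmonic_decay Amplitude ratio between successive harmonics.
#' @param drift_amplitude SD of the slow baseline drift (pA).
#' @param drift_timescale Smoothing timescale of the drift (s).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(gaussian_sd = 3, line_amplitude = 2, n_harmonics = 4,
                       harmonic_decay = 0.5, drift_amplitude = 5,
                       drift_timescale = 5) {
  vals <- c(gaussian_sd, line_amplitude, n_harmonics, harmonic_decay,
            drift_amplitude, drift_timescale)
  if (any(vals < 0)) stop("all noise_spec fields must be non-negative")
  structure(list(gaussian_sd = gaussian_sd, line_amplitude = line_amplitude,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 drift_amplitude = drift_amplitude,
                 drift_timescale = drift_timescale),
            class = "noise_spec")
}

#' Describe a synthetic whole-cell recording
#'
#' Defaults mirror a typical acquisition: 180 s at 20 kHz with one quantal
#' population over background noise, mains interference and slow drift.
#'
#' @param duration Recording duration (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param populations A `population_spec` or list of them (one or two for the
#'   study scenarios; more are allowed).
#' @param noise A [noise_spec()].
#' @param seed Integer seed making the rendered recording reproducible.
#' @param cell_id,group Metadata carried onto the rendered trace.
#' @return A `recording_spec` list.
#' @export
recording_spec <- function(duration = 180, sampling_rate = 20000,
                           populations = list(population_spec()),
                           noise = noise_spec(), seed = 1L,
                           cell_id = "synthetic", group = "SYN") {
  if (duration <= 0) stop("`duration` must be positive")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (!length(populations) ||
      !all(vapply(populations, inherits, logical(1), "population_spec")))
    stop("`populations` must be a list of population_spec objects")
  if (noise$n_harmonics * 50 >= sampling_rate / 2)
    stop("mains harmonics extend to or beyond the Nyquist frequency")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 populations = populations, noise = noise,
                 seed = as.integer(seed), cell_id = cell_id, group = group),
            class = "recording_spec")
}

#' Draw a ground-truth event schedule
#'
#' Event times of each population form a homogeneous Poisson process of the
#' stated rate over `(0, duration)`; amplitudes, rises and decays are drawn
#' log-normally with the stated medians and log-SDs. Populations are merged
#' and sorted by time.
#'
#' @param populations A `population_spec` or list of them.
#' @param duration Recording duration (s).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (as when called from [render_recording()]).
#' @return A data frame with class `mepsc_ground_truth`: columns `population`,
#'   `time_s`, `amplitude_pA`, `rise_ms`, `decay_ms`, sorted by `time_s`.
#' @export
generate_event_schedule <- function(populations, duration, seed = NULL) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be a positive number")
  if (!is.null(seed)) set.seed(as.integer(seed))
  per_pop <- lapply(seq_along(populations), function(i) {
    p <- populations[[i]]
    n <- stats::rpois(1L, p$rate * duration)
    if (n == 0L)
      return(data.frame(population = integer(0), time_s = numeric(0),
                        amplitude_pA = numeric(0), rise_ms = numeric(0),
                        decay_ms = numeric(0)))
    data.frame(
      population = rep.int(i, n),
      time_s = sort(stats::runif(n, 0, duration)),
      amplitude_pA = stats::rlnorm(n, log(p$median_amplitude), p$sigma_log_amplitude),
      rise_ms = stats::rlnorm(n, log(p$median_rise), p$sigma_log_rise),
      decay_ms = stats::rlnorm(n, log(p$median_decay), p$sigma_log_decay))
  })
  out <- do.call(rbind, per_pop)
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mepsc_ground_truth", "data.frame")
  out
}

# Low-frequency baseline: random walk on a coarse knot grid, spline-smoothed
# at the drift timescale, standardised to unit SD then scaled.
render_drift <- function(n, fs, amplitude, timescale) {
  if (n < 2L) return(numeric(n))
  step <- max(timescale / 4, 4 / fs)
  knots <- seq(0, (n - 1) / fs + step, by = step)
  walk <- cumsum(stats::rnorm(length(knots)))
  y <- stats::spline(knots, walk, xout = (seq_len(n) - 1) / fs)$y
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  amplitude * y
}

#' Render a synthetic recording with ground truth
#'
#' Sums the model waveform of every scheduled event (negated: inward currents
#' are negative), then adds white Gaussian noise, mains interference
#' (fundamental plus geometrically decaying harmonics at uniformly drawn
#' phases) and a slow baseline drift. Superposition is linear; the same spec
#' and seed give a bit-identical trace.
#'
#' @param spec A [recording_spec()].
#' @return A list with elements `trace` (an `mepsc_trace`) and `ground_truth`
#'   (the event schedule).
#' @export
#' @examples
#' rec <- render_recording(recording_spec(duration = 2, seed = 42))
#' rec$trace
#' head(rec$ground_truth)
render_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  set.seed(spec$seed)
  schedule <- generate_event_schedule(spec$populations, spec$duration)
  x <- numeric(n)
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      ev <- schedule[i, ]
      i0 <- max(1L, floor((ev$time_s - ev$rise_ms / 1000) * fs) + 1L)
      i1 <- min(n, ceiling((ev$time_s + 12 * ev$decay_ms / 1000) * fs) + 1L)
      if (i0 > n || i1 < 1L || i0 > i1) next
      t_ms <- ((i0:i1 - 1) / fs) * 1000
      x[i0:i1] <- x[i0:i1] - model_waveform(
        list(amplitude = ev$amplitude_pA, rise = ev$rise_ms,
             t0 = ev$time_s * 1000, decay = ev$decay_ms), t_ms)
    }
  }
  nz <- spec$noise
  tt <- (seq_len(n) - 1) / fs
  if (nz$n_harmonics > 0L) {
    phases <- stats::runif(nz$n_harmonics, 0, 2 * pi)
    for (k in seq_len(nz$n_harmonics)) {
      amp_k <- nz$line_amplitude * nz$harmonic_decay^(k - 1)
      if (amp_k > 0) x <- x + amp_k * sin(2 * pi * 50 * k * tt + phases[k])
    }
  }
  if (nz$gaussian_sd > 0) x <- x + stats::rnorm(n, 0, nz$gaussian_sd)
  x <- x + render_drift(n, fs, nz$drift_amplitude, nz$drift_timescale)
  list(trace = trace(x, fs, cell_id = spec$cell_id, group = spec$group),
       ground_truth = schedule)
}

#' Write a ground-truth event schedule as tab-delimited text
#'
#' @param gt Schedule from [generate_event_schedule()] / [render_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.table(as.data.frame(gt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
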