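test_that("spec constructors validate their invariants", {
  expect_error(population_spec(median_amplitude = -1), "medians")
  expect_error(population_spec(sigma_log_rise = -0.1), "log-SDs")
  expect_error(population_spec(rate = -2), "rate")
  expect_error(recording_spec(duration = 0), "duration")
  expect_error(recording_spec(sampling_rate = -1), "sampling_rate")
  # harmonics must stay below Nyquist
  expect_error(recording_spec(sampling_rate = 300,
                              noise = noise_spec(n_harmonics = 4)),
               "Nyquist")
})

test_that("zero-rate populations give an empty schedule", {
  gt <- generate_event_schedule(population_spec(rate = 0), 180, seed = 1)
  expect_identical(nrow(gt), 0L)
})

test_that("degenerate log-normal (sigma 0) yields exactly the medians", {
  p <- population_spec(median_amplitude = 55, sigma_log_amplitude = 0,
                       median_rise = 0.4, sigma_log_rise = 0,
                       median_decay = 1.5, sigma_log_decay = 0, rate = 3)
  gt <- generate_event_schedule(p, 60, seed = 2)
  expect_gt(nrow(gt), 0)
  expect_equal(unique(gt$amplitude_pA), 55)
  expect_equal(unique(gt$rise_ms), 0.4)
  expect_equal(unique(gt$decay_ms), 1.5)
})

test_that("event counts follow the Poisson mean over many seeds", {
  # rate 2/s for 180 s: mean count 360, SE sqrt(360) per run
  counts <- vapply(1:1000, function(s)
    nrow(generate_event_schedule(population_spec(rate = 2), 180, seed = s)),
    integer(1))
  se_mean <- sqrt(360) / sqrt(1000)
  expect_lt(abs(mean(counts) - 360), 3 * se_mean)
  # variance should also be Poisson-like
  expect_lt(abs(var(counts) / 360 - 1), 0.15)
})

test_that("schedules are time-sorted with log-normal parameter moments", {
  p <- population_spec(median_amplitude = 60, sigma_log_amplitude = 0.3,
                       median_decay = 2, sigma_log_decay = 0.25, rate = 60)
  gt <- generate_event_schedule(p, 300, seed = 3)  # ~18k events
  expect_false(is.unsorted(gt$time_s))
  expect_true(all(gt$amplitude_pA > 0 & gt$rise_ms > 0 & gt$decay_ms > 0))
  n <- nrow(gt)
  expect_gt(n, 1e4)
  # empirical log-moments within 3 SE of the population_spec values
  expect_lt(abs(mean(log(gt$amplitude_pA)) - log(60)), 3 * 0.3 / sqrt(n))
  expect_lt(abs(sd(log(gt$amplitude_pA)) - 0.3), 3 * 0.3 / sqrt(2 * n))
  expect_lt(abs(mean(log(gt$decay_ms)) - log(2)), 3 * 0.25 / sqrt(n))
})

test_that("inter-event intervals of one population look exponential", {
  gt <- generate_event_schedule(population_spec(rate = 20), 500, seed = 4)
  iei <- diff(gt$time_s)
  # R's uniform RNG has 32-bit granularity, so rare exact interval ties occur
  ks <- suppressWarnings(ks.test(iei, "pexp", rate = 1 / mean(iei)))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering is seed-deterministic", {
  spec <- recording_spec(duration = 1, seed = 11)
  a <- render_recording(spec)
  b <- render_recording(spec)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("pure line interference has RMS A/sqrt(2)", {
  spec <- recording_spec(
    duration = 1, seed = 5,
    populations = list(population_spec(rate = 0)),
    noise = noise_spec(gaussian_sd = 0, line_amplitude = 8, n_harmonics = 1,
                       drift_amplitude = 0))
  x <- render_recording(spec)$trace$samples
  expect_equal(rms(x), 8 / sqrt(2), tolerance = 1e-3)
})

test_that("a single noise-free event peaks at -Amplitude at t0", {
  p <- population_spec(median_amplitude = 60, sigma_log_amplitude = 0,
                       median_rise = 0.5, sigma_log_rise = 0,
                       median_decay = 2, sigma_log_decay = 0, rate = 0.5)
  spec <- recording_spec(duration = 4, seed = 8, populations = list(p),
                         noise = noise_spec(gaussian_sd = 0, line_amplitude = 0,
                                            drift_amplitude = 0))
  rec <- render_recording(spec)
  gt <- rec$ground_truth
  expect_gt(nrow(gt), 0)
  x <- rec$trace$samples
  # the continuous-time peak -Amplitude is met up to half-sample rounding on
  # the steep ramp: one 0.05 ms sample spans 10% of a 0.5 ms rise
  expect_gte(min(x), -60 - 1e-9)
  expect_lte(min(x), -57)
  t_min <- (which.min(x) - 1) / spec$sampling_rate
  expect_lt(min(abs(t_min - gt$time_s)), 1 / spec$sampling_rate + 1e-9)
})

test_that("zero noise and zero events renders an identically zero trace", {
  spec <- recording_spec(
    duration = 1, seed = 6,
    populations = list(population_spec(rate = 0)),
    noise = noise_spec(gaussian_sd = 0, line_amplitude = 0,
                       drift_amplitude = 0))
  expect_identical(unique(render_recording(spec)$trace$samples), 0)
})

test_that("trace text round-trip preserves samples and metadata", {
  rec <- render_recording(recording_spec(duration = 0.1, seed = 9,
                                         cell_id = "c01", group = "SYN"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_trace(rec$trace, path)
  back <- read_trace(path)
  expect_equal(back$samples, rec$trace$samples, tolerance = 1e-8)
  expect_identical(back$cell_id, "c01")
  expect_identical(back$group, "SYN")
  expect_identical(back$sampling_rate, 20000)
})
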