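true_params <- list(amplitude = 60, rise = 0.5, t0 = 5, decay = 2)
fs <- 20000

render_snippet <- function(params = true_params, dur_ms = 30, fs. = fs) {
  t_ms <- (0:round(dur_ms / 1000 * fs.)) / fs. * 1000
  model_waveform(params, t_ms)
}

test_that("model waveform honours its piecewise definition", {
  p <- true_params
  expect_equal(model_waveform(p, p$t0), 60)                    # peak
  expect_equal(model_waveform(p, p$t0 + p$decay), 60 * exp(-1))
  expect_equal(model_waveform(p, p$t0 - p$rise), 0)            # onset
  expect_equal(model_waveform(p, p$t0 - p$rise / 2), 30)       # mid-ramp
  expect_equal(model_waveform(p, c(-5, 0, p$t0 - p$rise - 1e-9)),
               c(0, 0, 0))
  # continuity at t0
  eps <- 1e-9
  expect_lt(abs(model_waveform(p, p$t0 + eps) -
                  model_waveform(p, p$t0 - eps)), 1e-5)
  expect_error(model_waveform(list(amplitude = 1, rise = 0, t0 = 1, decay = 1),
                              0.5), "positive")
})

test_that("initial guess lands within 10% on noiseless waveforms", {
  for (p in list(true_params,
                 list(amplitude = 25, rise = 1.5, t0 = 8, decay = 6),
                 list(amplitude = 150, rise = 0.2, t0 = 4, decay = 0.8))) {
    g <- initial_guess(render_snippet(p), fs)
    expect_true(g$ok)
    rel <- abs(unlist(g$params) / unlist(p) - 1)
    expect_lt(max(rel), 0.1)
  }
})

test_that("degenerate snippets are reported as fit failures", {
  expect_false(initial_guess(numeric(200), fs)$ok)
  ramp_up <- seq(0, 50, length.out = 100)       # peak at last sample
  expect_false(initial_guess(ramp_up, fs)$ok)
  ramp_down <- seq(50, 0, length.out = 100)     # peak at first sample
  expect_false(initial_guess(ramp_down, fs)$ok)
  f <- fit_event(numeric(200), fs)
  expect_false(f$fit_status == "ok")
  expect_true(is.na(f$amplitude_pA))
})

test_that("noiseless model data is recovered essentially exactly", {
  f <- fit_event(render_snippet(), fs)
  expect_identical(f$fit_status, "ok")
  got <- unlist(f[1, c("amplitude_pA", "rise_ms", "t0_ms", "decay_ms")])
  expect_lt(max(abs(got / unlist(true_params) - 1)), 1e-4)
  expect_gte(f$r2, 1 - 1e-8)
  expect_equal(f$rise_10_90_ms, 0.8 * f$rise_ms)
})

test_that("10-90% rise time is 0.8 of the fitted full rise", {
  p <- list(amplitude = 40, rise = 1.0, t0 = 5, decay = 3)
  f <- fit_event(render_snippet(p), fs)
  expect_equal(f$rise_10_90_ms, 0.8, tolerance = 1e-6)
})

test_that("fitting is scale- and shift-equivariant", {
  set.seed(51)
  snip <- render_snippet() + rnorm(601, sd = 2)
  f0 <- fit_event(snip, fs)
  # amplitude scales, shape parameters do not
  f2 <- fit_event(3 * snip, fs)
  expect_equal(f2$amplitude_pA / f0$amplitude_pA, 3, tolerance = 1e-4)
  expect_equal(f2$rise_ms, f0$rise_ms, tolerance = 1e-4)
  expect_equal(f2$decay_ms, f0$decay_ms, tolerance = 1e-4)
  expect_equal(f2$r2, f0$r2, tolerance = 1e-8)
  # shifting the snippet by whole samples shifts t0 only
  shift <- 40 # samples = 2 ms
  f3 <- fit_event(c(numeric(shift), snip), fs)
  expect_equal(f3$t0_ms - f0$t0_ms, shift / fs * 1000, tolerance = 1e-3)
  expect_equal(f3$amplitude_pA, f0$amplitude_pA, tolerance = 1e-3)
  expect_equal(f3$decay_ms, f0$decay_ms, tolerance = 1e-3)
})

test_that("the solver never degrades an exact starting point", {
  snip <- render_snippet()
  f <- fit_event(snip, fs, init = true_params)
  resid <- sum((model_waveform(
    list(amplitude = f$amplitude_pA, rise = f$rise_ms, t0 = f$t0_ms,
         decay = f$decay_ms),
    (seq_along(snip) - 1) / fs * 1000) - snip)^2)
  expect_lt(resid, 1e-12)
})

test_that("LM fits agree with a grid-search oracle on noisy events", {
  set.seed(52)
  n_events <- 50
  err_lm <- err_grid <- numeric(n_events)
  for (i in seq_len(n_events)) {
    snip <- render_snippet() + rnorm(601, sd = 4)
    f <- fit_event(snip, fs)
    expect_identical(f$fit_status, "ok")
    err_lm[i] <- abs(f$amplitude_pA / 60 - 1)
    err_grid[i] <- abs(grid_fit_event(snip, fs)[1] / 60 - 1)
  }
  expect_lt(abs(median(err_lm) - median(err_grid)), 0.01)
})

test_that("fit_events assembles per-event rows with absolute times", {
  p <- population_spec(median_amplitude = 80, sigma_log_amplitude = 0,
                       median_rise = 0.5, sigma_log_rise = 0,
                       median_decay = 2, sigma_log_decay = 0, rate = 1)
  rec <- render_recording(recording_spec(
    duration = 10, seed = 53, populations = list(p),
    noise = noise_spec(gaussian_sd = 0, line_amplitude = 0,
                       drift_amplitude = 0)))
  tr <- rec$trace
  cand <- enforce_refractory(detect_events(tr, -20))
  ev <- fit_events(tr, cand)
  ok <- ev[ev$fit_status == "ok", ]
  expect_gt(nrow(ok), 0)
  # every fitted event time matches a ground-truth event within 0.5 ms
  gaps <- vapply(ok$event_time_s,
                 function(t) min(abs(rec$ground_truth$time_s - t)), numeric(1))
  expect_lt(max(gaps), 5e-4)
  # isolated events (no neighbour within 30 ms) recover the amplitude
  # exactly; events overlapping a close neighbour carry biased estimates,
  # which is why the refractory rule exists
  isolated <- vapply(ok$event_time_s, function(t) {
    d <- sort(abs(rec$ground_truth$time_s - t))
    length(d) == 1L || d[2] > 0.03
  }, logical(1))
  expect_gt(sum(isolated), 0)
  expect_equal(ok$amplitude_pA[isolated], rep(80, sum(isolated)),
               tolerance = 1e-3)
})
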