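make_trace <- function(times, amplitudes, noise_sd = 0, duration = 2,
                       mode = "current_clamp", seed = 1, mini_rate = 0) {
  cfg <- recording_config(noise_sd = noise_sd, mini_rate = mini_rate,
                          duration = duration, mode = mode)
  synthesize_trace(tibble::tibble(time = times, amplitude = amplitudes),
                   cfg, seed = seed)
}

test_that("noiseless injected events are recovered exactly", {
  tr <- make_trace(c(0.2, 0.5, 0.8, 1.1, 1.6), rep(2, 5))
  ev <- detect_minis(tr, threshold = 1)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$amplitude, rep(2, 5), tolerance = 0.01)
  off <- kernel_peak_time(0.001, 0.006)
  expect_equal(ev$time, c(0.2, 0.5, 0.8, 1.1, 1.6) + off, tolerance = 1e-3)
  expect_true(all(ev$rise_time > 0 & ev$rise_time < 0.005))
})

test_that("a flat noiseless trace yields no events, and bad inputs error", {
  flat <- make_trace(numeric(), numeric())
  expect_equal(nrow(detect_minis(flat, threshold = 0.5)), 0)
  expect_error(detect_minis(flat, threshold = -1), "threshold")
  expect_error(detect_minis(trace_recording(numeric(1), 1000)[0, ],
                            threshold = 1), "empty")
})

test_that("detection works on TEVC traces with inward (negative) events", {
  cfg <- recording_config(noise_sd = 0, mini_rate = 0, duration = 1,
                          mode = "tevc")
  tr <- synthesize_trace(tibble::tibble(time = c(0.3, 0.6),
                                        amplitude = c(1.5, 2.5)), cfg)
  expect_lt(min(tr$value), 0)  # inward current
  ev <- detect_minis(tr, threshold = 0.5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$amplitude, c(1.5, 2.5), tolerance = 0.01)
})

test_that("detection is translation-invariant and amplitude-linear", {
  times <- c(0.3, 0.7, 1.2)
  tr <- make_trace(times, c(2, 3, 4))
  ev <- detect_minis(tr, threshold = 1)
  shifted <- make_trace(times + 0.25, c(2, 3, 4), duration = 2.5)
  ev_s <- detect_minis(shifted, threshold = 1)
  expect_equal(ev_s$time, ev$time + 0.25, tolerance = 1e-3)
  expect_equal(ev_s$amplitude, ev$amplitude, tolerance = 1e-6)
  scaled <- trace_recording((tr$value - (-70)) * 3 + (-70),
                            sampling_rate = 10000)
  ev_c <- detect_minis(scaled, threshold = 3)
  expect_equal(ev_c$amplitude, ev$amplitude * 3, tolerance = 1e-6)
})

test_that("detection at SNR 5 keeps precision and recall high", {
  amp <- 1
  cfg <- recording_config(noise_sd = amp / 5, mini_rate = 0, duration = 20)
  set.seed(11)
  times <- sort(runif(60, 0.05, 19.8))
  tr <- synthesize_trace(tibble::tibble(time = times, amplitude = amp),
                         cfg, seed = 2)
  ev <- detect_minis(tr, threshold = amp / 2)
  off <- kernel_peak_time(cfg$kernel_rise, cfg$kernel_decay)
  m <- match_events(ev, tibble::tibble(time = times + off), tol = 0.002)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
})

test_that("detection performance does not improve as noise grows", {
  amp <- 1
  set.seed(21)
  times <- sort(runif(80, 0.05, 19.8))
  off <- kernel_peak_time(0.001, 0.006)
  recall_at <- function(noise_sd) {
    cfg <- recording_config(noise_sd = noise_sd, mini_rate = 0, duration = 20)
    tr <- synthesize_trace(tibble::tibble(time = times, amplitude = amp),
                           cfg, seed = 3)
    ev <- detect_minis(tr, threshold = amp / 2)
    match_events(ev, tibble::tibble(time = times + off), tol = 0.002)$recall
  }
  r <- sapply(c(0.05, 0.5, 1.5), recall_at)
  expect_true(all(diff(r) <= 0.05))  # nonincreasing up to matching jitter
  expect_gt(r[1], r[3])
})

test_that("evoked measurement recovers injected amplitudes", {
  cfg <- recording_config(noise_sd = 0, mini_rate = 0, duration = 1,
                          mode = "tevc")
  tr <- synthesize_trace(tibble::tibble(time = 0.3, amplitude = 40), cfg,
                         evoked = TRUE)
  out <- measure_evoked(tr)
  expect_s3_class(out, "evoked_response_set")
  expect_equal(out$amplitude, 40, tolerance = 1e-6)
  # stimulus with no deflection measures zero
  tr0 <- trace_recording(rep(0, 10000), 10000, stim_times = 0.5,
                         mode = "tevc")
  expect_equal(measure_evoked(tr0)$amplitude, 0)
  expect_error(measure_evoked(make_trace(numeric(), numeric())), "stimulus")
})

test_that("train measurement matches the generator's per-stimulus amplitudes", {
  m <- model_at_p(10, 1, q_mean = 2, q_cv = 0.3)
  pool <- pool_model(400, 0.2, 2000)
  train <- simulate_train(m, pool, n_stim = 30, freq = 60, seed = 9)
  # fast kernel so successive responses do not overlap at 60 Hz
  cfg <- recording_config(noise_sd = 0, mini_rate = 0, mode = "tevc",
                          duration = 0.8, kernel_rise = 0.0004,
                          kernel_decay = 0.0015)
  times <- 0.05 + train$time
  tr <- synthesize_trace(tibble::tibble(time = times,
                                        amplitude = train$amplitude),
                         cfg, evoked = TRUE)
  out <- measure_evoked(tr, window = 0.012)
  expect_equal(out$amplitude, train$amplitude, tolerance = 0.02)
})

test_that("overlapping windows warn and truncate outside train mode", {
  cfg <- recording_config(noise_sd = 0, mini_rate = 0, duration = 2,
                          mode = "tevc")
  tr <- synthesize_trace(tibble::tibble(time = c(0.5, 1.0), amplitude = 5),
                         cfg, evoked = TRUE)
  expect_warning(out <- measure_evoked(tr, window = 0.7), "truncated")
  expect_true(out$truncated[1])
  expect_equal(out$amplitude, c(5, 5), tolerance = 0.01)
})
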