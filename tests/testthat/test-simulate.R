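test_that("evoked draws hit deterministic saturation and zero-release limits", {
  m <- model_at_p(n_sites = 12, p = 1, q_mean = 2, q_cv = 0)
  a <- draw_evoked_amplitudes(m, ca = 3, n_sweeps = 20, seed = 1)
  expect_equal(a$amplitude, rep(12 * 2, 20), tolerance = 2e-3)
  m0 <- release_model(12, p_max = 0.5, ca_half = 1, hill = 1, q_mean = 2)
  a0 <- draw_evoked_amplitudes(m0, ca = 0, n_sweeps = 20, seed = 1)
  expect_equal(a0$amplitude, rep(0, 20))
})

test_that("evoked amplitude moments match the binomial closed forms", {
  n <- 20000
  m <- model_at_p(100, p = 0.3, q_mean = 1, q_cv = 0)
  a <- draw_evoked_amplitudes(m, ca = 3, n_sweeps = n, seed = 7)$amplitude
  # mean N p Q = 30, variance N p (1-p) Q^2 = 21
  expect_lt(abs(mean(a) - 30), 3 * sqrt(21 / n))
  expect_lt(abs(var(a) - 21) / 21, 0.06)
  # with quantal variability: + N p Q^2 cv^2
  cv <- 0.4
  mv <- model_at_p(100, p = 0.3, q_mean = 1, q_cv = cv)
  av <- draw_evoked_amplitudes(mv, ca = 3, n_sweeps = n, seed = 8)$amplitude
  target <- 21 + 100 * 0.3 * cv^2
  expect_lt(abs(mean(av) - 30), 4 * sqrt(target / n))
  expect_lt(abs(var(av) - target) / target, 0.06)
})

test_that("draws are reproducible for a fixed seed and leave the RNG alone", {
  m <- quantalr:::wild_type_release()
  set.seed(123); before <- runif(1)
  set.seed(123)
  a1 <- draw_evoked_amplitudes(m, 3, 50, seed = 99)
  expect_identical(runif(1), before)
  a2 <- draw_evoked_amplitudes(m, 3, 50, seed = 99)
  expect_identical(a1, a2)
})

test_that("train simulation obeys depletion limits and conservation", {
  m <- model_at_p(10, p = 1, q_mean = 1.5, q_cv = 0)
  none <- simulate_train(m, pool_model(500, 0, 1000), n_stim = 10, seed = 1)
  expect_true(all(none$amplitude == 0))
  oneshot <- simulate_train(m, pool_model(300, 1, 0), n_stim = 10, seed = 1)
  expect_equal(oneshot$amplitude[1], 300 * 1.5)
  expect_true(all(oneshot$amplitude[-1] == 0))
  # without replenishment, total release never exceeds the pool
  for (s in 1:10) {
    tr <- simulate_train(m, pool_model(200, 0.3, 0), n_stim = 40, seed = s)
    expect_lte(sum(tr$n_released), 200)
  }
})

test_that("train amplitudes decay to the depletion-replenishment fixed point", {
  pool <- pool_model(500, 0.25, 3000)
  m <- model_at_p(10, 1, q_mean = 1, q_cv = 0)
  oracle <- mean_train_intercept(500, 0.25, 3000, freq = 60, n_stim = 30)
  steady_oracle <- mean(oracle$released[18:30])
  steady <- sapply(1:40, function(s) {
    tr <- simulate_train(m, pool, n_stim = 30, freq = 60, seed = s)
    mean(tr$amplitude[18:30])
  })
  expect_lt(abs(mean(steady) - steady_oracle) / steady_oracle, 0.1)
  one <- simulate_train(m, pool, n_stim = 30, freq = 60, seed = 4)
  expect_gt(mean(one$amplitude[1:3]), mean(one$amplitude[18:30]))
})

test_that("trace synthesis superposes unit-peak kernels over baseline", {
  cfg <- recording_config(noise_sd = 0, mini_rate = 0, duration = 1)
  flat <- synthesize_trace(tibble::tibble(time = numeric(),
                                          amplitude = numeric()), cfg)
  expect_equal(unique(flat$value), cfg$holding)
  one <- synthesize_trace(tibble::tibble(time = 0.2, amplitude = 3), cfg)
  expect_equal(max(one$value) - cfg$holding, 3, tolerance = 1e-6)
  peak_t <- one$time[which.max(one$value)]
  expect_lt(abs(peak_t - 0.2 -
                  kernel_peak_time(cfg$kernel_rise, cfg$kernel_decay)),
            1.5 / cfg$sampling_rate)
  expect_error(
    synthesize_trace(tibble::tibble(time = 2, amplitude = 1), cfg),
    "within")
})

test_that("trace integral equals the summed kernel integrals of its events", {
  cfg <- recording_config(noise_sd = 0, mini_rate = 20, duration = 2,
                          holding = -70, mode = "current_clamp")
  tr <- synthesize_trace(tibble::tibble(time = numeric(),
                                        amplitude = numeric()),
                         cfg, seed = 5, q_mean = 1.2, q_cv = 0.3)
  truth <- attr(tr, "truth")
  kern <- quantalr:::event_kernel(cfg$kernel_rise, cfg$kernel_decay,
                                  cfg$sampling_rate)
  # per-event kernel integrals, truncated at the end of the sweep
  n <- nrow(tr)
  expected <- sum(purrr::map2_dbl(truth$time, truth$amplitude, function(t0, a) {
    i0 <- round(t0 * cfg$sampling_rate) + 1
    a * sum(kern[seq_len(min(length(kern), n - i0 + 1))])
  })) / cfg$sampling_rate
  trace_integral <- sum(tr$value - cfg$holding) / cfg$sampling_rate
  expect_equal(trace_integral, expected, tolerance = 1e-6)
})

test_that("scenario templates encode the compartmentalized knockdown", {
  wt <- scenario_wild_type(n_cells = 2, seed = 3)
  expect_identical(wt$muscles$m6, wt$muscles$m7)
  kd <- scenario_m6_knockdown(n_cells = 2, seed = 3)
  expect_lt(kd$muscles$m6$release$q_mean, kd$muscles$m7$release$q_mean)
  expect_gt(kd$muscles$m6$release$n_sites, kd$muscles$m7$release$n_sites)
  expect_gt(kd$muscles$m6$pool$pool_size, kd$muscles$m7$pool$pool_size)
  expect_identical(kd$muscles$m7, wt$muscles$m7)
  ph <- scenario_phtx(n_cells = 2, seed = 3, php = FALSE)
  expect_identical(ph$muscles$m6, ph$muscles$m7)
  expect_lt(ph$muscles$m6$release$q_mean, wt$muscles$m6$release$q_mean)
})

test_that("scenario generation is deterministic and carries ground truth", {
  sc <- scenario_m6_knockdown(n_cells = 2, seed = 17)
  d1 <- generate_scenario(sc)
  d2 <- generate_scenario(sc)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$ground_truth, d2$ground_truth)
  gt <- d1$ground_truth
  expect_lt(gt$q_mean[gt$muscle == "m6"], gt$q_mean[gt$muscle == "m7"])
  expect_gt(gt$pool_size[gt$muscle == "m6"], gt$pool_size[gt$muscle == "m7"])
  expect_equal(nrow(d1$cells), 4)
  p6 <- gt$p_ca[[which(gt$muscle == "m6")]]
  expect_equal(p6$p,
               release_probability_at(sc$muscles$m6$release, p6$ca_mM))
})
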