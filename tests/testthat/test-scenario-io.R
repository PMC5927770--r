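test_that("scenario datasets round-trip through plain files", {
  d <- generate_scenario(scenario_m6_knockdown(n_cells = 2, seed = 12))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "kd")
  write_scenario(d, out)
  expect_error(write_scenario(d, out), class = "quantalr_overwrite_error")
  write_scenario(d, out, overwrite = TRUE)
  d2 <- read_scenario(out)
  expect_equal(d2$label, d$label)
  expect_equal(nrow(d2$cells), nrow(d$cells))
  for (i in seq_len(nrow(d$cells))) {
    j <- which(d2$cells$cell_id == d$cells$cell_id[i])
    expect_equal(d2$cells$minis_cc[[j]]$amplitude,
                 d$cells$minis_cc[[i]]$amplitude, tolerance = 1e-9)
    expect_equal(d2$cells$evoked[[j]]$amplitude,
                 d$cells$evoked[[i]]$amplitude, tolerance = 1e-9)
    expect_equal(d2$cells$train[[j]]$amplitude,
                 d$cells$train[[i]]$amplitude, tolerance = 1e-9)
  }
  expect_equal(sort(d2$ground_truth$pool_size), sort(d$ground_truth$pool_size))
})

test_that("traces round-trip losslessly at declared precision in both formats", {
  cfg <- recording_config(duration = 0.2, noise_sd = 0.05, mini_rate = 5)
  tr <- synthesize_trace(tibble::tibble(time = 0.05, amplitude = 2), cfg,
                         seed = 3)
  dir <- withr::local_tempdir()
  p_tsv <- write_trace(tr, file.path(dir, "t"), format = "tsv")
  back <- read_trace(p_tsv, sampling_rate = cfg$sampling_rate)
  expect_equal(back$value, round(tr$value, 7))
  expect_equal(attr(back, "sampling_rate"), cfg$sampling_rate)
  p_f <- write_trace(tr, file.path(dir, "t"), format = "feather")
  back_f <- read_trace(p_f, sampling_rate = cfg$sampling_rate)
  expect_identical(back_f$value, round(tr$value, 7))
})

test_that("raw-trace generation feeds the detection stage end to end", {
  sc <- scenario_wild_type(n_cells = 1, seed = 21,
                           recording = recording_config(noise_sd = 0.15,
                                                        mini_rate = 2))
  d <- generate_scenario(sc, traces = TRUE, spont_duration = 8)
  cell <- d$cells[d$cells$muscle == "m6", ]
  spont <- cell$spont_trace[[1]]
  truth <- attr(spont, "truth")
  ev <- detect_minis(spont, threshold = 0.45)
  off <- kernel_peak_time(sc$recording$kernel_rise, sc$recording$kernel_decay)
  m <- match_events(ev, dplyr::mutate(truth, time = time + off), tol = 0.003)
  expect_gte(m$recall, 0.8)   # 0.9 mV minis with CV 0.3: some fall below threshold
  expect_gte(m$precision, 0.9)
  # evoked traces measure back to the generated amplitudes
  tr_ev <- cell$evoked_traces[[1]][["3"]]
  out <- measure_evoked(tr_ev)
  gen <- cell$evoked[[1]]
  expect_equal(out$amplitude, gen$amplitude[gen$ca_mM == 3],
               tolerance = 0.15)
  # train trace reproduces the generated train
  tr_train <- cell$train_trace[[1]]
  out_tr <- measure_evoked(tr_train)
  expect_equal(out_tr$amplitude, cell$train[[1]]$amplitude, tolerance = 0.2)
})

test_that("exported tables carry '#' metadata headers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "events.tsv")
  ev <- tibble::tibble(time = c(0.1, 0.2), amplitude = c(1, 2))
  export_table(ev, path, metadata = list(cell_id = "c1", muscle = "m6"))
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# cell_id: c1"))
  expect_true(startsWith(lines[2], "# muscle: m6"))
  body <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(body$amplitude, c(1, 2))
})
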