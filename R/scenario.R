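#' Scenario configuration for synthetic experiments
#'
#' A scenario describes one simulated genotype: for each muscle innervated by
#' the shared motor neuron, a [release_model()] and a [pool_model()], plus
#' the recording protocol (calcium titration levels, sweeps per level,
#' train parameters, spontaneous recording) and a master seed.  All
#' randomness is split into named substreams per (cell, muscle, component),
#' so adding a condition never perturbs the draws of another.
#'
#' @param label Scenario label, e.g. `"wild_type"` or `"M6_GluRIIA_RNAi"`.
#' @param muscles Named list; each element is `list(release = <release_model>,
#'   pool = <pool_model>)` for one muscle.
#' @param ca_levels Calcium titration levels (mM), strictly increasing; the
#'   protocol default is 0.5, 1.5, 3.0, 6.0.
#' @param n_sweeps_per_level Evoked sweeps recorded at each calcium level.
#' @param baseline_ca Calcium (mM) of the baseline (quantal-content)
#'   recordings; 0.4 mM is the standard low-calcium saline.
#' @param n_baseline_sweeps Evoked sweeps in the baseline condition.
#' @param n_minis Spontaneous miniature events sampled per cell and mode.
#' @param train_freq,train_n Train frequency (Hz) and stimulus count.
#' @param n_cells Cells recorded per muscle.
#' @param q_scale_cc Current-clamp quantal scale (mV per TEVC nA); converts
#'   the muscle's quantal size into miniature-potential units.
#' @param recording A [recording_config()] used when raw traces are
#'   synthesized.
#' @param seed Master seed for the scenario.
#'
#' @return An object of class `scenario_config`.
#' @seealso [scenario_wild_type()], [scenario_m6_knockdown()],
#'   [generate_scenario()]
#' @export
scenario_config <- function(label, muscles,
                            ca_levels = c(0.5, 1.5, 3.0, 6.0),
                            n_sweeps_per_level = 30,
                            baseline_ca = 0.4,
                            n_baseline_sweeps = 30,
                            n_minis = 60,
                            train_freq = 60, train_n = 30,
                            n_cells = 12,
                            q_scale_cc = 1.5,
                            recording = recording_config(),
                            seed = 1) {
  stop_if_not(is.character(label) && length(label) == 1, "`label` must be a string")
  stop_if_not(is.list(muscles) && length(muscles) >= 1 &&
                !is.null(names(muscles)) && all(nzchar(names(muscles))),
              "`muscles` must be a non-empty named list")
  for (m in names(muscles)) {
    entry <- muscles[[m]]
    stop_if_not(is.list(entry) && inherits(entry$release, "release_model") &&
                  inherits(entry$pool, "pool_model") &&
                  length(entry) == 2,
                sprintf("muscle '%s' needs exactly a (release, pool) model pair", m))
  }
  stop_if_not(length(ca_levels) >= 1 && all(ca_levels > 0) &&
                all(diff(ca_levels) > 0),
              "`ca_levels` must be non-empty and strictly increasing")
  stop_if_not(is_count(n_cells) && n_cells >= 1, "`n_cells` must be >= 1")
  structure(
    list(label = label, muscles = muscles, ca_levels = ca_levels,
         n_sweeps_per_level = n_sweeps_per_level, baseline_ca = baseline_ca,
         n_baseline_sweeps = n_baseline_sweeps, n_minis = n_minis,
         train_freq = train_freq, train_n = train_n, n_cells = n_cells,
         q_scale_cc = q_scale_cc, recording = recording,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %d muscle(s) x %d cell(s), Ca levels %s mM, seed %d\n",
              x$label, length(x$muscles), x$n_cells,
              paste(x$ca_levels, collapse = "/"), x$seed))
  invisible(x)
}

# Wild-type per-muscle parameters shared by the scenario templates.  These
# are the study conditions; see the methods vignette for their rationale.
wild_type_release <- function() {
  release_model(n_sites = 150, p_max = 0.95, ca_half = 2.86, hill = 2.26,
                q_mean = 0.6, q_cv = 0.3)
}

wild_type_pool <- function() {
  pool_model(pool_size = 600, release_fraction = 0.25, replenish_rate = 2400)
}

scale_release <- function(model, q_factor = 1, n_factor = 1) {
  release_model(n_sites = as.integer(round(model$n_sites * n_factor)),
                p_max = model$p_max, ca_half = model$ca_half,
                hill = model$hill, q_mean = model$q_mean * q_factor,
                q_cv = model$q_cv)
}

scale_pool <- function(pool, factor = 1) {
  pool_model(pool_size = as.integer(round(pool$pool_size * factor)),
             release_fraction = pool$release_fraction,
             replenish_rate = pool$replenish_rate * factor)
}

#' Scenario templates: wild type, muscle-specific knockdown, acute blockade
#'
#' `scenario_wild_type()` gives both muscles identical wild-type parameters.
#' `scenario_m6_knockdown()` models a GluRIIA knockdown restricted to muscle
#' 6: quantal size reduced by `q_factor` with compensating homeostatic
#' potentiation on that muscle only (release sites scaled by `n_factor`,
#' readily releasable pool by `pool_factor`), while muscle 7 keeps wild-type
#' parameters.  The default `q_factor = 0.5`, `n_factor = 2` exactly
#' compensates, so evoked amplitude is maintained while quantal content
#' doubles — the signature of presynaptic homeostatic potentiation.
#' `scenario_phtx()` models acute philanthotoxin receptor blockade as a
#' quantal-size reduction on both muscles, with or without homeostatic
#' compensation.
#'
#' @param n_cells Cells per muscle.
#' @param seed Master seed.
#' @param q_factor Quantal-size scaling on the manipulated muscle(s).
#' @param n_factor Release-site scaling on the manipulated muscle(s).
#' @param pool_factor Readily-releasable-pool scaling (with proportional
#'   replenishment) on the manipulated muscle(s).
#' @param php For `scenario_phtx()`: whether homeostatic compensation is
#'   expressed (scaling N and the pool) or only the receptor blockade.
#' @param ... Passed to [scenario_config()].
#'
#' @return A `scenario_config`.
#' @export
scenario_wild_type <- function(n_cells = 12, seed = 1, ...) {
  wt <- list(release = wild_type_release(), pool = wild_type_pool())
  scenario_config("wild_type", muscles = list(m6 = wt, m7 = wt),
                  n_cells = n_cells, seed = seed, ...)
}

#' @rdname scenario_wild_type
#' @export
scenario_m6_knockdown <- function(n_cells = 12, seed = 1, q_factor = 0.5,
                                  n_factor = 2, pool_factor = 1.65, ...) {
  wt <- list(release = wild_type_release(), pool = wild_type_pool())
  kd <- list(release = scale_release(wt$release, q_factor, n_factor),
             pool = scale_pool(wt$pool, pool_factor))
  scenario_config("M6_GluRIIA_RNAi", muscles = list(m6 = kd, m7 = wt),
                  n_cells = n_cells, seed = seed, ...)
}

#' @rdname scenario_wild_type
#' @export
scenario_phtx <- function(n_cells = 12, seed = 1, q_factor = 0.5, php = TRUE,
                          n_factor = 2, pool_factor = 1.65, ...) {
  wt <- list(release = wild_type_release(), pool = wild_type_pool())
  blocked <- list(
    release = scale_release(wt$release, q_factor, if (php) n_factor else 1),
    pool = scale_pool(wt$pool, if (php) pool_factor else 1))
  scenario_config(if (php) "PhTx" else "PhTx_no_PHP",
                  muscles = list(m6 = blocked, m7 = blocked),
                  n_cells = n_cells, seed = seed, ...)
}

#' Generate a synthetic dataset from a scenario
#'
#' For every cell x muscle, draws: spontaneous miniature amplitude samples in
#' both recording modes, an evoked sweep set in the baseline (low-calcium,
#' current-clamp) condition, evoked sweep sets at each calcium-titration
#' level (TEVC), and a depleting stimulus train.  A ground-truth record (true
#' N, Q, p(Ca), pool parameters) is attached for parameter-recovery testing.
#' With `traces = TRUE`, raw sweeps are additionally synthesized through the
#' recording front-end (kernel convolution, spontaneous minis, noise) so the
#' event-detection stage can be exercised end to end.
#'
#' @param scenario A [scenario_config()].
#' @param traces Synthesize raw traces as well as amplitude tables.
#' @param spont_duration Duration (s) of the spontaneous trace when
#'   `traces = TRUE`.
#'
#' @return A list of class `scenario_dataset` with elements `label`,
#'   `config`, `cells` (a tibble, one row per cell x muscle with list-columns
#'   of amplitude tables and, optionally, traces), `manifest` and
#'   `ground_truth`.
#' @export
generate_scenario <- function(scenario, traces = FALSE, spont_duration = 10) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  rows <- list()
  for (muscle in names(sc$muscles)) {
    mdl <- sc$muscles[[muscle]]$release
    pool <- sc$muscles[[muscle]]$pool
    mdl_cc <- scale_release(mdl, q_factor = sc$q_scale_cc)
    for (cell in seq_len(sc$n_cells)) {
      cell_id <- sprintf("%s_%s_c%02d", sc$label, muscle, cell)
      sub <- function(...) substream_seed(sc$seed, muscle, cell, ...)
      minis_cc <- with_seed(sub("minis_cc"),
        draw_quantal_sums(rep(1L, sc$n_minis), mdl_cc$q_mean, mdl_cc$q_cv))
      minis_tevc <- with_seed(sub("minis_tevc"),
        draw_quantal_sums(rep(1L, sc$n_minis), mdl$q_mean, mdl$q_cv))
      baseline <- draw_evoked_amplitudes(mdl_cc, sc$baseline_ca,
                                         sc$n_baseline_sweeps,
                                         seed = sub("baseline"))
      evoked <- purrr::map(sc$ca_levels, function(ca) {
        draw_evoked_amplitudes(mdl, ca, sc$n_sweeps_per_level,
                               seed = sub("evoked", format(ca)))
      }) |> list_rbind()
      train <- simulate_train(mdl, pool, ca = 3, n_stim = sc$train_n,
                              freq = sc$train_freq, seed = sub("train"))
      row <- tibble(
        cell_id = cell_id, muscle = muscle, genotype = sc$label,
        minis_cc = list(tibble(amplitude = minis_cc)),
        minis_tevc = list(tibble(amplitude = minis_tevc)),
        evoked_baseline = list(baseline),
        evoked = list(evoked),
        train = list(train))
      if (traces) {
        row$spont_trace <- list(synthesize_spont_trace(
          sc, mdl_cc, spont_duration, sub("spont_trace"), cell_id, muscle))
        row$evoked_traces <- list(synthesize_evoked_traces(
          sc, evoked, sub("evoked_trace"), cell_id, muscle))
        row$train_trace <- list(synthesize_train_trace(
          sc, train, sub("train_trace"), cell_id, muscle))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  cells <- list_rbind(rows)
  truth <- imap(sc$muscles, function(entry, muscle) {
    tibble(
      genotype = sc$label, muscle = muscle,
      n_sites = entry$release$n_sites, q_mean = entry$release$q_mean,
      q_cv = entry$release$q_cv, p_max = entry$release$p_max,
      ca_half = entry$release$ca_half, hill = entry$release$hill,
      pool_size = entry$pool$pool_size,
      release_fraction = entry$pool$release_fraction,
      replenish_rate = entry$pool$replenish_rate,
      p_ca = list(tibble(ca_mM = sc$ca_levels,
                         p = release_probability_at(entry$release,
                                                    sc$ca_levels))))
  }) |> list_rbind()
  manifest <- build_manifest(sc, cells)
  structure(list(label = sc$label, config = sc, cells = cells,
                 manifest = manifest, ground_truth = truth),
            class = "scenario_dataset")
}

synthesize_spont_trace <- function(sc, mdl_cc, duration, seed, cell_id, muscle) {
  cfg <- sc$recording
  cfg$duration <- duration
  cfg$mode <- "current_clamp"
  synthesize_trace(tibble(time = numeric(), amplitude = numeric()),
                   cfg, seed = seed, q_mean = mdl_cc$q_mean,
                   q_cv = mdl_cc$q_cv,
                   metadata = list(cell_id = cell_id, muscle = muscle,
                                   genotype = sc$label, kind = "spont"))
}

# Evoked sweeps are stored back to back at a fixed 0.25 s inter-stimulus
# interval (the kernel has fully decayed well before the next stimulus).
synthesize_evoked_traces <- function(sc, evoked, seed, cell_id, muscle) {
  cfg <- sc$recording
  cfg$mode <- "tevc"
  cfg$mini_rate <- 0
  purrr::map(split(evoked, evoked$ca_mM), function(df) {
    times <- 0.05 + (seq_len(nrow(df)) - 1) * 0.25
    cfg$duration <- max(times) + 0.2
    synthesize_trace(tibble(time = times, amplitude = df$amplitude),
                     cfg, seed = substream_seed(seed, format(df$ca_mM[1])),
                     evoked = TRUE,
                     metadata = list(cell_id = cell_id, muscle = muscle,
                                     genotype = sc$label, kind = "evoked",
                                     ca_mM = df$ca_mM[1]))
  })
}

synthesize_train_trace <- function(sc, train, seed, cell_id, muscle) {
  cfg <- sc$recording
  cfg$mode <- "tevc"
  cfg$mini_rate <- 0
  times <- 0.05 + train$time
  cfg$duration <- max(times) + 0.2
  synthesize_trace(tibble(time = times, amplitude = train$amplitude),
                   cfg, seed = seed, evoked = TRUE,
                   metadata = list(cell_id = cell_id, muscle = muscle,
                                   genotype = sc$label, kind = "train",
                                   ca_mM = attr(train, "ca_mM"),
                                   freq = attr(train, "freq")))
}

build_manifest <- function(sc, cells) {
  purrr::pmap(list(cells$cell_id, cells$muscle, seq_len(nrow(cells))),
              function(cell_id, muscle, i) {
    bind_rows(
      tibble(kind = "spont", mode = "current_clamp", ca_mM = sc$baseline_ca,
             n_sweeps = NA_integer_),
      tibble(kind = "evoked", mode = "current_clamp", ca_mM = sc$baseline_ca,
             n_sweeps = sc$n_baseline_sweeps),
      tibble(kind = "evoked", mode = "tevc", ca_mM = sc$ca_levels,
             n_sweeps = sc$n_sweeps_per_level),
      tibble(kind = "train", mode = "tevc", ca_mM = 3,
             n_sweeps = sc$train_n)) |>
      mutate(cell_id = cell_id, muscle = muscle, genotype = sc$label,
             sampling_rate = sc$recording$sampling_rate,
             .before = 1)
  }) |> list_rbind()
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat(sprintf("<scenario_dataset> '%s': %d cells across %d muscle(s); %d manifest entries\n",
              x$label, nrow(x$cells), length(unique(x$cells$muscle)),
              nrow(x$manifest)))
  invisible(x)
}

#' Write and read a scenario dataset
#'
#' `write_scenario()` lays a dataset out as plain files: a tab-separated
#' manifest, tidy amplitude tables (`minis.tsv`, `evoked.tsv`,
#' `trains.tsv`), a JSON ground-truth sidecar mirroring the scenario
#' configuration, and (when traces were generated) per-sweep traces as
#' two-column `time_s`/`value` files in tab-separated text or Feather
#' format.  `read_scenario()` reconstructs the amplitude-level dataset.
#'
#' @param dataset A `scenario_dataset`.
#' @param dir Output directory.
#' @param overwrite Refuse to write into an existing directory unless `TRUE`.
#' @param trace_format `"tsv"` (two-column text) or `"feather"` (binary
#'   columnar container with the identical schema; requires the arrow
#'   package).
#'
#' @return `write_scenario()` returns `dir` invisibly; `read_scenario()`
#'   returns a `scenario_dataset` (amplitude tables and manifest; traces are
#'   listed in the manifest and can be read with [read_trace()]).
#' @export
write_scenario <- function(dataset, dir, overwrite = FALSE,
                           trace_format = c("tsv", "feather")) {
  stopifnot(inherits(dataset, "scenario_dataset"))
  trace_format <- match.arg(trace_format)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("output directory '%s' is non-empty; use overwrite = TRUE", dir),
          class = "quantalr_overwrite_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dataset$cells
  minis <- bind_rows(
    cells |> select("cell_id", "muscle", "genotype", "minis_cc") |>
      mutate(mode = "current_clamp") |> rename(events = "minis_cc"),
    cells |> select("cell_id", "muscle", "genotype", "minis_tevc") |>
      mutate(mode = "tevc") |> rename(events = "minis_tevc")) |>
    unnest("events")
  evoked <- bind_rows(
    cells |> select("cell_id", "muscle", "genotype", "evoked_baseline") |>
      mutate(mode = "current_clamp") |> rename(sweeps = "evoked_baseline"),
    cells |> select("cell_id", "muscle", "genotype", "evoked") |>
      mutate(mode = "tevc") |> rename(sweeps = "evoked")) |>
    unnest("sweeps")
  trains <- cells |>
    select("cell_id", "muscle", "genotype", "train") |>
    mutate(train = purrr::map(.data$train, function(tr) {
      as_tibble(tr) |> mutate(freq = attr(tr, "freq"), ca_mM = attr(tr, "ca_mM"))
    })) |>
    unnest("train")
  write_tsv_file(minis, file.path(dir, "minis.tsv"))
  write_tsv_file(evoked, file.path(dir, "evoked.tsv"))
  write_tsv_file(trains, file.path(dir, "trains.tsv"))
  manifest <- dataset$manifest
  if ("spont_trace" %in% names(cells)) {
    tr_dir <- file.path(dir, "traces")
    dir.create(tr_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(cells))) {
      base <- file.path(tr_dir, cells$cell_id[i])
      write_trace(cells$spont_trace[[i]], paste0(base, "_spont"), trace_format)
      for (tr in cells$evoked_traces[[i]]) {
        write_trace(tr, sprintf("%s_evoked_ca%s", base,
                                format(attr(tr, "metadata")$ca_mM)),
                    trace_format)
      }
      write_trace(cells$train_trace[[i]], paste0(base, "_train"), trace_format)
    }
  }
  write_tsv_file(manifest, file.path(dir, "manifest.tsv"))
  truth <- dataset$ground_truth |>
    mutate(p_ca = purrr::map(.data$p_ca, as.list))
  jsonlite::write_json(
    list(label = dataset$label,
         seed = dataset$config$seed,
         ca_levels = dataset$config$ca_levels,
         ground_truth = truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_file <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write/read a single trace
#'
#' Traces are stored as two columns, `time_s` and `value`, either as
#' tab-separated text (values at 1e-7 precision, lossless for the declared
#' units) or as a Feather file with the identical schema.
#'
#' @param trace A [trace_recording()].
#' @param path Output path without extension (for `write_trace`) or with
#'   extension (for `read_trace`).
#' @param format `"tsv"` or `"feather"`.
#' @param sampling_rate,mode For `read_trace`: metadata not stored in the
#'   two-column file; sampling rate defaults to the reciprocal median time
#'   step.
#' @return `write_trace()` the file path; `read_trace()` a
#'   [trace_recording()].
#' @export
write_trace <- function(trace, path, format = c("tsv", "feather")) {
  format <- match.arg(format)
  df <- tibble(time_s = round(trace$time, 7), value = round(trace$value, 7))
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for feather output")
    }
    path <- paste0(path, ".feather")
    arrow::write_feather(df, path)
  } else {
    path <- paste0(path, ".tsv")
    write_tsv_file(df, path)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, sampling_rate = NULL,
                       mode = c("current_clamp", "tevc")) {
  mode <- match.arg(mode)
  df <- if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for feather input")
    }
    as_tibble(arrow::read_feather(path))
  } else {
    read_tsv_file(path)
  }
  sr <- sampling_rate %||% (1 / median(diff(df$time_s)))
  trace_recording(df$value, sampling_rate = sr, mode = mode)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  stop_if_not(dir.exists(dir), sprintf("no such directory: %s", dir))
  minis <- read_tsv_file(file.path(dir, "minis.tsv"))
  evoked <- read_tsv_file(file.path(dir, "evoked.tsv"))
  trains <- read_tsv_file(file.path(dir, "trains.tsv"))
  manifest <- read_tsv_file(file.path(dir, "manifest.tsv"))
  truth_json <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                    simplifyVector = TRUE)
  ids <- distinct(minis, .data$cell_id, .data$muscle, .data$genotype)
  cells <- purrr::pmap(ids, function(cell_id, muscle, genotype) {
    ev_cols <- c("sweep", "ca_mM", "amplitude", "n_released")
    tr <- trains[trains$cell_id == cell_id, ]
    train <- train_response(tr$amplitude, freq = tr$freq[1],
                            ca_mM = tr$ca_mM[1], cell_id = cell_id)
    train$n_released <- tr$n_released
    tibble(
      cell_id = cell_id, muscle = muscle, genotype = genotype,
      minis_cc = list(tibble(amplitude = minis$amplitude[
        minis$cell_id == cell_id & minis$mode == "current_clamp"])),
      minis_tevc = list(tibble(amplitude = minis$amplitude[
        minis$cell_id == cell_id & minis$mode == "tevc"])),
      evoked_baseline = list(as_tibble(
        evoked[evoked$cell_id == cell_id & evoked$mode == "current_clamp",
               ev_cols])),
      evoked = list(as_tibble(
        evoked[evoked$cell_id == cell_id & evoked$mode == "tevc", ev_cols])),
      train = list(train))
  }) |> list_rbind()
  structure(list(label = truth_json$label, config = NULL, cells = cells,
                 manifest = manifest,
                 ground_truth = as_tibble(truth_json$ground_truth)),
            class = "scenario_dataset")
}
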