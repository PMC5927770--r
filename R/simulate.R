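# Binomial-release generative model: evoked amplitude draws, train dynamics
# with pool depletion, and raw-trace synthesis.

# Sum of k i.i.d. gamma quanta with mean q_mean and CV q_cv, one draw per
# element of k.  Exact: the sum of k gamma(shape, scale) is
# gamma(k * shape, scale); k = 0 contributes 0.
draw_quantal_sums <- function(k, q_mean, q_cv) {
  if (q_cv == 0) return(k * q_mean)
  shape <- 1 / q_cv^2
  scale <- q_mean * q_cv^2
  out <- numeric(length(k))
  nz <- k > 0
  out[nz] <- rgamma(sum(nz), shape = k[nz] * shape, scale = scale)
  out
}

#' Draw evoked response amplitudes under binomial release
#'
#' Each sweep's amplitude is the sum, over `n_sites` independent release
#' sites, of Bernoulli(p) releases scaled by gamma-distributed quantal sizes
#' (mean `q_mean`, CV `q_cv`), with p given by the model's Hill curve at the
#' stated calcium concentration.  The classical moments follow:
#' mean N p Q and variance N p (1-p) Q^2 + N p Q^2 cv^2.
#'
#' @param model A [release_model()].
#' @param ca Extracellular Ca2+ concentration, mM.
#' @param n_sweeps Number of sweeps to draw (>= 1).
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#'
#' @return A tibble with columns `sweep`, `ca_mM`, `amplitude` (response
#'   magnitude in the model's quantal units) and `n_released` (ground-truth
#'   released quanta per sweep).
#' @export
#' @examples
#' m <- release_model(100, p_max = 0.6, ca_half = 1.5, hill = 2, q_mean = 1)
#' amps <- draw_evoked_amplitudes(m, ca = 3, n_sweeps = 30, seed = 1)
#' mean(amps$amplitude)  # near N * p * Q = 48
draw_evoked_amplitudes <- function(model, ca, n_sweeps, seed) {
  stopifnot(inherits(model, "release_model"))
  stop_if_not(is_count(n_sweeps) && n_sweeps >= 1, "`n_sweeps` must be >= 1")
  p <- release_probability_at(model, ca)
  with_seed(seed, {
    k <- rbinom(n_sweeps, size = model$n_sites, prob = p)
    amp <- draw_quantal_sums(k, model$q_mean, model$q_cv)
    tibble(sweep = seq_len(n_sweeps), ca_mM = ca, amplitude = amp,
           n_released = k)
  })
}

#' Construct a train response
#'
#' Per-stimulus evoked amplitudes of a high-frequency train (the paper-style
#' protocol is 30-60 stimuli at 60 Hz in 3 mM Ca2+), as consumed by the RRP
#' back-extrapolation estimator.
#'
#' @param amplitudes Per-stimulus response magnitudes (nA for TEVC).
#' @param freq Stimulation frequency, Hz.
#' @param ca_mM Extracellular Ca2+, mM.
#' @param cell_id Optional cell identifier.
#'
#' @return A tibble of class `train_response` with columns `stim_index`,
#'   `time` (s from the first stimulus) and `amplitude`.
#' @export
train_response <- function(amplitudes, freq, ca_mM = NA_real_,
                           cell_id = NA_character_) {
  stop_if_not(is.numeric(amplitudes) && length(amplitudes) >= 2,
              "`amplitudes` must have at least 2 stimuli")
  stop_if_not(is_pos(freq), "`freq` must be > 0")
  out <- tibble(
    stim_index = seq_along(amplitudes),
    time = (seq_along(amplitudes) - 1) / freq,
    amplitude = as.numeric(amplitudes)
  )
  structure(out, class = c("train_response", class(out)),
            freq = freq, ca_mM = ca_mM, cell_id = cell_id)
}

#' Simulate a stimulus train with pool depletion and replenishment
#'
#' Released quanta per stimulus are Binomial(available, release_fraction);
#' between stimuli the pool is replenished by a Poisson number of quanta with
#' mean `replenish_rate / freq`, capped at `pool_size`.  Amplitudes decay
#' from an initial (fully stocked pool) response toward the steady state in
#' which release per stimulus balances replenishment per interval.
#'
#' @param model A [release_model()]; supplies quantal size statistics.
#' @param pool A [pool_model()].
#' @param ca Extracellular Ca2+, mM (metadata; train release uses the pool's
#'   `release_fraction`).
#' @param n_stim Number of stimuli (>= 2).
#' @param freq Train frequency, Hz.
#' @param seed Integer seed.
#'
#' @return A `train_response` tibble with an extra ground-truth column
#'   `n_released` (quanta released per stimulus).
#' @export
simulate_train <- function(model, pool, ca = 3, n_stim = 30, freq = 60, seed = 1) {
  stopifnot(inherits(model, "release_model"), inherits(pool, "pool_model"))
  stop_if_not(is_count(n_stim) && n_stim >= 2, "`n_stim` must be >= 2")
  stop_if_not(is_pos(freq), "`freq` must be > 0")
  with_seed(seed, {
    available <- pool$pool_size
    released <- integer(n_stim)
    mean_repl <- pool$replenish_rate / freq
    for (k in seq_len(n_stim)) {
      r <- rbinom(1, size = available, prob = pool$release_fraction)
      released[k] <- r
      available <- available - r
      if (k < n_stim && mean_repl > 0) {
        available <- min(pool$pool_size, available + rpois(1, mean_repl))
      }
    }
    amps <- draw_quantal_sums(released, model$q_mean, model$q_cv)
    out <- train_response(amps, freq = freq, ca_mM = ca)
    out$n_released <- released
    out
  })
}

# Difference-of-exponentials kernel sampled at `sampling_rate`, normalized to
# unit peak, truncated where the tail falls below 1e-4 of peak.
event_kernel <- function(kernel_rise, kernel_decay, sampling_rate) {
  t_end <- kernel_decay * log(1e4)
  t <- seq(0, t_end, by = 1 / sampling_rate)
  k <- exp(-t / kernel_decay) - exp(-t / kernel_rise)
  k / max(k)
}

#' Time from event onset to the kernel peak
#'
#' For the difference-of-exponentials kernel, the peak occurs at
#' `rise * decay / (decay - rise) * log(decay / rise)` after onset; useful
#' for aligning detected peak times with ground-truth onset times.
#'
#' @param kernel_rise,kernel_decay Kernel time constants, s.
#' @return Peak latency, s.
#' @export
kernel_peak_time <- function(kernel_rise, kernel_decay) {
  kernel_rise * kernel_decay / (kernel_decay - kernel_rise) *
    log(kernel_decay / kernel_rise)
}

#' Synthesize a raw recording trace from an event list
#'
#' Builds `baseline + sum of events * kernel + Gaussian noise`, where the
#' kernel is a unit-peak difference of exponentials, plus spontaneous
#' miniature events placed as a Poisson process at the configured
#' `mini_rate` with gamma quantal-size draws.  Event amplitudes are response
#' magnitudes; the deflection sign follows the recording mode
#' (depolarizing/positive in current clamp, inward/negative under TEVC).
#'
#' @param events A data frame with columns `time` (s) and `amplitude`
#'   (magnitude, trace units); may have zero rows.
#' @param config A [recording_config()].
#' @param seed Integer seed.
#' @param q_mean,q_cv Quantal-size distribution used for the spontaneous
#'   minis added at `config$mini_rate`.
#' @param stim_times Stimulus times to carry on the trace (defaults to the
#'   event times when `events` is marked evoked via `evoked = TRUE`).
#' @param evoked If `TRUE`, `events$time` are recorded as stimulus times.
#' @param metadata Named list carried through to the trace.
#'
#' @return A [trace_recording()] whose attribute `"truth"` holds the full
#'   injected event list (including generated minis) for recovery testing.
#' @export
synthesize_trace <- function(events, config, seed = 1, q_mean = 1, q_cv = 0,
                             stim_times = NULL, evoked = FALSE,
                             metadata = list()) {
  stopifnot(inherits(config, "recording_config"))
  events <- as_tibble(events)
  if (nrow(events)) {
    stop_if_not(all(c("time", "amplitude") %in% names(events)),
                "`events` needs columns `time` and `amplitude`")
    stop_if_not(all(events$time >= 0 & events$time <= config$duration),
                "event times must lie within [0, duration]")
  }
  n <- round(config$sampling_rate * config$duration)
  kern <- event_kernel(config$kernel_rise, config$kernel_decay,
                       config$sampling_rate)
  with_seed(seed, {
    minis <- if (config$mini_rate > 0) {
      n_mini <- rpois(1, config$mini_rate * config$duration)
      tibble(time = sort(runif(n_mini, 0, config$duration)),
             amplitude = draw_quantal_sums(rep(1L, n_mini), q_mean, q_cv),
             kind = rep("mini", n_mini))
    } else {
      tibble(time = numeric(), amplitude = numeric(), kind = character())
    }
    all_events <- bind_rows(
      if (nrow(events)) mutate(events[c("time", "amplitude")], kind = "evoked"),
      minis
    )
    trace <- numeric(n)
    if (nrow(all_events)) {
      idx0 <- round(all_events$time * config$sampling_rate) + 1
      for (i in seq_len(nrow(all_events))) {
        span <- idx0[i]:min(n, idx0[i] + length(kern) - 1)
        trace[span] <- trace[span] +
          all_events$amplitude[i] * kern[seq_along(span)]
      }
    }
    sign <- if (config$mode == "tevc") -1 else 1
    baseline <- if (config$mode == "tevc") 0 else config$holding
    value <- baseline + sign * trace +
      if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
    out <- trace_recording(
      value, config$sampling_rate,
      stim_times = stim_times %||% if (evoked) events$time else numeric(),
      mode = config$mode, metadata = metadata)
    attr(out, "truth") <- arrange(all_events, .data$time)
    out
  })
}
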