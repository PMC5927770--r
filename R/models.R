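#' Binomial release model for a single synaptic connection
#'
#' Describes evoked release at a connection with `n_sites` independent
#' functional release sites, each releasing at most one vesicle per stimulus
#' with a calcium-dependent probability, and quantal (single-vesicle) response
#' sizes drawn from a gamma distribution.  Together with [pool_model()] this
#' parameterizes the classical decomposition of evoked amplitude into
#' N (sites) x P (release probability) x Q (quantal size).
#'
#' The calcium dependence of the per-site release probability is a Hill
#' curve, `p(ca) = p_max * ca^hill / (ca_half^hill + ca^hill)`: zero in
#' calcium-free saline, half-saturating at `ca_half`, approaching `p_max`.
#'
#' @param n_sites Number of functional release sites N (positive integer).
#' @param p_max Maximal per-site release probability (0, 1].
#' @param ca_half Extracellular Ca2+ concentration (mM) at half-maximal
#'   release probability.
#' @param hill Hill exponent of the p(Ca) curve (> 0).
#' @param q_mean Mean quantal size Q, in mV (current clamp) or nA (TEVC
#'   magnitude).
#' @param q_cv Coefficient of variation of quantal size (>= 0); 0 means every
#'   quantum has amplitude exactly `q_mean`.
#'
#' @return An object of class `release_model`.
#' @seealso [release_probability_at()], [draw_evoked_amplitudes()]
#' @export
#' @examples
#' m <- release_model(n_sites = 150, p_max = 0.9, ca_half = 2, hill = 2,
#'                    q_mean = 0.6, q_cv = 0.3)
#' release_probability_at(m, c(0.5, 1.5, 3, 6))
release_model <- function(n_sites, p_max, ca_half, hill, q_mean, q_cv = 0) {
  stop_if_not(is_count(n_sites) && n_sites >= 1, "`n_sites` must be an integer >= 1")
  stop_if_not(is_prob(p_max) && p_max > 0, "`p_max` must be in (0, 1]")
  stop_if_not(is_pos(ca_half), "`ca_half` must be > 0")
  stop_if_not(is_pos(hill), "`hill` must be > 0")
  stop_if_not(is_pos(q_mean), "`q_mean` must be > 0")
  stop_if_not(is_nonneg(q_cv), "`q_cv` must be >= 0")
  structure(
    list(n_sites = as.integer(n_sites), p_max = p_max, ca_half = ca_half,
         hill = hill, q_mean = q_mean, q_cv = q_cv),
    class = "release_model"
  )
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf(
    "<release_model> N = %d sites, p_max = %.3g (ca_half = %.3g mM, hill = %.3g), Q = %.3g (CV %.3g)\n",
    x$n_sites, x$p_max, x$ca_half, x$hill, x$q_mean, x$q_cv))
  invisible(x)
}

#' Readily-releasable-pool dynamics for train stimulation
#'
#' A discrete-time depletion/replenishment model: a pool of `pool_size`
#' release-ready quanta, a fraction `release_fraction` of the available pool
#' released (binomially) per stimulus, and replenishment at `replenish_rate`
#' quanta per second toward (never beyond) `pool_size`.  This is the simplest
#' model producing the linear late phase of the cumulative evoked amplitude
#' that back-extrapolation RRP estimation assumes.
#'
#' @param pool_size Readily releasable pool size in quanta (>= 0).
#' @param release_fraction Probability that an available quantum is released
#'   by one stimulus, in [0, 1].
#' @param replenish_rate Replenishment rate, quanta per second (>= 0).
#'
#' @return An object of class `pool_model`.
#' @seealso [simulate_train()], [estimate_rrp()]
#' @export
pool_model <- function(pool_size, release_fraction, replenish_rate) {
  stop_if_not(is_count(pool_size) && pool_size >= 0, "`pool_size` must be an integer >= 0")
  stop_if_not(is_prob(release_fraction), "`release_fraction` must be in [0, 1]")
  stop_if_not(is_nonneg(replenish_rate), "`replenish_rate` must be >= 0")
  structure(
    list(pool_size = as.integer(pool_size), release_fraction = release_fraction,
         replenish_rate = replenish_rate),
    class = "pool_model"
  )
}

#' @export
print.pool_model <- function(x, ...) {
  cat(sprintf(
    "<pool_model> pool = %d quanta, release fraction = %.3g/stimulus, replenishment = %.3g quanta/s\n",
    x$pool_size, x$release_fraction, x$replenish_rate))
  invisible(x)
}

#' Recording/synthesis configuration for raw sweeps
#'
#' Parameters of the synthetic recording front-end: sampling, the
#' difference-of-exponentials postsynaptic kernel, baseline noise, and the
#' spontaneous miniature event rate.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param duration Sweep duration, s.
#' @param kernel_rise,kernel_decay Rise and decay time constants (s) of the
#'   difference-of-exponentials event kernel; `kernel_decay > kernel_rise`.
#' @param noise_sd Gaussian baseline noise SD, in trace units.
#' @param mini_rate Spontaneous miniature event rate, events/s.
#' @param holding Holding potential, mV (TEVC muscles are clamped to -70 mV).
#' @param mode `"current_clamp"` (mV, depolarizing events positive-going) or
#'   `"tevc"` (nA, synaptic currents inward/negative-going).
#'
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(sampling_rate = 10000, duration = 1,
                             kernel_rise = 0.001, kernel_decay = 0.006,
                             noise_sd = 0.1, mini_rate = 2,
                             holding = -70,
                             mode = c("current_clamp", "tevc")) {
  mode <- match.arg(mode)
  stop_if_not(is_pos(sampling_rate), "`sampling_rate` must be > 0")
  stop_if_not(is_pos(duration), "`duration` must be > 0")
  stop_if_not(is_pos(kernel_rise) && kernel_decay > kernel_rise,
              "need `kernel_decay` > `kernel_rise` > 0")
  stop_if_not(is_nonneg(noise_sd), "`noise_sd` must be >= 0")
  stop_if_not(is_nonneg(mini_rate), "`mini_rate` must be >= 0")
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         kernel_rise = kernel_rise, kernel_decay = kernel_decay,
         noise_sd = noise_sd, mini_rate = mini_rate, holding = holding,
         mode = mode),
    class = "recording_config"
  )
}

#' Per-site release probability at a given calcium concentration
#'
#' Evaluates the model's Hill curve
#' `p(ca) = p_max * ca^hill / (ca_half^hill + ca^hill)`.
#'
#' @param model A [release_model()].
#' @param ca Extracellular Ca2+ concentration(s), mM (>= 0).
#'
#' @return Numeric vector of per-site release probabilities, one per `ca`.
#' @export
#' @examples
#' m <- release_model(100, p_max = 0.6, ca_half = 1.5, hill = 2, q_mean = 1)
#' release_probability_at(m, 3)  # 0.6 * 9 / (2.25 + 9) = 0.48
release_probability_at <- function(model, ca) {
  stopifnot(inherits(model, "release_model"))
  stop_if_not(is.numeric(ca) && all(is.finite(ca)) && all(ca >= 0),
              "`ca` must be nonnegative and finite")
  ch <- ca^model$hill
  p <- model$p_max * ch / (model$ca_half^model$hill + ch)
  # ca = 0 gives 0/positive = 0 already; guard only hill underflow pathologies
  p[ca == 0] <- 0
  p
}
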