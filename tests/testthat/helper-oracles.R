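# Independent oracles used across the suite.  These deliberately avoid the
# package's own fitting code paths.

# Brute-force search for the variance-mean parabola: scans N over a dense
# log grid (zooming over rounds) and, for each candidate N, minimizes the
# residual sum of squares over Q by 1-D numerical optimization of
# sum((v - (Q*m - m^2/N))^2).  Independent of the package's fitting path.
grid_search_parabola <- function(m, v, rounds = 5) {
  q_hi <- 20 * max(v) / min(m[m > 0])
  rss_at <- function(N) {
    opt <- stats::optimize(function(Q) sum((v - (Q * m - m^2 / N))^2),
                           interval = c(0, q_hi), tol = 1e-12)
    c(opt$objective, opt$minimum)
  }
  n_lo <- 1; n_hi <- 1e7
  best <- NULL
  for (r in seq_len(rounds)) {
    ns <- exp(seq(log(n_lo), log(n_hi), length.out = 200))
    scan <- vapply(ns, rss_at, numeric(2))
    i <- which.min(scan[1, ])
    best <- list(Q = scan[2, i], N = ns[i], rss = scan[1, i])
    step <- diff(log(ns[1:2]))
    n_lo <- exp(log(best$N) - 3 * step)
    n_hi <- exp(log(best$N) + 3 * step)
  }
  best
}

# Deterministic mean-process dynamics of the depletion/replenishment model:
# expected per-stimulus release, its cumulative sum, and the back-extrapolated
# zero-time intercept of the late linear phase (in quanta).
mean_train_intercept <- function(pool_size, release_fraction, replenish_rate,
                                 freq, n_stim, window = c(18, 30)) {
  a <- pool_size
  r <- numeric(n_stim)
  repl <- replenish_rate / freq
  for (k in seq_len(n_stim)) {
    r[k] <- release_fraction * a
    a <- min(pool_size, a - r[k] + repl)
  }
  cs <- cumsum(r)
  t <- (seq_len(n_stim) - 1) / freq
  idx <- window[1]:window[2]
  fit <- stats::lm(cs[idx] ~ t[idx])
  list(intercept = unname(stats::coef(fit)[1]), released = r)
}

# Release model whose Hill curve is effectively saturated, so the per-site
# probability at any tested calcium equals `p` to within 1e-3 relative.
model_at_p <- function(n_sites, p, q_mean, q_cv = 0) {
  release_model(n_sites = n_sites, p_max = p, ca_half = 1e-6, hill = 1,
                q_mean = q_mean, q_cv = q_cv)
}

# Sweep table for a cell measured at fixed per-condition release
# probabilities (the multiple-probability protocol with known ground truth).
sweeps_at_probs <- function(n_sites, q_mean, q_cv, probs, ca_levels,
                            n_sweeps, seed) {
  purrr::map2(probs, ca_levels, function(p, ca) {
    draw_evoked_amplitudes(model_at_p(n_sites, p, q_mean, q_cv), ca,
                           n_sweeps,
                           seed = substream_seed(seed, "sweeps", format(ca)))
  }) |> purrr::list_rbind()
}
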