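exact_points <- function() {
  with_origin(tibble::tibble(
    ca_mM = c(1, 2, 3), mean_amp = c(2, 5, 8),
    variance = c(1.6, 2.5, 1.6), n_sweeps = 30L, theoretical = FALSE,
    cell_id = "demo"))
}

test_that("condition summaries use the unbiased variance", {
  p <- summarize_condition(c(1, 3), ca_mM = 1.5)
  expect_equal(p$mean_amp, 2)
  expect_equal(p$variance, 2)
  expect_equal(summarize_condition(rep(4, 10), 3)$variance, 0)
  expect_error(summarize_condition(5, 3), "2 sweeps")
  n <- 50000
  a <- draw_evoked_amplitudes(model_at_p(100, 0.5, 1, 0), 3, n, seed = 3)
  s <- summarize_condition(a$amplitude, 3)
  expect_lt(abs(s$variance - 25) / 25, 0.05)
})

test_that("the theoretical origin is appended and bookkept separately", {
  empty <- with_origin(tibble::tibble(ca_mM = numeric(),
                                      mean_amp = numeric(),
                                      variance = numeric(),
                                      n_sweeps = integer(),
                                      theoretical = logical(),
                                      cell_id = character()))
  expect_equal(nrow(empty), 1)
  expect_equal(empty$mean_amp, 0)
  pts <- exact_points()
  expect_equal(nrow(pts), 4)
  expect_true(pts$theoretical[4])
  expect_equal(pts$n_sweeps[4], 0L)
  expect_equal(sum(pts$n_sweeps), 90L)  # origin excluded from accounting
  expect_error(with_origin(pts), "mean 0")
})

test_that("an exact parabola is recovered to machine precision", {
  fit <- fit_parabola(exact_points())
  expect_equal(fit$quantal_size_Q, 1, tolerance = 1e-12)
  expect_equal(fit$n_sites_N, 10, tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_true(fit$accepted)
})

test_that("degenerate variance-mean data take the declared error paths", {
  # variance exactly proportional to mean: zero curvature, N unidentifiable
  lin <- with_origin(tibble::tibble(
    ca_mM = 1:3, mean_amp = c(2, 5, 8), variance = 0.7 * c(2, 5, 8),
    n_sweeps = 30L, theoretical = FALSE, cell_id = "lin"))
  fit <- fit_parabola(lin)
  expect_false(fit$accepted)
  expect_identical(fit$n_sites_N, Inf)
  expect_true("n_unidentifiable" %in% fit$flags)
  expect_error(release_probabilities(fit), "accepted")
  # convex-up variance cannot come from binomial saturation
  bad <- with_origin(tibble::tibble(
    ca_mM = 1:3, mean_amp = c(2, 5, 8), variance = c(0.5, 3, 9),
    n_sweeps = 30L, theoretical = FALSE, cell_id = "bad"))
  expect_error(fit_parabola(bad), class = "quantalr_fit_error")
  expect_error(fit_parabola(exact_points()[1:2, ]), "3 points")
})

test_that("least squares agrees with a brute-force grid search", {
  set.seed(55)
  for (i in 1:5) {
    N <- sample(20:300, 1); Q <- runif(1, 0.3, 2)
    probs <- sort(runif(4, 0.05, 0.85))
    sw <- sweeps_at_probs(N, Q, 0, probs, c(0.5, 1.5, 3, 6), 30,
                          seed = 100 + i)
    pts <- with_origin(
      purrr::map(split(sw, sw$ca_mM),
                 function(d) summarize_condition(d$amplitude, d$ca_mM[1])) |>
        purrr::list_rbind())
    fit <- fit_parabola(pts)
    oracle <- grid_search_parabola(pts$mean_amp, pts$variance)
    expect_lt(abs(fit$rss - oracle$rss) / max(oracle$rss, 1e-12), 1e-6)
  }
})

test_that("release probabilities follow p = mean/(N Q)", {
  fit <- fit_parabola(exact_points())
  p <- release_probabilities(fit)
  expect_equal(p$p[p$mean_amp == 5], 0.5)
  expect_equal(p$p[p$mean_amp == 0], 0)
  # mean at N*Q implies p = 1; beyond is flagged with a warning
  extra <- tibble::tibble(ca_mM = 9, mean_amp = c(10, 12))
  expect_warning(pp <- release_probabilities(fit, extra), "exceed 1")
  expect_equal(pp$p[1], 1)
  expect_true(pp$flagged[2])
})

test_that("the fit is scale-equivariant in amplitude units", {
  sw <- sweeps_at_probs(150, 0.6, 0, c(0.05, 0.2, 0.5, 0.8),
                        c(0.5, 1.5, 3, 6), 30, seed = 41)
  f1 <- varmean_analysis(sw)
  f2 <- varmean_analysis(dplyr::mutate(sw, amplitude = amplitude * 4.2))
  expect_equal(f2$quantal_size_Q, f1$quantal_size_Q * 4.2, tolerance = 1e-9)
  expect_equal(f2$n_sites_N, f1$n_sites_N, tolerance = 1e-9)
  expect_equal(release_probabilities(f2)$p, release_probabilities(f1)$p,
               tolerance = 1e-9)
})

test_that("intra-site quantal variability inflates Q-hat, not the curvature", {
  # population algebra: variance = Q(1+cv^2) mean - mean^2/N, so the
  # apparent quantal size absorbs the quantal CV while N stays consistent
  cv <- 0.3
  est <- sapply(1:60, function(s) {
    sw <- sweeps_at_probs(150, 0.6, cv, c(0.05, 0.2, 0.5, 0.8),
                          c(0.5, 1.5, 3, 6), 200, seed = 300 + s)
    fit <- tryCatch(varmean_analysis(sw), error = function(e) NULL)
    if (is.null(fit)) c(NA, NA) else c(fit$quantal_size_Q, fit$n_sites_N)
  })
  q_hat <- median(est[1, ], na.rm = TRUE)
  n_hat <- median(est[2, ], na.rm = TRUE)
  expect_equal(q_hat, 0.6 * (1 + cv^2), tolerance = 0.05)
  expect_gt(q_hat, 0.6)  # biased upward relative to the true quantal size
  expect_equal(n_hat, 150, tolerance = 0.1)
})

test_that("tidy/glance/autoplot summarize the fit", {
  fit <- fit_parabola(exact_points())
  td <- tidy(fit)
  expect_equal(td$estimate, c(1, 10), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$n_points, 4)
  expect_equal(gl$n_sweeps, 90)
  expect_s3_class(autoplot(fit), "ggplot")
})
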