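#' Variance-mean summary of one calcium condition
#'
#' The variance (unbiased, n-1 denominator) and mean of the evoked
#' amplitudes recorded at one extracellular calcium concentration: one point
#' of the variance-mean (multiple-probability fluctuation) plot.
#'
#' @param amplitudes Evoked amplitudes (>= 2 sweeps).
#' @param ca_mM Calcium concentration, mM.
#' @param cell_id Optional cell identifier.
#'
#' @return A one-row tibble: `ca_mM`, `mean_amp`, `variance`, `n_sweeps`,
#'   `theoretical = FALSE`, `cell_id`.
#' @export
summarize_condition <- function(amplitudes, ca_mM, cell_id = NA_character_) {
  stop_if_not(is.numeric(amplitudes) && length(amplitudes) >= 2,
              "need at least 2 sweeps to estimate a variance")
  tibble(ca_mM = ca_mM, mean_amp = mean(amplitudes),
         variance = var(amplitudes), n_sweeps = length(amplitudes),
         theoretical = FALSE, cell_id = cell_id)
}

#' Append the theoretical origin point
#'
#' In calcium-free saline no release occurs, so variance and mean are both
#' theoretically zero; this point anchors the parabola at the origin and is
#' flagged `theoretical` (it carries `n_sweeps = 0` and never enters sweep
#' accounting).
#'
#' @param points A tibble of [summarize_condition()] rows (possibly empty).
#' @return `points` with the origin appended as the last row.
#' @export
with_origin <- function(points) {
  if (nrow(points) > 0) {
    stop_if_not(!any(points$mean_amp == 0),
                "a point with mean 0 already exists")
  }
  origin <- tibble(ca_mM = 0, mean_amp = 0, variance = 0, n_sweeps = 0L,
                   theoretical = TRUE,
                   cell_id = if (nrow(points)) points$cell_id[1] else NA_character_)
  bind_rows(as_tibble(points), origin)
}

#' Fit the standard variance-mean parabola
#'
#' Under a simple binomial release model the trial-to-trial variance of the
#' evoked amplitude is a parabolic function of its mean across
#' release-probability conditions:
#' `variance = Q * mean - mean^2 / N`, where Q is the quantal size and N the
#' number of functional release sites.  The model is linear in the
#' parameters (Q, 1/N), so the unweighted least-squares optimum is computed
#' exactly by linear regression of variance on (mean, -mean^2) with no
#' intercept — the fitted parabola passes through the origin by
#' construction.  Positivity of Q and N is then checked rather than imposed:
#' data with no downward curvature leave N unidentifiable (reported as
#' `Inf`, flagged, not silently coerced), and clearly negative curvature or
#' a non-positive Q is an error carrying diagnostics.
#'
#' @param points Variance-mean points including the origin (>= 3 rows with
#'   distinct means); see [summarize_condition()] and [with_origin()].
#' @param curvature_tol Relative curvature below which N is declared
#'   unidentifiable (the data are collinear through the origin).
#'
#' @return An object of class `parabola_fit` with elements `quantal_size_Q`,
#'   `n_sites_N`, `points`, `rss`, `r_squared`, `accepted`, `flags`.
#' @seealso [release_probabilities()], [tidy.parabola_fit()]
#' @export
#' @examples
#' pts <- with_origin(tibble::tibble(
#'   ca_mM = c(1, 2, 3), mean_amp = c(2, 5, 8),
#'   variance = c(1.6, 2.5, 1.6), n_sweeps = 30, theoretical = FALSE,
#'   cell_id = "demo"))
#' fit <- fit_parabola(pts)
#' c(fit$quantal_size_Q, fit$n_sites_N)  # 1, 10
fit_parabola <- function(points, curvature_tol = 1e-8) {
  points <- as_tibble(points)
  stop_if_not(all(c("mean_amp", "variance") %in% names(points)),
              "`points` must have columns mean_amp and variance")
  stop_if_not(nrow(points) >= 3 && length(unique(points$mean_amp)) >= 3,
              "need >= 3 points with distinct means (origin included)")
  m <- points$mean_amp
  v <- points$variance
  X <- cbind(mean = m, neg_mean_sq = -m^2)
  beta <- stats::lm.fit(X, v)$coefficients
  Q <- unname(beta["mean"])
  B <- unname(beta["neg_mean_sq"])  # 1/N
  scale <- max(abs(v)) / max(m^2)
  flags <- character()
  if (!is.finite(Q) || Q <= 0) {
    abort(sprintf("parabola fit rejected: fitted quantal size Q = %.3g <= 0", Q),
          class = "quantalr_fit_error")
  }
  if (!is.finite(B) || B < -curvature_tol * max(scale, .Machine$double.eps)) {
    abort(sprintf(paste0(
      "parabola fit rejected: negative curvature (1/N = %.3g); variance grows ",
      "faster than binomial saturation allows"), B),
      class = "quantalr_fit_error")
  }
  unidentifiable <- B <= curvature_tol * max(scale, .Machine$double.eps)
  N <- if (unidentifiable) Inf else 1 / B
  if (unidentifiable) flags <- c(flags, "n_unidentifiable")
  fitted <- Q * m - if (is.finite(N)) m^2 / N else 0
  rss <- sum((v - fitted)^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - rss / ss_tot else 1
  structure(
    list(quantal_size_Q = Q, n_sites_N = N, points = points,
         fitted = fitted, rss = rss, r_squared = r2,
         accepted = !unidentifiable, flags = flags,
         cell_id = points$cell_id[1] %||% NA_character_),
    class = "parabola_fit"
  )
}

#' Per-condition release probability from a parabola fit
#'
#' Since quantal content equals N x p and the mean amplitude is
#' `N * p * Q`, the release probability at each measured condition is
#' `p = mean_amp / (N * Q)`.  Values above 1 are flagged and returned with a
#' warning (they indicate a failure of the simple binomial model, not a
#' probability).
#'
#' @param fit An accepted `parabola_fit`.
#' @param points Points to evaluate (defaults to the fit's measured,
#'   non-theoretical points plus the origin at p = 0).
#'
#' @return A tibble: `ca_mM`, `mean_amp`, `p`, `flagged`.
#' @export
release_probabilities <- function(fit, points = NULL) {
  stopifnot(inherits(fit, "parabola_fit"))
  stop_if_not(fit$accepted, "release probabilities need an accepted fit (finite N)")
  points <- as_tibble(points %||% fit$points)
  p <- points$mean_amp / (fit$n_sites_N * fit$quantal_size_Q)
  flagged <- p > 1
  if (any(flagged)) {
    warn(sprintf("%d release probability value(s) exceed 1; binomial model violated",
                 sum(flagged)))
  }
  tibble(ca_mM = points$ca_mM, mean_amp = points$mean_amp, p = p,
         flagged = flagged)
}

#' Variance-mean analysis of one cell's calcium titration
#'
#' Convenience wrapper: summarizes each calcium condition, appends the
#' theoretical origin, and fits the standard parabola.
#'
#' @param sweeps A tibble with columns `ca_mM` and `amplitude` (one row per
#'   sweep).
#' @param cell_id Optional identifier.
#' @return A `parabola_fit`.
#' @export
varmean_analysis <- function(sweeps, cell_id = NA_character_) {
  pts <- sweeps |>
    summarise(point = list(summarize_condition(.data$amplitude,
                                               .data$ca_mM[1], cell_id)),
              .by = "ca_mM") |>
    pull("point") |>
    list_rbind()
  fit_parabola(with_origin(pts))
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf(
    "<parabola_fit> Q = %.3g, N = %s (%d points incl. origin, r^2 = %.4f%s)\n",
    x$quantal_size_Q,
    if (is.finite(x$n_sites_N)) sprintf("%.1f", x$n_sites_N) else "unidentifiable",
    nrow(x$points), x$r_squared,
    if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Tidy and glance methods for parabola fits
#'
#' @param x A `parabola_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`quantal_size_Q`, `n_sites_N`);
#'   `glance()`: a one-row fit summary.
#' @method tidy parabola_fit
#' @export
tidy.parabola_fit <- function(x, ...) {
  tibble(term = c("quantal_size_Q", "n_sites_N"),
         estimate = c(x$quantal_size_Q, x$n_sites_N))
}

#' @rdname tidy.parabola_fit
#' @method glance parabola_fit
#' @export
glance.parabola_fit <- function(x, ...) {
  tibble(quantal_size_Q = x$quantal_size_Q, n_sites_N = x$n_sites_N,
         rss = x$rss, r_squared = x$r_squared,
         n_points = nrow(x$points),
         n_sweeps = sum(x$points$n_sweeps),
         accepted = x$accepted,
         flags = paste(x$flags, collapse = ","),
         cell_id = x$cell_id)
}

#' Plot a variance-mean parabola fit
#'
#' @param object A `parabola_fit`.
#' @param ... Unused.
#' @return A ggplot object: measured points, the theoretical origin, and the
#'   fitted parabola.
#' @method autoplot parabola_fit
#' @export
autoplot.parabola_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(mean_amp = seq(0, max(pts$mean_amp) * 1.05, length.out = 200))
  grid$variance <- object$quantal_size_Q * grid$mean_amp -
    if (is.finite(object$n_sites_N)) grid$mean_amp^2 / object$n_sites_N else 0
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_amp, y = .data$variance)) +
    ggplot2::geom_line(data = grid, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$theoretical), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "mean amplitude", y = "variance",
                  title = sprintf("Q = %.2f, N = %s", object$quantal_size_Q,
                                  if (is.finite(object$n_sites_N))
                                    sprintf("%.0f", object$n_sites_N)
                                  else "unidentifiable"))
}
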