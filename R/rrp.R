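#' Cumulative evoked amplitude of a stimulus train
#'
#' @param train A [train_response()].
#' @return The train tibble with an added `cumulative` column
#'   (running sum of amplitudes, nondecreasing for nonnegative amplitudes).
#' @export
cumulative_series <- function(train) {
  stopifnot(inherits(train, "train_response"))
  out <- mutate(train, cumulative = cumsum(.data$amplitude))
  out
}

#' Back-extrapolate the linear phase of the cumulative train response
#'
#' Fits an ordinary least-squares line to the cumulative amplitude over the
#' late, linear phase of the train (stimuli 18-30 by default, 1-based
#' inclusive) against time, with the first stimulus at t = 0
#' (`t_k = (k - 1)/freq`), and evaluates the line at t = 0.  During the
#' linear phase release is balanced by replenishment, so the zero-time
#' intercept estimates the response of the pool available before the train.
#'
#' @param train A [train_response()] with at least `max(window)` stimuli.
#' @param window Stimulus-index window `c(first, last)`, 1-based inclusive.
#'
#' @return A one-row tibble: `slope` (units/s), `intercept_at_t0`,
#'   `r_squared`, `window_start`, `window_end`.
#' @export
backextrapolate <- function(train, window = c(18, 30)) {
  stopifnot(inherits(train, "train_response"))
  stop_if_not(length(window) == 2 && window[1] >= 1 &&
                window[2] >= window[1] && window[2] <= nrow(train),
              "invalid fit window for this train")
  idx <- seq(window[1], window[2])
  stop_if_not(length(idx) >= 3, "fit window must contain at least 3 stimuli")
  cs <- cumulative_series(train)
  fit <- lm(cumulative ~ time, data = cs[idx, ])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((cs$cumulative[idx] - mean(cs$cumulative[idx]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  tibble(slope = unname(coef(fit)[2]),
         intercept_at_t0 = unname(coef(fit)[1]),
         r_squared = r2,
         window_start = window[1], window_end = window[2])
}

#' Estimate readily-releasable-pool size from a train
#'
#' The RRP (in quanta) is the back-extrapolated cumulative amplitude at time
#' zero divided by the mean miniature amplitude of the same cell and mode.
#' A negative intercept is reported with a quality flag, never silently
#' clamped.
#'
#' @param train A [train_response()] (TEVC amplitudes, nA).
#' @param mean_mepsc Mean miniature amplitude, same units (> 0).
#' @param window Back-extrapolation window, see [backextrapolate()].
#' @param mepsc_source Provenance note for `mean_mepsc` (e.g. `"same_cell"`
#'   or `"user_supplied"`).
#'
#' @return An object of class `rrp_estimate`; see [tidy.rrp_estimate()] and
#'   [glance.rrp_estimate()].
#' @export
#' @examples
#' tr <- train_response(c(50, rep(10, 29)), freq = 60)
#' est <- estimate_rrp(tr, mean_mepsc = 1)
#' est$rrp_quanta  # 50
estimate_rrp <- function(train, mean_mepsc, window = c(18, 30),
                         mepsc_source = "user_supplied") {
  stop_if_not(is_pos(mean_mepsc), "`mean_mepsc` must be > 0")
  line <- backextrapolate(train, window)
  rrp <- line$intercept_at_t0 / mean_mepsc
  structure(
    list(train = train, cumulative = cumulative_series(train),
         window = c(line$window_start, line$window_end),
         slope = line$slope, intercept_at_t0 = line$intercept_at_t0,
         r_squared = line$r_squared, mean_mepsc = mean_mepsc,
         mepsc_source = mepsc_source, rrp_quanta = rrp,
         negative_intercept = line$intercept_at_t0 < 0,
         freq = attr(train, "freq"), ca_mM = attr(train, "ca_mM"),
         cell_id = attr(train, "cell_id")),
    class = "rrp_estimate"
  )
}

#' @export
print.rrp_estimate <- function(x, ...) {
  cat(sprintf(
    "<rrp_estimate> RRP = %.1f quanta (intercept %.3g / mean mEPSC %.3g; stimuli %d-%d, r^2 = %.4f)%s\n",
    x$rrp_quanta, x$intercept_at_t0, x$mean_mepsc, x$window[1], x$window[2],
    x$r_squared,
    if (x$negative_intercept) "  [flag: negative intercept]" else ""))
  invisible(x)
}

#' Tidy and glance methods for RRP estimates
#'
#' @param x An `rrp_estimate`.
#' @param ... Unused.
#' @return `tidy()`: one row per quantity (`slope`, `intercept_at_t0`,
#'   `rrp_quanta`); `glance()`: a one-row fit summary.
#' @method tidy rrp_estimate
#' @export
tidy.rrp_estimate <- function(x, ...) {
  tibble(term = c("slope", "intercept_at_t0", "rrp_quanta"),
         estimate = c(x$slope, x$intercept_at_t0, x$rrp_quanta))
}

#' @rdname tidy.rrp_estimate
#' @method glance rrp_estimate
#' @export
glance.rrp_estimate <- function(x, ...) {
  tibble(rrp_quanta = x$rrp_quanta, intercept_at_t0 = x$intercept_at_t0,
         slope = x$slope, r_squared = x$r_squared,
         mean_mepsc = x$mean_mepsc, mepsc_source = x$mepsc_source,
         window_start = x$window[1], window_end = x$window[2],
         n_stimuli = nrow(x$train),
         negative_intercept = x$negative_intercept)
}

#' Plot an RRP back-extrapolation
#'
#' Cumulative amplitude against time with the fitted line extended to t = 0.
#'
#' @param object An `rrp_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rrp_estimate
#' @export
autoplot.rrp_estimate <- function(object, ...) {
  cs <- object$cumulative
  idx <- seq(object$window[1], object$window[2])
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$time, y = .data$cumulative)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = cs[idx, ], colour = "firebrick", size = 1) +
    ggplot2::geom_abline(intercept = object$intercept_at_t0,
                         slope = object$slope, linetype = "dashed") +
    ggplot2::annotate("point", x = 0, y = object$intercept_at_t0,
                      shape = 4, size = 3) +
    ggplot2::labs(x = "time (s)", y = "cumulative amplitude",
                  title = sprintf("RRP = %.0f quanta", object$rrp_quanta))
}
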