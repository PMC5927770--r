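#' Construct a trace recording
#'
#' A single uniformly sampled sweep (current-clamp voltage in mV or
#' two-electrode voltage-clamp current in nA) stored as a tibble with columns
#' `time` (s) and `value`, carrying sampling rate, stimulus times and
#' condition metadata as attributes.
#'
#' @param value Numeric vector of samples.
#' @param sampling_rate Sampling rate, Hz.
#' @param stim_times Stimulus times, s (sorted, within the sweep).
#' @param mode `"current_clamp"` or `"tevc"`.
#' @param metadata Named list of condition metadata (genotype, muscle,
#'   ca_mM, cell_id, ...).
#'
#' @return A tibble of class `trace_recording` with columns `time`, `value`.
#' @export
trace_recording <- function(value, sampling_rate, stim_times = numeric(),
                            mode = c("current_clamp", "tevc"),
                            metadata = list()) {
  mode <- match.arg(mode)
  stop_if_not(is.numeric(value) && length(value) >= 1, "`value` must be a numeric vector")
  stop_if_not(is_pos(sampling_rate), "`sampling_rate` must be > 0")
  duration <- length(value) / sampling_rate
  stim_times <- sort(as.numeric(stim_times))
  stop_if_not(all(stim_times >= 0 & stim_times <= duration),
              "`stim_times` must lie within the trace span")
  out <- tibble(time = (seq_along(value) - 1) / sampling_rate, value = value)
  structure(out,
            class = c("trace_recording", class(out)),
            sampling_rate = sampling_rate,
            stim_times = stim_times,
            mode = mode,
            metadata = metadata)
}

#' @export
print.trace_recording <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<trace_recording> %d samples @ %g Hz (%.3g s), mode %s, %d stimuli\n",
              nrow(x), attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate"),
              attr(x, "mode"), length(attr(x, "stim_times"))))
  if (length(md)) {
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

trace_sampling_rate <- function(trace) attr(trace, "sampling_rate")
trace_mode <- function(trace) attr(trace, "mode")
trace_stim_times <- function(trace) attr(trace, "stim_times")

# Sign that maps raw deflections onto positive "response magnitude" units:
# depolarizations are positive-going in current clamp, synaptic currents are
# inward (negative) under TEVC and reported as magnitudes.
trace_sign <- function(trace) {
  if (identical(trace_mode(trace), "tevc")) -1 else 1
}

#' Plot a trace recording
#'
#' @param object A [trace_recording()].
#' @param ... Unused.
#' @return A ggplot object: value vs time, stimulus times as vertical marks.
#' @export
autoplot.trace_recording <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = if (trace_mode(object) == "tevc") "current (nA)" else "potential (mV)")
  st <- trace_stim_times(object)
  if (length(st)) {
    p <- p + ggplot2::geom_vline(xintercept = st, colour = "firebrick",
                                 alpha = 0.4, linetype = "dotted")
  }
  p
}
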