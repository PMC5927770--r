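#' Detect spontaneous miniature events in a trace
#'
#' Events are local deflections (depolarizing in current clamp, inward under
#' TEVC) that exceed `threshold` above a running-median baseline.  The
#' sign-rectified, baseline-subtracted trace is lightly smoothed (boxcar,
#' `smooth` seconds) for threshold crossing; the amplitude of each event is
#' the unsmoothed extremum minus a local pre-onset baseline (median over
#' `pre_window` seconds before onset).  Candidate events whose peaks fall
#' within `refractory` of each other are merged, keeping the larger peak.
#'
#' @param trace A [trace_recording()] of a spontaneous segment (or with
#'   stimulus windows already masked).
#' @param threshold Detection threshold in trace units (> 0).
#' @param refractory Merge window, s.
#' @param baseline_window Running-median window, s; robust to slow drift.
#' @param smooth Boxcar width for threshold crossing, s.
#' @param pre_window Local-baseline window before event onset, s.
#'
#' @return An `event_table` tibble: `time` (peak, s), `amplitude` (magnitude,
#'   trace units), `baseline` (local baseline in rectified units) and
#'   `rise_time` (10-90%, s).
#' @export
detect_minis <- function(trace, threshold, refractory = 0.005,
                         baseline_window = 0.05, smooth = 0.001,
                         pre_window = 0.002) {
  stopifnot(inherits(trace, "trace_recording"))
  stop_if_not(nrow(trace) > 0, "empty trace")
  stop_if_not(is_pos(threshold), "`threshold` must be > 0")
  fs <- trace_sampling_rate(trace)
  sgn <- trace_sign(trace)
  v <- sgn * trace$value
  k <- max(3L, 2L * floor(baseline_window * fs / 2) + 1L)
  k <- min(k, 2L * floor((length(v) - 1) / 2) + 1L)
  base <- stats::runmed(v, k, endrule = "median")
  w <- v - base
  m <- max(1L, round(smooth * fs))
  ws <- if (m > 1) {
    as.numeric(stats::filter(w, rep(1 / m, m), sides = 2))
  } else {
    w
  }
  ws[is.na(ws)] <- 0
  above <- ws > threshold
  if (!any(above)) {
    return(empty_event_table())
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # suprathreshold stretches separated by less than the refractory window
  # belong to one event (noise briefly dipping below threshold in the tail)
  gap <- round(refractory * fs)
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] < gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  npre <- max(1L, round(pre_window * fs))
  events <- apply(runs, 1, function(run) {
    i1 <- run[1]; i2 <- run[2]
    peak <- i1 - 1L + which.max(ws[i1:i2])  # smoothed peak: stable timing
    pre <- v[max(1L, i1 - npre):max(1L, i1 - 1L)]
    local_base <- median(pre)
    amp <- max(v[i1:i2]) - local_base
    # 10-90% rise over the rising limb before the peak
    seg <- v[i1:peak] - local_base
    t10 <- which(seg >= 0.1 * amp)[1]
    t90 <- which(seg >= 0.9 * amp)[1]
    rise <- if (is.na(t10) || is.na(t90)) NA_real_ else (t90 - t10) / fs
    c(time = (peak - 1) / fs, amplitude = amp, baseline = local_base,
      rise_time = rise)
  })
  out <- as_tibble(t(events))
  out <- out[out$amplitude > 0, , drop = FALSE]
  out <- merge_refractory(out, refractory)
  structure(out, class = c("event_table", class(out)))
}

empty_event_table <- function() {
  out <- tibble(time = numeric(), amplitude = numeric(),
                baseline = numeric(), rise_time = numeric())
  structure(out, class = c("event_table", class(out)))
}

merge_refractory <- function(events, refractory) {
  if (nrow(events) < 2) return(events)
  events <- arrange(events, .data$time)
  keep <- rep(TRUE, nrow(events))
  last <- 1L
  for (i in 2:nrow(events)) {
    if (events$time[i] - events$time[last] < refractory) {
      if (events$amplitude[i] > events$amplitude[last]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  events[keep, , drop = FALSE]
}

#' Measure evoked response amplitudes around stimulus times
#'
#' For each stimulus, the amplitude is the peak sign-rectified deflection
#' within `window` seconds after the stimulus, minus a baseline taken
#' immediately before that stimulus (`"local"`, the default — appropriate
#' for trains, where residual decay from the previous response is absorbed
#' into the per-stimulus baseline) or before the first stimulus
#' (`"pre_train"`).  Measurement windows are truncated at the next stimulus;
#' in non-train recordings (inter-stimulus interval > 0.1 s) truncation
#' raises a warning.
#'
#' @param trace A [trace_recording()] with at least one stimulus time.
#' @param window Post-stimulus search window, s.
#' @param baseline_window Baseline-averaging window, s.
#' @param baseline `"local"` or `"pre_train"`.
#'
#' @return An `evoked_response_set` tibble: `stim_index`, `stim_time`,
#'   `amplitude` (magnitude), `baseline`, `ca_mM`, `rejected`.
#' @export
measure_evoked <- function(trace, window = 0.012, baseline_window = 0.002,
                           baseline = c("local", "pre_train")) {
  stopifnot(inherits(trace, "trace_recording"))
  baseline <- match.arg(baseline)
  stims <- trace_stim_times(trace)
  stop_if_not(length(stims) >= 1, "trace has no stimulus times")
  fs <- trace_sampling_rate(trace)
  sgn <- trace_sign(trace)
  v <- sgn * trace$value
  n <- length(v)
  nb <- max(1L, round(baseline_window * fs))
  isi <- if (length(stims) > 1) diff(stims) else Inf
  base_value <- function(i0) {
    mean(v[max(1L, i0 - nb):max(1L, i0 - 1L)])
  }
  pre_train_base <- base_value(floor(stims[1] * fs) + 1L)
  out <- purrr::map(seq_along(stims), function(k) {
    i0 <- floor(stims[k] * fs) + 1L
    w_end <- stims[k] + window
    truncated <- FALSE
    if (k < length(stims) && w_end > stims[k + 1]) {
      w_end <- stims[k + 1]
      truncated <- TRUE
      if (isi[k] > 0.1) {
        warn(sprintf("measurement window at stimulus %d overlaps the next stimulus; truncated", k))
      }
    }
    i1 <- min(n, floor(w_end * fs) + 1L)
    b <- if (baseline == "local") base_value(i0) else pre_train_base
    amp <- max(v[i0:i1]) - b
    tibble(stim_index = k, stim_time = stims[k],
           amplitude = max(0, amp), baseline = b, rejected = FALSE,
           truncated = truncated)
  }) |> list_rbind()
  out$ca_mM <- attr(trace, "metadata")$ca_mM %||% NA_real_
  structure(out, class = c("evoked_response_set", class(out)))
}

#' Match detected events against a ground-truth injection list
#'
#' Greedy one-to-one matching within `tol` seconds, used to score detection
#' performance on synthetic traces whose true event list is known.
#'
#' @param detected An `event_table` (or data frame with `time`).
#' @param truth A data frame with the injected event `time`s.
#' @param tol Match window, s.
#' @return A one-row tibble: `n_true`, `n_detected`, `n_matched`,
#'   `precision`, `recall`.
#' @export
match_events <- function(detected, truth, tol = 0.002) {
  td <- sort(detected$time)
  tt <- sort(truth$time)
  used <- rep(FALSE, length(td))
  matched <- 0L
  for (t0 in tt) {
    d <- abs(td - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble(n_true = length(tt), n_detected = length(td), n_matched = matched,
         precision = if (length(td)) matched / length(td) else NA_real_,
         recall = if (length(tt)) matched / length(tt) else NA_real_)
}

#' Export an event or evoked-response table with metadata header
#'
#' Writes a tidy delimited table preceded by `#`-prefixed metadata lines.
#'
#' @param x A data frame (e.g. an `event_table`).
#' @param path Output file.
#' @param metadata Named list written as `# key: value` header lines.
#' @return The path, invisibly.
#' @export
export_table <- function(x, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(metadata)) {
    writeLines(sprintf("# %s: %s", nm, format(metadata[[nm]])), con)
  }
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
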