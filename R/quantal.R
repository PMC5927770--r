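#' Quantal content from evoked and miniature amplitudes
#'
#' Quantal content — the number of vesicles released per action potential —
#' is estimated as the ratio of the mean evoked amplitude to the mean
#' miniature amplitude recorded in the same mode; theoretically it equals
#' N x P, the product of functional release-site number and release
#' probability.
#'
#' @param epsp_mean Mean evoked amplitude(s).
#' @param mepsp_mean Mean miniature amplitude(s), same units and recording
#'   mode (> 0).
#' @param mode,mini_mode Optional recording-mode labels; supplying different
#'   modes is an error (evoked potentials cannot be divided by miniature
#'   currents).
#'
#' @return Quantal content (dimensionless), vectorized over inputs.
#' @export
#' @examples
#' quantal_content(40, 1)   # 40 quanta
quantal_content <- function(epsp_mean, mepsp_mean, mode = NULL,
                            mini_mode = NULL) {
  if (!is.null(mode) && !is.null(mini_mode) && !identical(mode, mini_mode)) {
    abort("evoked and miniature amplitudes come from different recording modes",
          class = "quantalr_mode_error")
  }
  stop_if_not(all(is.finite(mepsp_mean)) && all(mepsp_mean > 0),
              "`mepsp_mean` must be > 0")
  epsp_mean / mepsp_mean
}

#' Per-cell quantal summary
#'
#' Summarizes one cell's spontaneous and evoked recordings into the standard
#' quantal measures: mean miniature amplitude, mean evoked amplitude, and
#' quantal content (per-cell ratio of means).
#'
#' @param mini_amplitudes Miniature event amplitudes (>= 1).
#' @param evoked_amplitudes Evoked response amplitudes (>= 1).
#' @param cell_id,muscle,genotype Metadata carried into the summary row.
#' @param mode Recording mode of both measurements.
#' @param rin,vrest Optional passive-property pass-through (input resistance
#'   in MOhm, resting potential in mV).
#'
#' @return A one-row tibble: metadata, `mepsp_mean`, `epsp_mean`,
#'   `quantal_content`, `n_minis`, `n_evoked`, `rin`, `vrest`.
#' @export
quantal_summary <- function(mini_amplitudes, evoked_amplitudes,
                            cell_id = NA_character_, muscle = NA_character_,
                            genotype = NA_character_,
                            mode = "current_clamp",
                            rin = NA_real_, vrest = NA_real_) {
  stop_if_not(length(mini_amplitudes) >= 1 && length(evoked_amplitudes) >= 1,
              "need at least one miniature and one evoked amplitude")
  mepsp <- mean(mini_amplitudes)
  epsp <- mean(evoked_amplitudes)
  tibble(cell_id = cell_id, muscle = muscle, genotype = genotype, mode = mode,
         mepsp_mean = mepsp, epsp_mean = epsp,
         quantal_content = quantal_content(epsp, mepsp),
         n_minis = length(mini_amplitudes),
         n_evoked = length(evoked_amplitudes),
         rin = rin, vrest = vrest)
}

#' Normalize per-cell values to a control group, as percentages
#'
#' Computes `100 * mean(values) / mean(baseline_values)` with the standard
#' error propagated by the delta method for a ratio of independent group
#' means.
#'
#' @param values Per-cell values of the test group.
#' @param baseline_values Per-cell values of the control/baseline group
#'   (mean > 0).
#'
#' @return A one-row tibble: `percent`, `sem` (both in %), `n`, `n_baseline`.
#' @export
normalize_to_baseline <- function(values, baseline_values) {
  stop_if_not(length(values) >= 1 && length(baseline_values) >= 1,
              "empty input")
  mb <- mean(baseline_values)
  stop_if_not(is.finite(mb) && mb > 0, "baseline mean must be > 0")
  mv <- mean(values)
  ratio <- mv / mb
  se_v <- if (length(values) > 1) sd(values) / sqrt(length(values)) else 0
  se_b <- if (length(baseline_values) > 1) {
    sd(baseline_values) / sqrt(length(baseline_values))
  } else 0
  sem <- 100 * abs(ratio) * sqrt((se_v / mv)^2 + (se_b / mb)^2)
  tibble(percent = 100 * ratio, sem = sem,
         n = length(values), n_baseline = length(baseline_values))
}

#' Assess presynaptic homeostatic potentiation between two groups
#'
#' Implements the three-way decision logic used to diagnose PHP from
#' per-cell quantal summaries: PHP is expressed when (i) the miniature
#' amplitude is significantly reduced relative to control, (ii) the evoked
#' amplitude is not significantly different (synaptic strength maintained),
#' and (iii) quantal content is significantly increased.  Comparisons use
#' Student's t tests at level `alpha`.
#'
#' @param test,control Tibbles of per-cell [quantal_summary()] rows (>= 2
#'   cells each, same muscle and mode).
#' @param alpha Significance level.
#'
#' @return A one-row tibble of class `php_report`: normalized miniature and
#'   quantal-content percentages (with delta-method SEM), the three
#'   comparison p-values, and the flags `mini_reduced`, `epsp_maintained`,
#'   `qc_increased`, `php_expressed`.
#' @export
php_assessment <- function(test, control, alpha = 0.05) {
  for (df in list(test, control)) {
    stop_if_not(all(c("mepsp_mean", "epsp_mean", "quantal_content") %in%
                      names(df)), "inputs must be quantal summary tables")
    stop_if_not(nrow(df) >= 2, "need >= 2 cells per group for a variance estimate")
  }
  if (all(c("mode") %in% names(test)) && all(c("mode") %in% names(control))) {
    stop_if_not(length(unique(c(test$mode, control$mode))) == 1,
                "test and control summaries mix recording modes")
  }
  cmp <- function(a, b) two_group_test(a, b)$p_value
  p_mini <- cmp(test$mepsp_mean, control$mepsp_mean)
  p_epsp <- cmp(test$epsp_mean, control$epsp_mean)
  p_qc <- cmp(test$quantal_content, control$quantal_content)
  mini_reduced <- p_mini < alpha &&
    mean(test$mepsp_mean) < mean(control$mepsp_mean)
  epsp_maintained <- p_epsp >= alpha
  qc_increased <- p_qc < alpha &&
    mean(test$quantal_content) > mean(control$quantal_content)
  norm_mini <- normalize_to_baseline(test$mepsp_mean, control$mepsp_mean)
  norm_qc <- normalize_to_baseline(test$quantal_content,
                                   control$quantal_content)
  out <- tibble(
    genotype = test$genotype[1] %||% NA_character_,
    muscle = test$muscle[1] %||% NA_character_,
    baseline = control$genotype[1] %||% NA_character_,
    mepsp_percent = norm_mini$percent, mepsp_sem = norm_mini$sem,
    qc_percent = norm_qc$percent, qc_sem = norm_qc$sem,
    p_mepsp = p_mini, p_epsp = p_epsp, p_qc = p_qc,
    mini_reduced = mini_reduced, epsp_maintained = epsp_maintained,
    qc_increased = qc_increased,
    php_expressed = mini_reduced && epsp_maintained && qc_increased,
    alpha = alpha, n_test = nrow(test), n_control = nrow(control))
  structure(out, class = c("php_report", class(out)))
}

#' @export
print.php_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("<php_report> %s, muscle %s (vs %s, n = %d/%d, alpha = %g)\n",
                r$genotype, r$muscle, r$baseline, r$n_test, r$n_control,
                r$alpha))
    cat(sprintf("  mEPSP %6.1f +/- %.1f %%   (p = %.3g, reduced: %s)\n",
                r$mepsp_percent, r$mepsp_sem, r$p_mepsp, r$mini_reduced))
    cat(sprintf("  QC    %6.1f +/- %.1f %%   (p = %.3g, increased: %s)\n",
                r$qc_percent, r$qc_sem, r$p_qc, r$qc_increased))
    cat(sprintf("  EPSP maintained: %s (p = %.3g)\n",
                r$epsp_maintained, r$p_epsp))
    cat(sprintf("  PHP expressed: %s\n", r$php_expressed))
  }
  invisible(x)
}
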