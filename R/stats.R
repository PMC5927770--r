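#' Two-group comparison (Student's t test)
#'
#' Equal-variance Student's t test by default, matching the standard
#' reporting of pairwise electrophysiological comparisons; Welch's
#' correction is available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param label Comparison label carried into the result.
#' @param var_equal Assume equal variances (Student) or not (Welch).
#'
#' @return A one-row `stat_result` tibble: `comparison`, `test`,
#'   `statistic`, `p_value`, group means, SEMs and sizes.
#' @export
two_group_test <- function(a, b, label = "a vs b", var_equal = TRUE) {
  stop_if_not(length(a) >= 2 && length(b) >= 2,
              "each group needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (identical(mean(a), mean(b))) {
      # degenerate but well-defined boundary: no difference, no evidence
      return(stat_result_row(label, "t_test", 0, 1, a, b))
    }
    abort("zero within-group variance in both groups", class = "quantalr_stat_error")
  }
  ht <- t.test(a, b, var.equal = var_equal)
  stat_result_row(label, if (var_equal) "t_test" else "welch_t_test",
                  unname(ht$statistic), ht$p.value, a, b)
}

stat_result_row <- function(label, test, statistic, p_value, a, b) {
  out <- tibble(
    comparison = label, test = test, statistic = statistic,
    p_value = p_value,
    mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)), n_a = length(a),
    mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)), n_b = length(b))
  structure(out, class = c("stat_result", class(out)))
}

#' One-way ANOVA with Tukey's multiple-comparison test
#'
#' Omnibus one-way ANOVA followed by Tukey's HSD (studentized range,
#' family-wise adjusted p per pair), the standard scheme for multi-genotype
#' comparisons.
#'
#' @param values Numeric response vector, or a named list of group vectors.
#' @param groups Group labels (ignored when `values` is a list).
#' @param label Family label.
#'
#' @return A `stat_result` tibble: one `anova` row (F statistic, p) followed
#'   by one `tukey` row per pair (statistic = mean difference, family-wise
#'   adjusted p).
#' @export
anova_tukey <- function(values, groups = NULL, label = "one-way") {
  if (is.list(values) && !is.data.frame(values)) {
    stop_if_not(!is.null(names(values)), "group list must be named")
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  stop_if_not(nlevels(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(table(groups) >= 2), "each group needs >= 2 values")
  if (all(tapply(values, groups, sd) == 0)) {
    abort("zero within-group variance in all groups", class = "quantalr_stat_error")
  }
  df <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  omnibus <- tibble(
    comparison = label, test = "anova",
    statistic = unname(an[["F value"]][1]),
    p_value = unname(an[["Pr(>F)"]][1]),
    mean_a = NA_real_, sem_a = NA_real_, n_a = length(values),
    mean_b = NA_real_, sem_b = NA_real_, n_b = nlevels(groups))
  tk <- TukeyHSD(fit)$g
  pairs <- tibble(
    comparison = rownames(tk), test = "tukey",
    statistic = unname(tk[, "diff"]), p_value = unname(tk[, "p adj"]),
    mean_a = NA_real_, sem_a = NA_real_, n_a = NA_integer_,
    mean_b = NA_real_, sem_b = NA_real_, n_b = NA_integer_)
  out <- bind_rows(omnibus, pairs)
  structure(out, class = c("stat_result", class(out)))
}
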