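#' Anxiety-score differences across contextual-variable levels
#'
#' Tests the STAI-S score across the levels of each contextual variable,
#' using the Wilcoxon rank-sum test for two-level variables and the
#' Kruskal-Wallis test (tie-corrected) for variables with more than two
#' levels. Age enters as its three-level bin; years of education are not
#' tested.
#'
#' @param cohort Cohort analysis table with `stai_s` and contextual
#'   columns.
#' @param vars Contextual variables to test. Default: loneliness, age_bin,
#'   sex, income, marital, employment, edu, race_ethnicity, covid_test,
#'   covid_diagnosis.
#' @return Data frame with `variable`, `test`, `n_levels`, `p_value`,
#'   `note` (non-empty when a variable was skipped).
#' @export
contextual_differences <- function(cohort,
                                   vars = c("loneliness", "age_bin", "sex",
                                            "income", "marital",
                                            "employment", "edu",
                                            "race_ethnicity", "covid_test",
                                            "covid_diagnosis")) {
  rows <- lapply(vars, function(v) {
    g <- factor(cohort[[v]])
    g <- droplevels(g)
    nl <- nlevels(g)
    if (nl < 2L)
      return(data.frame(variable = v, test = NA_character_, n_levels = nl,
                        p_value = NA_real_, note = "single level; skipped"))
    if (nl == 2L) {
      p <- stats::wilcox.test(cohort$stai_s ~ g, exact = FALSE)$p.value
      data.frame(variable = v, test = "wilcoxon_rank_sum", n_levels = nl,
                 p_value = p, note = "")
    } else {
      p <- stats::kruskal.test(cohort$stai_s ~ g)$p.value
      data.frame(variable = v, test = "kruskal_wallis", n_levels = nl,
                 p_value = p, note = "")
    }
  })
  do.call(rbind, rows)
}

#' Judgment-variable median shifts between anxiety groups
#'
#' Divides each judgment variable into higher/lower groups following the
#' anxiety-score grouping at each threshold and runs both one-sided
#' Wilcoxon rank-sum tests (alternative: higher-group median greater than
#' the lower group's, and the reverse). Bonferroni correction is applied
#' within each judgment variable across its six tests (two directions x
#' three thresholds), so the corrected significance level is 0.05/6.
#' The normal approximation with tie correction is used at cohort scale;
#' the exact test when both groups have under 50 observations.
#'
#' @param cohort Cohort analysis table with the judgment variables and
#'   `stai_s`.
#' @param thresholds STAI-S thresholds (default 35, 45, 55).
#' @param vars Judgment variables to test.
#' @param alpha Uncorrected significance level.
#' @return Data frame with one row per variable x threshold x direction:
#'   `variable`, `threshold`, `alternative` (`"H>L"` or `"H<L"`),
#'   `p_value`, `significant` (p < alpha), `significant_bonferroni`
#'   (p < alpha / 6).
#' @export
judgment_differences <- function(cohort, thresholds = c(35, 45, 55),
                                 vars = judgment_variable_names(),
                                 alpha = 0.05) {
  n_tests_per_var <- 2L * length(thresholds)
  rows <- list(); k <- 0L
  for (v in vars) {
    x <- cohort[[v]]
    for (th in thresholds) {
      hi <- cohort$stai_s >= th
      if (!any(hi) || all(hi)) next  # empty group: skip this threshold
      # exact distribution for small untied groups; tie-corrected normal
      # approximation otherwise
      exact <- sum(hi) < 50 && sum(!hi) < 50 && !anyDuplicated(x)
      for (alt in c("H>L", "H<L")) {
        p <- stats::wilcox.test(
          x[hi], x[!hi],
          alternative = if (alt == "H>L") "greater" else "less",
          exact = exact, correct = TRUE)$p.value
        k <- k + 1L
        rows[[k]] <- data.frame(
          variable = v, threshold = th, alternative = alt, p_value = p,
          significant = p < alpha,
          significant_bonferroni = p < alpha / n_tests_per_var)
      }
    }
  }
  do.call(rbind, rows)
}

#' Boxplot-style summaries of judgment variables by anxiety group
#'
#' @param cohort Cohort analysis table.
#' @param threshold STAI-S threshold for grouping.
#' @param vars Judgment variables to summarise.
#' @return Data frame of median and quartiles per variable and group.
#' @export
judgment_group_summaries <- function(cohort, threshold,
                                     vars = judgment_variable_names()) {
  hi <- cohort$stai_s >= threshold
  rows <- list(); k <- 0L
  for (v in vars) {
    for (grp in c("higher", "lower")) {
      x <- cohort[[v]][if (grp == "higher") hi else !hi]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
      k <- k + 1L
      rows[[k]] <- data.frame(variable = v, group = grp, threshold = threshold,
                              q25 = q[[1]], median = q[[2]], q75 = q[[3]],
                              n = length(x))
    }
  }
  do.call(rbind, rows)
}
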