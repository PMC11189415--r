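#' Mediation analysis (Baron-Kenny four-step with Sobel test)
#'
#' Fits the three ordinary least-squares regressions
#' `Y = g1 + c*X`, `Me = g2 + a*X`, `Y = g3 + c'*X + b*Me`, then the Sobel
#' z-score `ab / sqrt(b^2 s_a^2 + a^2 s_b^2)` (identical to
#' `(c - c') / sqrt(...)` because `c - c' = ab` holds exactly for these
#' nested OLS fits) with a two-tailed normal p-value, and the mediated
#' percentage `T_eff = 100 * (1 - c'/c)`. Mediation is significant when the
#' `a`, `b` and `c` p-values and the Sobel p-value are all below 0.05 and
#' `T_eff` exceeds 50 percent.
#'
#' @param X,Me,Y Numeric vectors of equal length (independent variable,
#'   candidate mediator, outcome), length at least 10.
#' @param alpha Significance level for the coefficient tests.
#' @return A `mediation_result` list: coefficients `c`, `a`, `b`,
#'   `c_prime` with standard errors and p-values, intercepts, residual
#'   variances, `sobel_z`, `p_sobel`, `t_eff` (percent), `significant`,
#'   and `reason` when the verdict is forced false.
#' @export
mediate <- function(X, Me, Y, alpha = 0.05) {
  n <- length(Y)
  stopifnot(length(X) == n, length(Me) == n)
  if (n < 10L) stop("mediation requires at least 10 observations")
  if (stats::sd(X) == 0 || stats::sd(Me) == 0)
    stop("X and Me must be non-constant")

  f1 <- stats::lm(Y ~ X)
  f2 <- stats::lm(Me ~ X)
  f3 <- stats::lm(Y ~ X + Me)
  if (anyNA(stats::coef(f3)))
    stop("collinear predictors: Me is aliased with X in the joint model")

  s1 <- summary(f1)$coefficients
  s2 <- summary(f2)$coefficients
  s3 <- summary(f3)$coefficients
  cc <- s1["X", "Estimate"];  p_c <- s1["X", "Pr(>|t|)"]
  a <- s2["X", "Estimate"];  s_a <- s2["X", "Std. Error"]
  p_a <- s2["X", "Pr(>|t|)"]
  b <- s3["Me", "Estimate"]; s_b <- s3["Me", "Std. Error"]
  p_b <- s3["Me", "Pr(>|t|)"]
  c_prime <- s3["X", "Estimate"]

  denom <- sqrt(b^2 * s_a^2 + a^2 * s_b^2)
  sobel_z <- if (denom > 0) a * b / denom else 0
  p_sobel <- 2 * stats::pnorm(-abs(sobel_z))

  reason <- NULL
  if (cc == 0) {
    t_eff <- NA_real_
    significant <- FALSE
    reason <- "total effect c is zero; T_eff undefined"
  } else {
    t_eff <- 100 * (1 - c_prime / cc)
    significant <- all(c(p_a, p_b, p_c) < alpha) && p_sobel < alpha &&
      t_eff > 50
  }
  structure(list(
    c = cc, p_c = p_c,
    a = a, s_a = s_a, p_a = p_a,
    b = b, s_b = s_b, p_b = p_b,
    c_prime = c_prime,
    intercepts = c(g1 = unname(stats::coef(f1)[1]),
                   g2 = unname(stats::coef(f2)[1]),
                   g3 = unname(stats::coef(f3)[1])),
    resid_var = c(e1 = summary(f1)$sigma^2, e2 = summary(f2)$sigma^2,
                  e3 = summary(f3)$sigma^2),
    sobel_z = sobel_z, p_sobel = p_sobel, t_eff = t_eff,
    significant = significant, reason = reason),
    class = "mediation_result")
}

#' Directionality check for a mediation
#'
#' Reruns [mediate()] with X and Me swapped; the mediation is directed when
#' the original assignment is significant and the swapped one is not.
#'
#' @inheritParams mediate
#' @return List with `original`, `swapped` (both `mediation_result`) and
#'   logical `directed`.
#' @export
mediation_direction_check <- function(X, Me, Y, alpha = 0.05) {
  orig <- mediate(X, Me, Y, alpha)
  swap <- mediate(Me, X, Y, alpha)
  list(original = orig, swapped = swap,
       directed = orig$significant && !swap$significant)
}

#' Moderation analysis (interaction model with partial F-test)
#'
#' Fits the full model `Y = b0 + b1*X + b2*Mo + b3*(X*Mo)` and the
#' restricted model without the interaction; the interaction coefficient is
#' tested with a partial F-test and the full model with an overall F-test.
#' Moderation is significant when both p-values are at or below 0.05.
#'
#' @param X,Mo,Y Numeric vectors of equal length (independent variable,
#'   moderator, outcome), length at least 10.
#' @param alpha Significance level.
#' @return A `moderation_result` list: `beta` (b0..b3) with p-values,
#'   restricted-model coefficients, `f_partial`, `p_b3`, `f_overall`,
#'   `p_overall`, `significant`.
#' @export
moderate <- function(X, Mo, Y, alpha = 0.05) {
  n <- length(Y)
  stopifnot(length(X) == n, length(Mo) == n)
  if (n < 10L) stop("moderation requires at least 10 observations")
  full <- stats::lm(Y ~ X * Mo)
  if (anyNA(stats::coef(full)))
    stop("degenerate moderation model: X*Mo is collinear with X or Mo")
  restricted <- stats::lm(Y ~ X + Mo)
  an <- stats::anova(restricted, full)
  f_partial <- an$F[2]
  p_b3 <- an$`Pr(>F)`[2]
  fs <- summary(full)$fstatistic
  p_overall <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  sf <- summary(full)$coefficients
  structure(list(
    beta = stats::coef(full),
    p_beta = sf[, "Pr(>|t|)"],
    restricted_beta = stats::coef(restricted),
    f_partial = f_partial, p_b3 = p_b3,
    f_overall = unname(fs[1]), p_overall = unname(p_overall),
    significant = p_b3 <= alpha && p_overall <= alpha),
    class = "moderation_result")
}

#' Screen all contextual x judgment pairs for mediation and moderation
#'
#' For every pair of a headline contextual variable (mediator/moderator)
#' and a judgment variable (independent variable), with the STAI-S score
#' as the outcome, runs the mediation (both directions) and moderation
#' analyses. Ordinal contextual variables enter as numeric codes. No
#' multiple-testing correction is applied by default, mirroring the
#' raw-significance reporting convention; a Bonferroni option is provided.
#'
#' @param cohort Cohort analysis table containing the judgment variables,
#'   the contextual columns and `stai_s`.
#' @param contextuals Character vector of contextual column names (default
#'   age, loneliness, income, employment).
#' @param judgment_vars Judgment-variable column names.
#' @param bonferroni Apply Bonferroni correction across the screen.
#' @return List with data frames `mediation` (one row per pair: verdicts,
#'   Sobel statistics, T_eff, directionality) and `moderation` (p_b3,
#'   p_overall, verdict).
#' @export
screen_all_pairs <- function(cohort,
                             contextuals = c("age", "loneliness", "income",
                                             "employment"),
                             judgment_vars = judgment_variable_names(),
                             bonferroni = FALSE) {
  Y <- cohort$stai_s
  as_num <- function(v) if (is.factor(v)) as.numeric(v) else as.numeric(v)
  n_tests <- length(contextuals) * length(judgment_vars)
  alpha <- if (bonferroni) 0.05 / n_tests else 0.05

  med_rows <- list(); mod_rows <- list(); k <- 0L
  for (ctx in contextuals) {
    Mvar <- as_num(cohort[[ctx]])
    for (jv in judgment_vars) {
      X <- as.numeric(cohort[[jv]])
      k <- k + 1L
      med <- mediation_direction_check(X, Mvar, Y, alpha)
      med_rows[[k]] <- data.frame(
        contextual = ctx, judgment = jv,
        a = med$original$a, b = med$original$b, c = med$original$c,
        c_prime = med$original$c_prime,
        sobel_z = med$original$sobel_z, p_sobel = med$original$p_sobel,
        t_eff = med$original$t_eff,
        significant = med$original$significant,
        swapped_significant = med$swapped$significant,
        directed = med$directed)
      mod <- moderate(X, Mvar, Y, alpha)
      mod_rows[[k]] <- data.frame(
        contextual = ctx, judgment = jv,
        beta3 = unname(mod$beta["X:Mo"]),
        p_b3 = mod$p_b3, p_overall = mod$p_overall,
        significant = mod$significant)
    }
  }
  list(mediation = do.call(rbind, med_rows),
       moderation = do.call(rbind, mod_rows))
}
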