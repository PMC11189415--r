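#' Configuration for RPT feature extraction
#'
#' Collects the tunable numerical conventions used when deriving judgment
#' variables from picture ratings.
#'
#' @param entropy_base Base of the logarithm used for Shannon entropy.
#'   Default 2 (entropy in bits), giving `H` in `[0, log2(3)]` for the
#'   three-outcome magnitude distribution.
#' @param variance Either `"population"` (divide by n, the default; the sets
#'   are small and fixed-size) or `"sample"` (divide by n - 1).
#' @param family_tiebreak Curve family retained when the logarithmic and
#'   power-law limb fits have equal adjusted R-squared; default `"log"`.
#' @param outlier_mad_mult Multiplier m in the extreme-outlier rule
#'   `|x - median| > m * MAD` applied to each of the 15 judgment variables.
#' @param swap_value_axes If `TRUE`, value limbs are fit as H = f(K) instead
#'   of the default K = f(H).
#' @param joint_limit_fit If `TRUE` (default) a single concave quadratic is
#'   fit across both signed (K, sigma) limbs; if `FALSE`, one per limb
#'   (features are then taken from the corresponding limb's fit).
#' @return A list of class `rpt_config`.
#' @export
rpt_config <- function(entropy_base = 2,
                       variance = c("population", "sample"),
                       family_tiebreak = c("log", "power"),
                       outlier_mad_mult = 5,
                       swap_value_axes = FALSE,
                       joint_limit_fit = TRUE) {
  variance <- match.arg(variance)
  family_tiebreak <- match.arg(family_tiebreak)
  stopifnot(entropy_base > 1, outlier_mad_mult > 0)
  structure(list(entropy_base = entropy_base, variance = variance,
                 family_tiebreak = family_tiebreak,
                 outlier_mad_mult = outlier_mad_mult,
                 swap_value_axes = swap_value_axes,
                 joint_limit_fit = joint_limit_fit),
            class = "rpt_config")
}

#' Names of the 15 judgment variables
#' @return Character vector of feature names in canonical order.
#' @export
judgment_variable_names <- function() {
  c("LA", "RA", "LR", "Ante", "Insurance",
    "PeakPR", "PeakNR", "RewardTP", "AversionTP", "TotalRR", "TotalAR",
    "RATradeoff", "TradeoffRange", "RAConsistency", "ConsistencyRange")
}

# Shannon entropy of the magnitude distribution of a signed rating set.
# Magnitudes live on {1,2,3}; 0*log(0) := 0.
rating_entropy <- function(ratings, base = 2) {
  m <- abs(ratings)
  p <- tabulate(m, nbins = 3L) / length(m)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

rating_variance <- function(x, convention = "population") {
  n <- length(x)
  if (convention == "population") mean((x - mean(x))^2)
  else if (n > 1) stats::var(x) else 0
}

#' Summarise one participant's ratings into signed (K, sigma, H) tuples
#'
#' Positive and negative ratings are split per category (zeros belong to
#' neither set). For each category x sign set the mean rating K, the
#' variance sigma and the Shannon entropy H of the rating magnitudes are
#' computed, yielding up to 12 tuples (6 categories x 2 signs), plus
#' cross-category means of each defined quantity.
#'
#' @param ratings Data frame with columns `category` (integer 1..6) and
#'   `rating` (integer in -3..3) for a single participant; 8 rows per
#'   category.
#' @param config An [rpt_config()].
#' @return A list with `summaries` (data frame: category, sign, K, sigma, H,
#'   n, defined) and `means` (named vector of cross-category means
#'   K_pos, sigma_pos, H_pos, K_neg, sigma_neg, H_neg).
#' @export
summarize_ratings <- function(ratings, config = rpt_config()) {
  stopifnot(all(c("category", "rating") %in% names(ratings)))
  if (!all(ratings$rating %in% -3:3))
    stop("ratings must be integers in [-3, 3]")
  cats <- sort(unique(ratings$category))
  rows <- vector("list", 2L * length(cats))
  k <- 0L
  for (cc in cats) {
    r <- ratings$rating[ratings$category == cc]
    for (sg in c("+", "-")) {
      x <- if (sg == "+") r[r > 0] else r[r < 0]
      k <- k + 1L
      if (length(x) == 0L) {
        rows[[k]] <- data.frame(category = cc, sign = sg, K = NA_real_,
                                sigma = NA_real_, H = NA_real_, n = 0L,
                                defined = FALSE)
      } else {
        rows[[k]] <- data.frame(
          category = cc, sign = sg,
          K = mean(x),
          sigma = rating_variance(x, config$variance),
          H = rating_entropy(x, config$entropy_base),
          n = length(x), defined = TRUE)
      }
    }
  }
  summaries <- do.call(rbind, rows)
  mean_of <- function(sg, col) {
    v <- summaries[summaries$sign == sg & summaries$defined, col]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  means <- c(K_pos = mean_of("+", "K"), sigma_pos = mean_of("+", "sigma"),
             H_pos = mean_of("+", "H"),
             K_neg = mean_of("-", "K"), sigma_neg = mean_of("-", "sigma"),
             H_neg = mean_of("-", "H"))
  list(summaries = summaries, means = means)
}

# Goodness-of-fit summary on the original scale for fitted values yhat.
fit_stats <- function(y, yhat, n_par) {
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - yhat)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  df_res <- n - n_par - 1L
  adj <- if (!is.na(r2) && df_res > 0) 1 - (1 - r2) * (n - 1) / df_res
         else NA_real_
  fstat <- if (!is.na(r2) && df_res > 0 && ss_res > 0)
    ((ss_tot - ss_res) / n_par) / (ss_res / df_res) else Inf
  list(r2 = r2, adj_r2 = adj, fstat = fstat, n_points = n)
}

#' Fit a value-function limb (logarithmic vs power-law)
#'
#' Fits `K = a*ln(H) + b` and `K = b*H^a` to one limb's (H, K) points by
#' least squares (the power law in log-log space, on `|K|` for the negative
#' limb) and retains the family with the higher adjusted R-squared computed
#' on the original scale. Points with `H = 0` are excluded (undefined
#' logarithm) and recorded in the diagnostics.
#'
#' @param H,K Numeric vectors of entropy and mean-rating coordinates for one
#'   limb (positive limb: K > 0; negative limb: K < 0).
#' @param config An [rpt_config()].
#' @return A `value_fit` list: `family`, `a`, `b`, `r2`, `adj_r2`, `fstat`,
#'   `n_points`, `n_dropped` (H = 0 points), `slope_sign` (+1/-1), and
#'   closures `f`, `f1`, `f2` (curve, first and second derivative), or
#'   `NULL` when fewer than 3 usable points remain.
#' @export
fit_value_function <- function(H, K, config = rpt_config()) {
  keep <- is.finite(H) & is.finite(K) & H > 0 & K != 0
  n_dropped <- sum(is.finite(H) & is.finite(K)) - sum(keep)
  H <- H[keep]; K <- K[keep]
  if (length(H) < 3L) return(NULL)
  sgn <- if (mean(K) >= 0) 1 else -1

  # logarithmic family
  lg <- stats::lm.fit(cbind(1, log(H)), K)
  b_log <- lg$coefficients[[1]]; a_log <- lg$coefficients[[2]]
  st_log <- fit_stats(K, cbind(1, log(H)) %*% lg$coefficients, 1L)

  # power family on |K|; degenerate if any |K| underflows
  pw <- stats::lm.fit(cbind(1, log(H)), log(abs(K)))
  b_pow <- sgn * exp(pw$coefficients[[1]]); a_pow <- pw$coefficients[[2]]
  yhat_pow <- b_pow * H^a_pow
  st_pow <- fit_stats(K, yhat_pow, 1L)

  pick_log <- if (is.na(st_pow$adj_r2)) TRUE
    else if (is.na(st_log$adj_r2)) FALSE
    else if (st_log$adj_r2 == st_pow$adj_r2) config$family_tiebreak == "log"
    else st_log$adj_r2 > st_pow$adj_r2

  if (pick_log) {
    a <- a_log; b <- b_log; st <- st_log
    f <- function(h) a * log(h) + b
    f1 <- function(h) a / h
    f2 <- function(h) -a / h^2
    fam <- "log"
  } else {
    a <- a_pow; b <- b_pow; st <- st_pow
    f <- function(h) b * h^a
    f1 <- function(h) b * a * h^(a - 1)
    f2 <- function(h) b * a * (a - 1) * h^(a - 2)
    fam <- "power"
  }
  structure(list(family = fam, a = a, b = b, r2 = st$r2, adj_r2 = st$adj_r2,
                 fstat = st$fstat, n_points = st$n_points,
                 n_dropped = n_dropped, slope_sign = sgn,
                 f = f, f1 = f1, f2 = f2),
            class = "value_fit")
}

# Limb steepness: first derivative of the fitted curve at H = 1
# (log family: a; power family: a*b).
limb_slope <- function(fit) fit$f1(1)

#' Extract value-function judgment variables from two limb fits
#'
#' @param pos_fit,neg_fit `value_fit` objects for the positive and negative
#'   limbs (from [fit_value_function()]).
#' @param h_mean_pos,h_mean_neg Participant's cross-category mean entropies
#'   at which the limb curvatures are evaluated.
#' @return Named numeric vector: `LA` (loss aversion, ratio of negative to
#'   positive limb steepness), `RA` (risk aversion, positive-limb curvature
#'   magnitude at the mean positive entropy), `LR` (loss resilience,
#'   negative-limb curvature magnitude at the mean negative entropy),
#'   `Ante` (positive limb value at unit entropy) and `Insurance`
#'   (magnitude of the negative limb at unit entropy). `NA`s returned when a
#'   limb fit is missing or the positive slope is non-positive.
#' @export
extract_value_features <- function(pos_fit, neg_fit, h_mean_pos, h_mean_neg) {
  out <- c(LA = NA_real_, RA = NA_real_, LR = NA_real_,
           Ante = NA_real_, Insurance = NA_real_)
  if (is.null(pos_fit) || is.null(neg_fit)) return(out)
  a_pos <- limb_slope(pos_fit)
  a_neg <- limb_slope(neg_fit)
  if (is.finite(a_pos) && a_pos > 0 && is.finite(a_neg))
    out["LA"] <- abs(a_neg) / a_pos
  if (is.finite(h_mean_pos) && h_mean_pos > 0)
    out["RA"] <- abs(pos_fit$f2(h_mean_pos))
  if (is.finite(h_mean_neg) && h_mean_neg > 0)
    out["LR"] <- abs(neg_fit$f2(h_mean_neg))
  out["Ante"] <- pos_fit$f(1)
  out["Insurance"] <- abs(neg_fit$f(1))
  out
}

#' Fit the limit function (concave quadratic of variance on mean rating)
#'
#' A single quadratic `sigma = alpha*K^2 + beta*K + gamma` is fit by
#' ordinary least squares across the signed (K, sigma) points of both limbs.
#'
#' @param K,sigma Numeric vectors of mean ratings (signed) and variances.
#' @return A `limit_fit` list with `alpha`, `beta`, `gamma`, fit statistics,
#'   `concave` flag and (when real and of opposite signs) the roots
#'   `root_neg < 0 < root_pos`; `NULL` if fewer than 4 points or the points
#'   do not span both signs of K.
#' @export
fit_limit_function <- function(K, sigma) {
  keep <- is.finite(K) & is.finite(sigma)
  K <- K[keep]; sigma <- sigma[keep]
  if (length(K) < 4L || !any(K > 0) || !any(K < 0)) return(NULL)
  X <- cbind(1, K, K^2)
  fit <- stats::lm.fit(X, sigma)
  cf <- fit$coefficients
  gamma <- cf[[1]]; beta <- cf[[2]]; alpha <- cf[[3]]
  st <- fit_stats(sigma, X %*% cf, 2L)
  disc <- beta^2 - 4 * alpha * gamma
  roots <- if (is.finite(alpha) && alpha < 0 && disc >= 0) {
    r <- sort(c((-beta - sqrt(disc)) / (2 * alpha),
                (-beta + sqrt(disc)) / (2 * alpha)))
    if (r[1] < 0 && r[2] > 0) r else NULL
  } else NULL
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 r2 = st$r2, adj_r2 = st$adj_r2, fstat = st$fstat,
                 n_points = st$n_points,
                 concave = is.finite(alpha) && alpha < 0,
                 root_neg = if (is.null(roots)) NA_real_ else roots[1],
                 root_pos = if (is.null(roots)) NA_real_ else roots[2]),
            class = "limit_fit")
}

#' Extract limit-function judgment variables
#'
#' The quadratic's roots are the tipping points: the reward value beyond
#' which approach choices are made and the aversion intensity beyond which
#' avoidance choices are made. Peak risks are the maxima of the fitted
#' curve over the approach half-interval `(0, root_pos]` and the avoidance
#' half-interval `[root_neg, 0)`; when the vertex falls outside a
#' half-interval the supremum is attained at the open endpoint, evaluated
#' at K = 0. Total risks are the areas under the curve between zero and
#' each root (closed-form antiderivative).
#'
#' @param fit A `limit_fit` from [fit_limit_function()].
#' @return Named numeric vector `PeakPR`, `PeakNR`, `RewardTP`,
#'   `AversionTP`, `TotalRR`, `TotalAR` (all `NA` when the fit is missing,
#'   convex, or lacks real roots of opposite signs).
#' @export
extract_limit_features <- function(fit) {
  out <- c(PeakPR = NA_real_, PeakNR = NA_real_, RewardTP = NA_real_,
           AversionTP = NA_real_, TotalRR = NA_real_, TotalAR = NA_real_)
  if (is.null(fit) || !isTRUE(fit$concave) ||
      !is.finite(fit$root_neg) || !is.finite(fit$root_pos)) return(out)
  a <- fit$alpha; b <- fit$beta; g <- fit$gamma
  curve <- function(k) a * k^2 + b * k + g
  vertex <- -b / (2 * a)
  out["RewardTP"] <- fit$root_pos
  out["AversionTP"] <- abs(fit$root_neg)
  out["PeakPR"] <- if (vertex > 0) curve(vertex) else g
  out["PeakNR"] <- if (vertex < 0) curve(vertex) else g
  anti <- function(k) a * k^3 / 3 + b * k^2 / 2 + g * k
  out["TotalRR"] <- anti(fit$root_pos) - anti(0)
  out["TotalAR"] <- abs(anti(0) - anti(fit$root_neg))
  out
}

#' Fit the tradeoff function (polar summary of per-category entropy pairs)
#'
#' Each category's `(H_pos, H_neg)` point is mapped to polar coordinates:
#' radius `r = sqrt(H_pos^2 + H_neg^2)` and angle
#' `theta = atan2(H_neg, H_pos)` in `[0, pi/2]` for non-negative entropies.
#' The radial fit is summarised by the mean and spread of r.
#'
#' @param H_pos,H_neg Numeric vectors of per-category positive and negative
#'   entropies.
#' @return A `tradeoff_fit` list with the polar `points` data frame and
#'   radial summary (`r_mean`, `r_sd`), or `NULL` if fewer than 2 categories
#'   have both entropies defined.
#' @export
fit_tradeoff_function <- function(H_pos, H_neg) {
  keep <- is.finite(H_pos) & is.finite(H_neg)
  H_pos <- H_pos[keep]; H_neg <- H_neg[keep]
  if (length(H_pos) < 2L) return(NULL)
  r <- sqrt(H_pos^2 + H_neg^2)
  theta <- atan2(H_neg, H_pos)
  structure(list(points = data.frame(H_pos = H_pos, H_neg = H_neg,
                                     r = r, theta = theta),
                 r_mean = mean(r),
                 r_sd = stats::sd(r)),
            class = "tradeoff_fit")
}

#' Extract tradeoff judgment variables
#'
#' @param fit A `tradeoff_fit` from [fit_tradeoff_function()].
#' @return Named numeric vector: `RATradeoff` (mean angle; average bias of
#'   information toward approach or avoidance), `TradeoffRange` (angular
#'   range), `RAConsistency` (mean radius; conflict-vs-indifference
#'   continuum) and `ConsistencyRange` (radial range).
#' @export
extract_tradeoff_features <- function(fit) {
  out <- c(RATradeoff = NA_real_, TradeoffRange = NA_real_,
           RAConsistency = NA_real_, ConsistencyRange = NA_real_)
  if (is.null(fit)) return(out)
  th <- fit$points$theta; r <- fit$points$r
  out["RATradeoff"] <- mean(th)
  out["TradeoffRange"] <- max(th) - min(th)
  out["RAConsistency"] <- mean(r)
  out["ConsistencyRange"] <- max(r) - min(r)
  out
}

#' Compute the full judgment profile for one participant
#'
#' Runs the complete RPT chain: signed summaries, value-limb fits, limit
#' fit and tradeoff fit, and assembles the 15 judgment variables with
#' per-curve goodness-of-fit diagnostics. Fit failures never raise; they
#' leave the affected features `NA` and mark the profile incomplete.
#'
#' @param ratings One participant's ratings (columns `category`, `rating`).
#' @param config An [rpt_config()].
#' @return One-row data frame: the 15 judgment variables, `complete` flag,
#'   and fit diagnostics (`r2`/`adj_r2` per curve).
#' @export
judgment_profile <- function(ratings, config = rpt_config()) {
  sm <- summarize_ratings(ratings, config)
  s <- sm$summaries
  pos <- s[s$sign == "+" & s$defined, ]
  neg <- s[s$sign == "-" & s$defined, ]

  fit_limb <- function(H, K) {
    if (config$swap_value_axes) fit_value_function(K, H, config)
    else fit_value_function(H, K, config)
  }
  pos_fit <- fit_limb(pos$H, pos$K)
  neg_fit <- fit_limb(neg$H, neg$K)
  vf <- extract_value_features(pos_fit, neg_fit,
                               sm$means[["H_pos"]], sm$means[["H_neg"]])

  lim_fit <- fit_limit_function(c(pos$K, neg$K), c(pos$sigma, neg$sigma))
  lf <- extract_limit_features(lim_fit)

  # tradeoff needs matched categories where both signs are defined
  both <- intersect(pos$category, neg$category)
  tr_fit <- fit_tradeoff_function(pos$H[match(both, pos$category)],
                                  neg$H[match(both, neg$category)])
  tf <- extract_tradeoff_features(tr_fit)

  feats <- c(vf, lf, tf)[judgment_variable_names()]
  diag1 <- function(fit, prefix) {
    v <- c(NA_real_, NA_real_)
    if (!is.null(fit)) v <- c(fit$r2, fit$adj_r2)
    stats::setNames(v, paste0(prefix, c("_r2", "_adj_r2")))
  }
  out <- data.frame(t(feats))
  out$complete <- !anyNA(feats)
  out <- cbind(out, t(c(diag1(pos_fit, "value_pos"),
                        diag1(neg_fit, "value_neg"),
                        diag1(lim_fit, "limit"))))
  out$value_pos_family <- if (is.null(pos_fit)) NA_character_ else pos_fit$family
  out$value_neg_family <- if (is.null(neg_fit)) NA_character_ else neg_fit$family
  out
}

#' Compute judgment profiles for a full rating table
#'
#' @param ratings Long-format rating table with columns `participant`,
#'   `category`, `rating`.
#' @param config An [rpt_config()].
#' @return Data frame with one row per participant (column `participant`
#'   first), the 15 judgment variables, completeness flag and diagnostics.
#' @export
compute_profiles <- function(ratings, config = rpt_config()) {
  stopifnot(all(c("participant", "category", "rating") %in% names(ratings)))
  parts <- split(ratings, ratings$participant)
  rows <- lapply(parts, judgment_profile, config = config)
  out <- do.call(rbind, rows)
  out <- cbind(participant = names(parts), out)
  rownames(out) <- NULL
  out
}

#' Apply rating-based participant exclusions
#'
#' Excludes participants whose 48 ratings show minimal variance (all
#' identical or varying by a single point), whose judgment profile is
#' incomplete (any of the 15 features undefined), or who are extreme
#' outliers on any feature (`|x - median| > m * MAD`, MAD with the standard
#' 1.4826 consistency constant; m from the config, default 5).
#'
#' @param ratings Long-format rating table (`participant`, `rating`, ...).
#' @param profiles Output of [compute_profiles()] for the same participants.
#' @param config An [rpt_config()].
#' @return A `filter_report` (see [filter_report()]) with per-participant
#'   triggered rules among `minimal_variance`, `incomplete_profile`,
#'   `extreme_outlier`.
#' @export
apply_rating_exclusions <- function(ratings, profiles, config = rpt_config()) {
  ids <- profiles$participant
  flags <- stats::setNames(vector("list", length(ids)), ids)

  rng <- tapply(ratings$rating, ratings$participant,
                function(r) diff(range(r)))
  for (id in ids) {
    f <- character(0)
    if (!is.na(rng[id]) && rng[id] <= 1) f <- c(f, "minimal_variance")
    if (!isTRUE(profiles$complete[profiles$participant == id]))
      f <- c(f, "incomplete_profile")
    flags[[id]] <- f
  }

  # outlier screen only among complete profiles
  jv <- judgment_variable_names()
  comp <- profiles[profiles$complete, , drop = FALSE]
  if (nrow(comp) > 2L) {
    for (v in jv) {
      x <- comp[[v]]
      med <- stats::median(x)
      mad <- stats::mad(x)
      if (is.finite(mad) && mad > 0) {
        hit <- comp$participant[abs(x - med) > config$outlier_mad_mult * mad]
        for (id in hit) flags[[id]] <- union(flags[[id]], "extreme_outlier")
      }
    }
  }
  filter_report(flags)
}
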