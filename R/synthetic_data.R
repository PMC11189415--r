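#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a generated cohort: a standard
#' normal latent anxiety trait drives the STAI-S item responses, shifts
#' the contextual-variable distributions along declared monotone
#' directions, and shifts the per-category rating distributions so that
#' high-trait participants show a steeper negative value limb (higher loss
#' aversion), a flatter negative-limb curvature (lower loss resilience)
#' and a narrower angular spread of the per-category entropy pairs (lower
#' tradeoff range).
#'
#' @param n_participants Cohort size (at least 2).
#' @param seed Integer seed; the same spec always generates a bit-identical
#'   cohort.
#' @param anxiety_effect Non-negative strength of the latent trait's
#'   influence on items, context and ratings; 0 decouples everything from
#'   the trait.
#' @param contextual_gradients Named character vector of monotone
#'   directions (`"+"`, `"-"`, `"none"`) of each contextual variable's
#'   association with the trait. Defaults follow the observed trends:
#'   loneliness, female sex and COVID-19 history increase with anxiety;
#'   age, income and education decrease.
#' @param rating_shift_profile Named numeric vector of shift strengths for
#'   the three planted judgment-construct directions: `la` (positive-limb
#'   window widening, flattening the positive slope, plus a
#'   negative-entropy compression that steepens the negative limb, so loss
#'   aversion rises), `lr` (negative-limb variance-floor raise, compressing
#'   the negative entropy range) and `tradeoff` (attenuation of the
#'   decisive-aversion categories with the trait; their zero-entropy
#'   negative points give low-anxiety participants higher loss resilience
#'   and a wider tradeoff range).
#' @param missing_rate Fraction of contextual cells set to missing.
#' @param loneliness_levels Number of loneliness response levels.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        seed = 1L,
                        anxiety_effect = 1.5,
                        contextual_gradients = c(
                          loneliness = "+", age = "-", sex = "+",
                          income = "-", marital = "none",
                          employment = "none", edu = "-",
                          race_ethnicity = "none", covid_test = "+",
                          covid_diagnosis = "+"),
                        rating_shift_profile = c(la = 0.15, lr = 0.40,
                                                 tradeoff = 2.6),
                        missing_rate = 0,
                        loneliness_levels = 5L) {
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (anxiety_effect < 0) stop("anxiety_effect must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!all(contextual_gradients %in% c("+", "-", "none")))
    stop("contextual gradient directions must be '+', '-' or 'none'")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 anxiety_effect = anxiety_effect,
                 contextual_gradients = contextual_gradients,
                 rating_shift_profile = rating_shift_profile,
                 missing_rate = missing_rate,
                 loneliness_levels = as.integer(loneliness_levels)),
            class = "cohort_spec")
}

# direction label -> sign multiplier
grad_sign <- function(gradients, var) {
  switch(gradients[[var]], "+" = 1, "-" = -1, "none" = 0)
}

# Cumulative-logit ordinal sampler: baseline category probabilities define
# the thresholds; eta shifts the latent scale upward.
ordinal_sample <- function(n, eta, base_probs) {
  k <- length(base_probs)
  thresholds <- stats::qlogis(cumsum(base_probs)[-k])
  u <- eta + stats::rlogis(n)
  1L + rowSums(outer(u, thresholds, ">"))
}

# Distribution on magnitudes {1,2,3} with exact mean K and variance s:
# p3 = ((K-1)(K-2)+s)/2, p2 = (K-1)(3-K)-s, p1 = 1-p2-p3 (clipped to the
# feasible simplex).
magnitude_probs <- function(K, s) {
  p3 <- ((K - 1) * (K - 2) + s) / 2
  p2 <- (K - 1) * (3 - K) - s
  p <- pmax(c(1 - p2 - p3, p2, p3), 0)
  p / sum(p)
}

# Largest variance attainable on {1,2,3} at mean K.
magnitude_var_max <- function(K) (K - 1) * (3 - K)

# Quasi-exact composition draw: rounded expected counts with
# largest-remainder allocation, then (with probability jitter_p) one unit
# moved between random cells. Keeps the realized (K, sigma, H) of small
# sets close to their targets.
draw_magnitudes <- function(n, p, jitter_p = 0.35) {
  exp_n <- n * p
  cnt <- floor(exp_n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(exp_n - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  if (stats::runif(1) < jitter_p) {
    from <- which(cnt > 0)
    from <- from[sample(length(from), 1L)]
    to <- sample(3L, 1L)
    cnt[from] <- cnt[from] - 1L
    cnt[to] <- cnt[to] + 1L
  }
  sample(rep(1:3, cnt))
}

#' Generate a synthetic cohort
#'
#' Draws a latent trait `z ~ N(0, 1)` per participant and generates (1)
#' 20 STAI-S item responses from an item-wise cumulative-logit model whose
#' expected scored sum increases monotonically in `z` (reverse-keyed items
#' are emitted on the raw, unreversed scale), (2) eleven contextual
#' variables shifted along the spec's gradient directions, (3) completion
#' time and diagnosis count that pass the vendor filters, and (4) a
#' 48-item picture rating table (6 categories x 8 pictures, each category
#' mixing positive and negative ratings) whose induced judgment variables
#' move with `z` in the planted directions.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `ratings`
#'   (long-format data frame), `survey` (STAI items, contextual variables,
#'   `completion_seconds`, `diagnosis_count`), `latent_trait`,
#'   `ground_truth` (invalid-responder tags, all `FALSE` here) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_participants
  id <- sprintf("P%05d", seq_len(n))
  z <- stats::rnorm(n)
  ze <- spec$anxiety_effect * z
  g <- spec$contextual_gradients
  shift <- spec$rating_shift_profile

  # --- STAI-S items: cumulative logit, thresholds shared across items ----
  item_thresholds <- c(-0.2, 1.1, 2.44)
  stai <- matrix(NA_integer_, n, 20L,
                 dimnames = list(NULL, paste0("stai_", 1:20)))
  rev_items <- stai_reverse_items()
  for (j in 1:20) {
    u <- ze + stats::rlogis(n)
    scored <- 1L + rowSums(outer(u, item_thresholds, ">"))
    stai[, j] <- if (j %in% rev_items) 5L - scored else scored
  }

  # --- contextual variables ---------------------------------------------
  lev <- contextual_levels(spec$loneliness_levels)
  lone_probs <- stats::dnorm(seq_len(spec$loneliness_levels),
                             mean = 1.8, sd = 1.4)
  lone_probs <- lone_probs / sum(lone_probs)
  loneliness <- ordinal_sample(n, 0.7 * grad_sign(g, "loneliness") * ze,
                               lone_probs)
  age <- pmin(70, pmax(18, round(
    51.4 + 4 * grad_sign(g, "age") * ze + stats::rnorm(n, 0, 13))))
  sex <- lev$sex[1L + stats::rbinom(
    n, 1L, stats::plogis(stats::qlogis(0.615) +
                           0.25 * grad_sign(g, "sex") * ze))]
  income <- ordinal_sample(n, 0.5 * grad_sign(g, "income") * ze,
                           c(0.10, 0.14, 0.16, 0.16, 0.15, 0.12, 0.10, 0.07))
  marital <- sample(lev$marital, n, replace = TRUE,
                    prob = c(0.20, 0.514, 0.06, 0.02, 0.12, 0.086))
  employment <- sample(lev$employment, n, replace = TRUE,
                       prob = c(0.22, 0.09, 0.05, 0.13, 0.358, 0.152))
  edu <- ordinal_sample(n, 0.3 * grad_sign(g, "edu") * ze,
                        c(0.05, 0.25, 0.296, 0.25, 0.12, 0.034))
  edu_tab <- edu_consistency_table()
  edu_years <- vapply(edu, function(e) {
    sample(seq(edu_tab$min_years[e], edu_tab$max_years[e]), 1L)
  }, numeric(1))
  race <- sample(lev$race_ethnicity, n, replace = TRUE,
                 prob = c(0.77, 0.08, 0.06, 0.04, 0.03, 0.02))
  covid_test <- lev$covid_test[1L + stats::rbinom(
    n, 1L, stats::plogis(stats::qlogis(0.30) +
                           0.25 * grad_sign(g, "covid_test") * ze))]
  covid_diag <- lev$covid_diagnosis[1L + stats::rbinom(
    n, 1L, stats::plogis(stats::qlogis(0.20) +
                           0.25 * grad_sign(g, "covid_diagnosis") * ze))]

  completion_seconds <- 900 + stats::rlnorm(n, log(900), 0.5)
  diagnosis_count <- stats::rbinom(n, 9L, 0.15)

  survey <- data.frame(participant = id, stai, loneliness = loneliness,
                       age = age, sex = sex, income = income,
                       marital = marital, employment = employment,
                       edu = edu, edu_years = edu_years,
                       race_ethnicity = race, covid_test = covid_test,
                       covid_diagnosis = covid_diag,
                       completion_seconds = completion_seconds,
                       diagnosis_count = diagnosis_count,
                       stringsAsFactors = FALSE)

  if (spec$missing_rate > 0) {
    ctx_cols <- c("loneliness", "age", "sex", "income", "marital",
                  "employment", "edu", "edu_years", "race_ethnicity",
                  "covid_test", "covid_diagnosis")
    for (v in ctx_cols) {
      miss <- stats::runif(n) < spec$missing_rate
      survey[[v]][miss] <- NA
    }
  }

  # --- picture ratings ---------------------------------------------------
  # Each category sits on a participant-jittered intensity gradient
  # g in [0, 1] that positions its positive and negative rating
  # distributions along a (K, sigma) path chosen so mean rating and
  # entropy rise together within each sign (positive value-limb slope)
  # while variance falls with |K| across the signed axis (concave limit
  # curve). The trait shifts three things: (1) the positive window widens
  # with z, flattening the positive limb; (2) the negative variance floor
  # rises with z, compressing the negative entropy range and steepening
  # the negative limb — together these raise loss aversion; (3) two
  # "decisive aversion" categories (all pictures of the aversive
  # categories rated -3) occur mostly at low z; their zero-entropy
  # negative points lower the low-anxiety stratum's mean negative entropy
  # (raising its loss resilience) and anchor a zero tradeoff angle
  # (widening its tradeoff range).
  p_pos <- c(0.65, 0.35, 0.75, 0.30, 0.60, 0.50)
  cat_grad <- (0:5) / 5
  aversive_cats <- c(2L, 4L)
  grad_jitter <- 0.08
  zero_rate <- 0.02

  ratings <- vector("list", n)
  for (i in seq_len(n)) {
    pos_widen <- exp(shift[["la"]] * ze[i])
    floor_raise <- shift[["lr"]] * (1 - exp(-0.8 * max(ze[i], 0)))
    decisive <- stats::runif(length(aversive_cats)) <
      stats::plogis(1 - shift[["tradeoff"]] * ze[i])

    rr <- matrix(NA_integer_, 6L, 8L)
    for (cc in 1:6) {
      gp <- min(max(cat_grad[cc] + stats::rnorm(1, 0, grad_jitter), 0), 1)
      gn <- min(max(cat_grad[cc] + stats::rnorm(1, 0, grad_jitter), 0), 1)
      Kp <- min(2.45, max(1.25, 1.825 + (gp - 0.5) * 0.65 * pos_widen))
      sp <- (0.93 - 0.51 * gp) * magnitude_var_max(Kp)
      sp <- max(min(sp, 0.95 * magnitude_var_max(Kp)),
                (Kp - 1) * (2 - Kp) + 0.01, 0.03)
      Kn <- 1.5 + 0.65 * gn
      fn <- 0.93 - 0.51 * gn + floor_raise
      sn <- max(min(fn * magnitude_var_max(Kn),
                    0.95 * magnitude_var_max(Kn)),
                (Kn - 1) * (2 - Kn) + 0.01, 0.03)
      n_pos <- 3L + stats::rbinom(1L, 2L, p_pos[cc])
      n_neg <- 8L - n_pos
      dc <- match(cc, aversive_cats)
      neg <- if (!is.na(dc) && decisive[dc]) rep(3L, n_neg)
             else draw_magnitudes(n_neg, magnitude_probs(Kn, sn))
      r <- c(draw_magnitudes(n_pos, magnitude_probs(Kp, sp)), -neg)
      r[stats::runif(8L) < zero_rate] <- 0L
      rr[cc, ] <- r
    }
    ratings[[i]] <- data.frame(participant = id[i],
                               category = rep(1:6, each = 8L),
                               picture = rep(1:8, times = 6L),
                               rating = as.integer(t(rr)))
  }

  structure(list(
    ratings = do.call(rbind, ratings),
    survey = survey,
    latent_trait = data.frame(participant = id, z = z),
    ground_truth = data.frame(participant = id, invalid = FALSE,
                              invalid_type = NA_character_,
                              stringsAsFactors = FALSE),
    spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$survey), "participants,",
      nrow(x$ratings), "ratings; anxiety_effect =",
      x$spec$anxiety_effect, "\n")
  invisible(x)
}

#' Rewrite a fraction of participants as invalid responders
#'
#' Tags `round(fraction * n)` participants (chosen reproducibly from the
#' cohort's seed) and rewrites each to violate one of the exclusion rules,
#' cycling through: straight-lined STAI section, completion under 800 s,
#' ten or more diagnoses, education level/years mismatch, and minimal
#' rating variance (all 48 pictures rated identically). The ground-truth
#' table records each participant's violation.
#'
#' @param cohort A `synthetic_cohort`.
#' @param fraction Fraction of participants to corrupt, in `[0, 1)`.
#' @return The modified cohort.
#' @export
inject_invalid_responders <- function(cohort, fraction) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n <- nrow(cohort$survey)
  n_bad <- round(fraction * n)
  if (n_bad == 0L) return(cohort)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cohort$spec$seed + 1L)

  bad <- sample(n, n_bad)
  types <- rep(c("straight_lining", "fast_completion", "excess_diagnoses",
                 "edu_mismatch", "minimal_variance"),
               length.out = n_bad)
  stai_cols <- paste0("stai_", 1:20)
  for (k in seq_len(n_bad)) {
    i <- bad[k]
    id <- cohort$survey$participant[i]
    switch(types[k],
      straight_lining = {
        cohort$survey[i, stai_cols] <- 3L
      },
      fast_completion = {
        cohort$survey$completion_seconds[i] <- stats::runif(1, 100, 790)
      },
      excess_diagnoses = {
        cohort$survey$diagnosis_count[i] <- sample(10:17, 1L)
      },
      edu_mismatch = {
        cohort$survey$edu[i] <- 1L
        cohort$survey$edu_years[i] <- 20
      },
      minimal_variance = {
        cohort$ratings$rating[cohort$ratings$participant == id] <- 2L
      })
    cohort$ground_truth$invalid[i] <- TRUE
    cohort$ground_truth$invalid_type[i] <- types[k]
  }
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Emits three CSV files (`ratings.csv` long format, `stai_items.csv`
#' wide, `contextual.csv` wide) and a JSON ground-truth sidecar
#' (`ground_truth.json`) carrying the latent trait and invalid-responder
#' tags.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stai_cols <- paste0("stai_", 1:20)
  ctx_cols <- setdiff(names(cohort$survey), stai_cols)
  paths <- c(
    ratings = file.path(dir, "ratings.csv"),
    stai = file.path(dir, "stai_items.csv"),
    contextual = file.path(dir, "contextual.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(cohort$ratings, paths["ratings"], row.names = FALSE)
  utils::write.csv(cohort$survey[c("participant", stai_cols)],
                   paths["stai"], row.names = FALSE)
  utils::write.csv(cohort$survey[ctx_cols], paths["contextual"],
                   row.names = FALSE)
  jsonlite::write_json(
    list(latent_trait = cohort$latent_trait,
         ground_truth = cohort$ground_truth,
         spec = unclass(cohort$spec)),
    paths["ground_truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
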