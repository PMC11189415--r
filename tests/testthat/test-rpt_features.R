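test_that("signed summaries compute mean, population variance and entropy", {
  df <- data.frame(category = 1L, rating = c(1L, 1L, 2L, 3L, -1L, -2L, -3L, 0L))
  sm <- summarize_ratings(df)
  pos <- sm$summaries[sm$summaries$sign == "+", ]
  expect_equal(pos$K, 1.75)
  expect_equal(pos$sigma, 0.6875)
  expect_equal(pos$H, 1.5)
  expect_equal(pos$n, 4L)  # the zero belongs to neither set
  neg <- sm$summaries[sm$summaries$sign == "-", ]
  expect_equal(neg$K, -2)
  expect_equal(neg$H, log2(3))
})

test_that("degenerate and empty rating sets are handled", {
  df <- data.frame(category = 1L, rating = c(2L, 2L, 2L, 2L, -1L, -1L, -1L, -1L))
  sm <- summarize_ratings(df)
  pos <- sm$summaries[sm$summaries$sign == "+", ]
  expect_equal(pos$H, 0)
  expect_equal(pos$sigma, 0)

  df2 <- data.frame(category = 1L, rating = rep(2L, 8))
  sm2 <- summarize_ratings(df2)
  neg2 <- sm2$summaries[sm2$summaries$sign == "-", ]
  expect_false(neg2$defined)
  expect_true(is.na(neg2$K))
})

test_that("entropy and moment bounds hold on random rating sets", {
  set.seed(11)
  for (i in 1:50) {
    r <- sample(c(-3:-1, 1:3), 8, replace = TRUE)
    df <- data.frame(category = 1L, rating = r)
    s <- summarize_ratings(df)$summaries
    s <- s[s$defined, ]
    expect_true(all(s$H >= 0 & s$H <= log2(3) + 1e-12))
    expect_true(all(s$sigma >= 0 & s$sigma <= 4))
    expect_true(all(s$K[s$sign == "+"] > 0 & s$K[s$sign == "+"] <= 3))
    expect_true(all(s$K[s$sign == "-"] < 0 & s$K[s$sign == "-"] >= -3))
  }
})

test_that("features are invariant to picture order within category", {
  r <- complete_ratings()
  p1 <- judgment_profile(r)
  set.seed(3)
  r2 <- r[sample(nrow(r)), ]
  p2 <- judgment_profile(r2)
  expect_equal(p1[judgment_variable_names()], p2[judgment_variable_names()])
})

test_that("exact logarithmic limbs are recovered with R^2 = 1", {
  pos <- log_limb_points(2, 1)
  fit <- fit_value_function(pos$H, pos$K)
  expect_equal(fit$family, "log")
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  neg <- log_limb_points(-3, -0.5)
  nfit <- fit_value_function(neg$H, neg$K)
  expect_equal(nfit$a, -3, tolerance = 1e-9)
  expect_equal(nfit$b, -0.5, tolerance = 1e-9)
})

test_that("exact power-law limbs are recovered", {
  H <- c(0.5, 0.8, 1.1, 1.4, 1.55)
  K <- 1.4 * H^0.7
  fit <- fit_value_function(H, K)
  expect_equal(fit$family, "power")
  expect_equal(fit$a, 0.7, tolerance = 1e-8)
  expect_equal(fit$b, 1.4, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("H = 0 points are excluded and sparse limbs yield no fit", {
  fit <- fit_value_function(c(0, 0.8, 1.2, 1.5), c(1, 1.5, 2, 2.3))
  expect_equal(fit$n_points, 3L)
  expect_equal(fit$n_dropped, 1L)
  expect_null(fit_value_function(c(0, 0.9), c(1, 2)))
})

test_that("log family wins adjusted R-squared on noisy log data", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    H <- c(0.6, 0.8, 1.0, 1.2, 1.4, 1.55)
    K <- 1.8 * log(H) + 1.2 + rnorm(6, 0, 0.05)
    fit <- fit_value_function(H, K)
    if (fit$family == "log") wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("value features follow the limb-curve formulas", {
  pos <- fit_value_function(log_limb_points(2, 1)$H, log_limb_points(2, 1)$K)
  neg <- fit_value_function(log_limb_points(-2, -1)$H, log_limb_points(-2, -1)$K)
  f <- extract_value_features(pos, neg, h_mean_pos = 2, h_mean_neg = 1.5)
  expect_equal(f[["LA"]], 1)                    # symmetric limbs
  expect_equal(f[["RA"]], 2 / 4)                # |a|/H^2 at H = 2
  expect_equal(f[["LR"]], 2 / 1.5^2)
  expect_equal(f[["Ante"]], 1)                  # b+ at unit entropy
  expect_equal(f[["Insurance"]], 1)

  neg3 <- fit_value_function(log_limb_points(-3, -1)$H, log_limb_points(-3, -1)$K)
  pos1 <- fit_value_function(log_limb_points(1, 0.5)$H, log_limb_points(1, 0.5)$K)
  expect_equal(extract_value_features(pos1, neg3, 1, 1)[["LA"]], 3)
})

test_that("non-positive upward slope leaves loss aversion undefined", {
  pos_bad <- fit_value_function(log_limb_points(-1, 2)$H, log_limb_points(-1, 2)$K)
  neg <- fit_value_function(log_limb_points(-2, -1)$H, log_limb_points(-2, -1)$K)
  f <- extract_value_features(pos_bad, neg, 1, 1)
  expect_true(is.na(f[["LA"]]))
})

test_that("exact concave quadratic is recovered and flagged correctly", {
  q <- quadratic_points(-1, 0, 4)
  fit <- fit_limit_function(q$K, q$sigma)
  expect_equal(fit$alpha, -1, tolerance = 1e-9)
  expect_equal(fit$beta, 0, tolerance = 1e-9)
  expect_equal(fit$gamma, 4, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$concave)

  flat <- fit_limit_function(c(-2, -1, 1, 2), rep(0.5, 4))
  expect_false(flat$concave)
})

test_that("noisy quadratic curvature is recovered within 0.1", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    q <- quadratic_points(-0.5, 0.1, 2)
    fit <- fit_limit_function(q$K, q$sigma + rnorm(length(q$K), 0, 0.05))
    fit$alpha - (-0.5)
  }, numeric(1))
  expect_true(all(abs(errs) <= 0.1))
})

test_that("limit features match symbolic roots, peaks and areas", {
  f <- extract_limit_features(fit_limit_function(
    quadratic_points(-1, 0, 4)$K, quadratic_points(-1, 0, 4)$sigma))
  expect_equal(f[["RewardTP"]], 2, tolerance = 1e-9)
  expect_equal(f[["AversionTP"]], 2, tolerance = 1e-9)
  expect_equal(f[["TotalRR"]], 16 / 3, tolerance = 1e-9)
  expect_equal(f[["TotalAR"]], 16 / 3, tolerance = 1e-9)
  # vertex at K = 0: supremum of both half-intervals at the open endpoint
  expect_equal(f[["PeakPR"]], 4, tolerance = 1e-9)
  expect_equal(f[["PeakNR"]], 4, tolerance = 1e-9)

  # shifted vertex: sigma = -(K-1)^2 + 4 = -K^2 + 2K + 3, roots -1 and 3
  g <- extract_limit_features(fit_limit_function(
    quadratic_points(-1, 2, 3)$K, quadratic_points(-1, 2, 3)$sigma))
  expect_equal(g[["RewardTP"]], 3, tolerance = 1e-9)
  expect_equal(g[["AversionTP"]], 1, tolerance = 1e-9)
  expect_equal(g[["PeakPR"]], 4, tolerance = 1e-9)   # vertex at K = 1
  expect_equal(g[["PeakNR"]], 3, tolerance = 1e-9)   # sigma(0)
  expect_equal(g[["TotalRR"]], 9, tolerance = 1e-9)
  expect_equal(g[["TotalAR"]], 5 / 3, tolerance = 1e-9)
})

test_that("convex fits leave limit features undefined", {
  q <- quadratic_points(0.5, 0, 0.2)
  f <- extract_limit_features(fit_limit_function(q$K, q$sigma))
  expect_true(all(is.na(f)))
})

test_that("closed-form areas agree with numerical quadrature", {
  set.seed(21)
  for (i in 1:20) {
    a <- -runif(1, 0.2, 2); g <- runif(1, 0.5, 4); b <- runif(1, -0.3, 0.3)
    q <- quadratic_points(a, b, g)
    fit <- fit_limit_function(q$K, q$sigma)
    f <- extract_limit_features(fit)
    if (is.na(f[["RewardTP"]])) next
    curve_fun <- function(k) a * k^2 + b * k + g
    expect_equal(f[["TotalRR"]],
                 stats::integrate(curve_fun, 0, fit$root_pos,
                                  rel.tol = 1e-12)$value, tolerance = 1e-9)
    expect_equal(f[["TotalAR"]],
                 abs(stats::integrate(curve_fun, fit$root_neg, 0,
                                      rel.tol = 1e-12)$value), tolerance = 1e-9)
  }
})

test_that("tradeoff polar mapping and features follow hand trigonometry", {
  fit <- fit_tradeoff_function(c(1, 0), c(0, 1))
  expect_equal(sort(fit$points$theta), c(0, pi / 2))
  expect_equal(fit$points$r, c(1, 1))
  f <- extract_tradeoff_features(fit)
  expect_equal(f[["RATradeoff"]], pi / 4)
  expect_equal(f[["TradeoffRange"]], pi / 2)
  expect_equal(f[["RAConsistency"]], 1)
  expect_equal(f[["ConsistencyRange"]], 0)

  one <- fit_tradeoff_function(c(1, 1), c(1, 1))
  expect_equal(extract_tradeoff_features(one)[["TradeoffRange"]], 0)
  expect_equal(fit_tradeoff_function(c(1, 1), c(1, 1))$points$theta[1], pi / 4)

  r13 <- extract_tradeoff_features(fit_tradeoff_function(
    c(1, 3) / sqrt(2), c(1, 3) / sqrt(2)))
  expect_equal(r13[["RAConsistency"]], 2)
  expect_equal(r13[["ConsistencyRange"]], 2)

  expect_null(fit_tradeoff_function(1, 1))
})

test_that("rating exclusions flag minimal variance and incomplete profiles", {
  r1 <- data.frame(participant = "A", category = rep(1:6, each = 8),
                   rating = 3L)
  r2 <- data.frame(participant = "B", category = rep(1:6, each = 8),
                   rating = rep(c(1L, 2L), 24))
  r3 <- complete_ratings("C")[c("participant", "category", "rating")]
  ratings <- rbind(r1, r2, r3)
  profiles <- compute_profiles(ratings)
  rep <- apply_rating_exclusions(ratings, profiles)
  expect_true("minimal_variance" %in% rep$flags[["A"]])
  expect_true("minimal_variance" %in% rep$flags[["B"]])
  expect_false("minimal_variance" %in% rep$flags[["C"]])
  if (profiles$complete[profiles$participant == "C"])
    expect_true("C" %in% rep$retained)
})
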