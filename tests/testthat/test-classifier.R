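# Two-class Gaussian data with a controllable class imbalance and signal.
make_gaussians <- function(n, p_higher = 0.5, sep = 3, n_noise = 4) {
  y <- factor(ifelse(seq_len(n) <= round(p_higher * n), "higher", "lower"),
              levels = c("lower", "higher"))
  x <- data.frame(signal = rnorm(n) + ifelse(y == "higher", sep, 0))
  for (j in seq_len(n_noise)) x[[paste0("noise", j)]] <- rnorm(n)
  list(x = x, y = y)
}

test_that("anxiety labelling is inclusive at the threshold", {
  y <- label_anxiety(c(34, 35, 36, 20), 35)
  expect_equal(as.character(y), c("lower", "higher", "higher", "lower"))
  pct <- attr(y, "class_percent")
  expect_equal(sum(pct), 100)
  expect_error(label_anxiety(c(20, 25), 90), "\\[20, 80\\]")
  expect_error(label_anxiety(rep(20, 5), 35), "unlearnable")
})

test_that("random forests learn separable data and refuse one class", {
  set.seed(201)
  d <- make_gaussians(500, sep = 5)
  model <- train_rf(d$x, d$y, mode = "rf", n_trees = 300)
  expect_gt(attr(model, "oob_accuracy"), 95)
  expect_error(train_rf(d$x[1:50, ], factor(rep("lower", 50),
                                            levels = c("lower", "higher"))),
               "single class")
})

test_that("balanced mode draws equal class counts in every tree", {
  set.seed(202)
  d <- make_gaussians(400, p_higher = 0.15)
  m <- min(table(d$y))
  model <- train_rf(d$x, d$y, mode = "brf", n_trees = 100, keep_inbag = TRUE)
  inbag <- model$inbag
  counts_h <- colSums(inbag[d$y == "higher", ])
  counts_l <- colSums(inbag[d$y == "lower", ])
  expect_true(all(counts_h == m))
  expect_true(all(counts_l == m))
})

test_that("shuffled labels bring out-of-bag accuracy to the base rate", {
  set.seed(203)
  d <- make_gaussians(600, p_higher = 0.5)
  y_perm <- sample(d$y)
  model <- train_rf(d$x, y_perm, mode = "rf", n_trees = 300,
                    vars_per_split = 2)
  base_rate <- 100 * max(table(y_perm)) / length(y_perm)
  # chance-level bound computed from repeated permutation runs of this
  # oracle: deviations stay within ~5 points at this sample size
  expect_lt(abs(attr(model, "oob_accuracy") - base_rate), 5)
})

test_that("evaluation reports confusion rates with 'higher' positive", {
  set.seed(204)
  d <- make_gaussians(600, sep = 6)
  idx <- sample(600, 400)
  model <- train_rf(d$x[idx, ], d$y[idx], mode = "rf", n_trees = 300)
  m <- evaluate_model(model, d$x[-idx, ], d$y[-idx])
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$auc, 1)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
})

test_that("classification runs are reproducible under a fixed seed", {
  d <- make_gaussians(300)
  cohort <- cbind(d$x, stai_s = ifelse(d$y == "higher", 50, 25))
  set.seed(205)
  r1 <- classify_cohort(cohort, 35, "brf", n_trees = 100)
  set.seed(205)
  r2 <- classify_cohort(cohort, 35, "brf", n_trees = 100)
  expect_equal(r1$metrics$accuracy, r2$metrics$accuracy)
  expect_equal(r1$metrics$auc, r2$metrics$auc)
  expect_equal(r1$split, r2$split)
})

test_that("normalized Gini shares sum to one and group sums partition", {
  set.seed(206)
  d <- make_gaussians(300)
  names(d$x) <- c("LA", "age", "loneliness", "RA", "sex")
  model <- train_rf(d$x, d$y, mode = "rf", n_trees = 200)
  imp <- gini_importance(model)
  expect_equal(sum(imp$shares), 1, tolerance = 1e-9)
  expect_equal(sum(imp$group_shares), 1, tolerance = 1e-9)
  expect_equal(names(imp$shares)[1], "LA")  # the only informative feature
})

test_that("proximity matrix is a valid similarity and separates clusters", {
  set.seed(207)
  d <- make_gaussians(120, sep = 8)
  d$x[1, ] <- d$x[2, ]  # exact duplicates
  model <- train_rf(d$x, d$y, mode = "rf", n_trees = 200)
  pm <- proximity_mds(model, d$x)
  P <- pm$proximity
  expect_equal(P, t(P))
  expect_true(all(diag(P) == 1))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(P[1, 2], 1)
  grp <- d$y
  cc <- pm$coords
  centroid <- rbind(colMeans(cc[grp == "higher", ]),
                    colMeans(cc[grp == "lower", ]))
  within_d <- mean(c(sqrt(rowSums((cc[grp == "higher", ] -
                                   centroid[rep(1, sum(grp == "higher")), ])^2)),
                     sqrt(rowSums((cc[grp == "lower", ] -
                                   centroid[rep(2, sum(grp == "lower")), ])^2))))
  between_d <- sqrt(sum((centroid[1, ] - centroid[2, ])^2))
  expect_lt(within_d, between_d)
  expect_error(proximity_mds(model, d$x[1:2, ]), "at least 3")
})

test_that("a single-iteration permutation equals one shuffled run", {
  set.seed(208)
  d <- make_gaussians(200)
  cohort <- cbind(d$x, stai_s = ifelse(d$y == "higher", 50, 25))
  pn <- permutation_null(cohort, 35, "rf", n_iter = 1, n_trees = 100)
  expect_equal(nrow(pn$per_iteration), 1L)
  expect_equal(unname(pn$mean["auc"]), pn$per_iteration$auc[1])
})
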