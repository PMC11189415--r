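#' Threshold anxiety scores into higher/lower classes
#'
#' Scores at or above the threshold are labelled `higher`, the rest
#' `lower`; `higher` is the positive class throughout.
#'
#' @param scores Numeric STAI-S scores in `[20, 80]`.
#' @param threshold Class boundary (must lie in `[20, 80]`; defaults used
#'   in the analyses are 35, 45 and 55, roughly the 50th, 75th and 90th
#'   score percentiles).
#' @return Factor with levels `lower`, `higher`; attribute
#'   `class_percent` gives each class's share of the data in percent.
#'   Errors if either class is empty (unlearnable split).
#' @export
label_anxiety <- function(scores, threshold) {
  if (threshold < 20 || threshold > 80)
    stop("threshold must lie within the STAI-S score range [20, 80]")
  y <- factor(ifelse(scores >= threshold, "higher", "lower"),
              levels = c("lower", "higher"))
  tab <- table(y)
  if (any(tab == 0))
    stop("unlearnable split: class '", names(tab)[tab == 0],
         "' is empty at threshold ", threshold)
  attr(y, "class_percent") <- 100 * as.numeric(tab) / length(y)
  names(attr(y, "class_percent")) <- names(tab)
  y
}

#' Split samples into train and test sets
#'
#' Simple random 70:30 split by default; optional stratification by class.
#'
#' @param y Class labels (used only when `stratify = TRUE`).
#' @param train_frac Fraction assigned to training.
#' @param stratify Preserve class proportions in both sets.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_frac = 0.7, stratify = FALSE) {
  n <- length(y)
  if (stratify) {
    train <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, round(train_frac * length(ix)))))
  } else {
    train <- sample(n, round(train_frac * n))
  }
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

#' Train a random forest or balanced random forest
#'
#' Both modes grow a forest of `n_trees` trees with `vars_per_split`
#' candidate variables per split. The balanced mode (`"brf"`) draws, for
#' every tree's bootstrap, an equal number of samples from each class
#' (with replacement), that number being the minority-class size, so the
#' majority class is down-sampled during training only; out-of-bag and test
#' metrics are always computed on the untouched, imbalanced data.
#'
#' @param x Predictor data frame (factors allowed).
#' @param y Factor of class labels with levels `lower`, `higher`.
#' @param mode `"rf"` (plain bootstrap) or `"brf"` (balanced bootstrap).
#' @param n_trees Number of trees (default 1000).
#' @param vars_per_split Candidate variables per split (default 5).
#' @param keep_inbag Record per-tree bootstrap counts (for auditing the
#'   per-tree class balance).
#' @param ... Further arguments passed to [randomForest::randomForest()].
#' @return A `randomForest` object with extra attribute `oob_accuracy`
#'   (percent, on the imbalanced training data).
#' @export
train_rf <- function(x, y, mode = c("rf", "brf"), n_trees = 1000L,
                     vars_per_split = 5L, keep_inbag = FALSE, ...) {
  mode <- match.arg(mode)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contains a single class")
  args <- list(x = x, y = y, ntree = n_trees,
               mtry = min(vars_per_split, ncol(x)),
               importance = FALSE, keep.inbag = keep_inbag, ...)
  if (mode == "brf") {
    m <- min(table(y))
    args$strata <- y
    args$sampsize <- stats::setNames(rep(m, nlevels(y)), levels(y))
    args$replace <- TRUE
  }
  model <- do.call(randomForest::randomForest, args)
  attr(model, "oob_accuracy") <- 100 * mean(model$predicted == y)
  attr(model, "mode") <- mode
  model
}

#' Evaluate a fitted forest on a test set
#'
#' Confusion-matrix rates treat `higher` as the positive class; the AUC is
#' computed from the continuous out-of-class vote fractions rather than
#' hard labels.
#'
#' @param model A forest from [train_rf()].
#' @param x_test,y_test Test predictors and labels.
#' @return A `metrics_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy` (all percent), `auc` (0-1),
#'   `oob_accuracy` (percent, from training), and the confusion matrix.
#'   Rates whose denominator class is absent from the test set are `NA`.
#' @export
evaluate_model <- function(model, x_test, y_test) {
  pred <- stats::predict(model, x_test)
  votes <- stats::predict(model, x_test, type = "prob")[, "higher"]
  cm <- table(truth = y_test, pred = factor(pred, levels = levels(y_test)))
  tp <- cm["higher", "higher"]; fn <- cm["higher", "lower"]
  tn <- cm["lower", "lower"];  fp <- cm["lower", "higher"]
  sens <- if ((tp + fn) > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if ((tn + fp) > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / sum(cm)
  auc <- if (nlevels(droplevels(y_test)) == 2L)
    as.numeric(pROC::auc(pROC::roc(response = y_test, predictor = votes,
                                   levels = c("lower", "higher"),
                                   direction = "<", quiet = TRUE)))
  else NA_real_
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 balanced_accuracy = mean(c(sens, spec)),
                 auc = auc,
                 oob_accuracy = attr(model, "oob_accuracy"),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f | sensitivity %.2f | specificity %.2f | balanced %.2f | AUC %.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$balanced_accuracy, x$auc))
  invisible(x)
}

#' Run one classification analysis at a threshold
#'
#' Labels the cohort, splits 70:30, trains in the requested mode and
#' evaluates on the held-out imbalanced test set.
#'
#' @param cohort A cohort analysis table (see [assemble_cohort_table()]):
#'   predictor columns plus `stai_s`.
#' @param threshold STAI-S class boundary.
#' @param mode `"rf"` or `"brf"`.
#' @param predictors Character vector of predictor column names; default
#'   all columns except `participant` and `stai_s`.
#' @param train_frac,stratify Split controls, see [split_train_test()].
#' @param n_trees,vars_per_split Forest controls, see [train_rf()].
#' @return List with `model`, `metrics` ([evaluate_model()] output),
#'   `class_percent`, and the split indices.
#' @export
classify_cohort <- function(cohort, threshold, mode = c("rf", "brf"),
                            predictors = NULL, train_frac = 0.7,
                            stratify = FALSE, n_trees = 1000L,
                            vars_per_split = 5L) {
  mode <- match.arg(mode)
  if (is.null(predictors))
    predictors <- setdiff(names(cohort), c("participant", "stai_s"))
  y <- label_anxiety(cohort$stai_s, threshold)
  x <- cohort[predictors]
  sp <- split_train_test(y, train_frac, stratify)
  model <- train_rf(x[sp$train, , drop = FALSE], y[sp$train],
                    mode = mode, n_trees = n_trees,
                    vars_per_split = vars_per_split)
  metrics <- evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
  list(model = model, metrics = metrics,
       class_percent = attr(y, "class_percent"), split = sp,
       threshold = threshold, mode = mode)
}

#' Permutation null for classifier metrics
#'
#' Shuffles the class labels, reruns the full train/evaluate procedure and
#' averages the metrics over iterations, giving the chance-level
#' calibration of the classifier.
#'
#' @inheritParams classify_cohort
#' @param n_iter Number of label-shuffle iterations (default 100).
#' @return List with `mean` (averaged metrics) and `per_iteration`
#'   data frame.
#' @export
permutation_null <- function(cohort, threshold, mode = c("rf", "brf"),
                             n_iter = 100L, predictors = NULL,
                             train_frac = 0.7, n_trees = 1000L,
                             vars_per_split = 5L) {
  mode <- match.arg(mode)
  stopifnot(n_iter >= 1L)
  if (is.null(predictors))
    predictors <- setdiff(names(cohort), c("participant", "stai_s"))
  y0 <- label_anxiety(cohort$stai_s, threshold)
  x <- cohort[predictors]
  res <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    y <- sample(y0)
    sp <- split_train_test(y, train_frac)
    model <- train_rf(x[sp$train, , drop = FALSE], y[sp$train],
                      mode = mode, n_trees = n_trees,
                      vars_per_split = vars_per_split)
    m <- evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
    res[[i]] <- data.frame(accuracy = m$accuracy,
                           sensitivity = m$sensitivity,
                           specificity = m$specificity,
                           balanced_accuracy = m$balanced_accuracy,
                           auc = m$auc, oob_accuracy = m$oob_accuracy)
  }
  per_iter <- do.call(rbind, res)
  list(mean = colMeans(per_iter, na.rm = TRUE), per_iteration = per_iter)
}

#' Normalized Gini relative importance
#'
#' Normalizes each feature's mean decrease in Gini by the sum over all
#' features, giving relative importance shares that sum to one, plus group
#' sums for the top contextual variables, the 15 judgment variables, and
#' the remaining predictors.
#'
#' @param model A fitted forest.
#' @param judgment_vars Names of the judgment-variable predictors.
#' @param top_contextuals Names of the headline contextual predictors
#'   (default age, loneliness, income, employment).
#' @return An `importance_report` list: `shares` (named, sorted decreasing),
#'   `raw`, and `group_shares` (`top_contextual`, `judgment`, `other`).
#' @export
gini_importance <- function(model,
                            judgment_vars = judgment_variable_names(),
                            top_contextuals = c("age", "loneliness",
                                                "income", "employment")) {
  raw <- randomForest::importance(model, type = 2)[, "MeanDecreaseGini"]
  if (sum(raw) <= 0) stop("all Gini importances are zero")
  shares <- raw / sum(raw)
  grp <- c(
    top_contextual = sum(shares[intersect(names(shares), top_contextuals)]),
    judgment = sum(shares[intersect(names(shares), judgment_vars)]))
  grp["other"] <- 1 - sum(grp)
  structure(list(shares = sort(shares, decreasing = TRUE), raw = raw,
                 group_shares = grp),
            class = "importance_report")
}

#' Proximity matrix and 2-D multidimensional scaling
#'
#' Pushes the samples through the fitted forest; two samples' proximity is
#' the fraction of trees in which they share a terminal node (symmetric,
#' unit diagonal). Classical metric MDS on `1 - P` gives 2-D coordinates.
#'
#' @param model A fitted forest.
#' @param x Data frame of samples (at least 3 rows).
#' @return List with `proximity` matrix and `coords` (n x 2 matrix).
#' @export
proximity_mds <- function(model, x) {
  if (nrow(x) < 3L) stop("proximity MDS needs at least 3 samples")
  pr <- stats::predict(model, x, proximity = TRUE)$proximity
  coords <- stats::cmdscale(stats::as.dist(1 - pr), k = 2)
  list(proximity = pr, coords = coords)
}
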