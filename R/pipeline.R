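#' Apply all participant-level exclusion filters
#'
#' Combines the four vendor criteria ([apply_vendor_filters()]) with the
#' minimal-rating-variance rule (all 48 ratings identical or varying by a
#' single point). Rules are evaluated independently of order.
#'
#' @param survey Survey data frame (see [apply_vendor_filters()]).
#' @param ratings Long-format rating table for the same participants.
#' @param ... Passed to [apply_vendor_filters()].
#' @return A [filter_report()].
#' @export
apply_all_filters <- function(survey, ratings, ...) {
  vendor <- apply_vendor_filters(survey, ...)
  flags <- vendor$flags
  rng <- tapply(ratings$rating, ratings$participant,
                function(r) diff(range(r)))
  for (id in names(flags)) {
    if (!is.na(rng[id]) && rng[id] <= 1)
      flags[[id]] <- union(flags[[id]], "minimal_variance")
  }
  filter_report(flags)
}

#' Assemble the cohort analysis table
#'
#' Joins the judgment profiles, encoded contextual variables and STAI-S
#' scores into the participants x predictors matrix used by the
#' classification, mediation/moderation and post hoc stages: 15 judgment
#' variables, 11 contextual predictors and the anxiety score. Only
#' complete cases are retained.
#'
#' @param profiles Output of [compute_profiles()].
#' @param contextual Output of [encode_contextuals()] with a `participant`
#'   column.
#' @param stai_scores Data frame with `participant` and `stai_s`.
#' @return Data frame keyed by `participant`.
#' @export
assemble_cohort_table <- function(profiles, contextual, stai_scores) {
  jv <- judgment_variable_names()
  left <- profiles[c("participant", jv)]
  out <- merge(left, contextual, by = "participant")
  out <- merge(out, stai_scores[c("participant", "stai_s")],
               by = "participant")
  keep <- stats::complete.cases(
    out[c(jv, "loneliness", "age", "sex", "income", "marital",
          "employment", "edu", "edu_years", "race_ethnicity",
          "covid_test", "covid_diagnosis", "stai_s")])
  out[keep, , drop = FALSE]
}

#' Read a deposited participant table
#'
#' Loads a participants-by-variables table (precomputed judgment
#' variables, contextual variables and anxiety scores) from CSV or, when
#' the readxl package is available, from an Excel workbook. Column names
#' are resolved through a declared name map so externally produced tables
#' load without transformation beyond renaming; unmapped extra columns are
#' kept with a warning.
#'
#' @param path File path (`.csv`, `.xlsx` or `.xls`).
#' @param name_map Named character vector mapping source column names to
#'   canonical names (`canonical = "source"`).
#' @param required Canonical columns that must be present after mapping.
#' @return Data frame with canonical column names.
#' @export
read_participant_table <- function(path, name_map = NULL,
                                   required = c("participant", "stai_s")) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading Excel files requires the readxl package")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(name_map)) {
    hit <- match(name_map, names(df))
    found <- !is.na(hit)
    names(df)[hit[found]] <- names(name_map)[found]
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  extras <- setdiff(names(df), c(required, judgment_variable_names(),
                                 names(contextual_levels()),
                                 c("age", "edu_years", "age_bin")))
  if (length(extras))
    warning("unmapped extra column(s): ", paste(extras, collapse = ", "))
  df
}

#' Pipeline run configuration
#'
#' Every field defaults to the analysis's canonical settings: thresholds
#' 35/45/55, a 70:30 train/test split, 1000 trees with 5 candidate
#' variables per split, and a 100-iteration permutation null.
#'
#' @param thresholds STAI-S class thresholds.
#' @param modes Classifier modes to run.
#' @param n_trees,vars_per_split,train_frac Forest and split settings.
#' @param n_permutations Permutation-null iterations (0 disables the null).
#' @param seed Integer seed governing the whole run.
#' @param rpt An [rpt_config()].
#' @param medmod_contextuals Contextual variables screened in the
#'   mediation/moderation stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = c(35, 45, 55),
                       modes = c("rf", "brf"),
                       n_trees = 1000L, vars_per_split = 5L,
                       train_frac = 0.7, n_permutations = 100L,
                       seed = 1L, rpt = rpt_config(),
                       medmod_contextuals = c("age", "loneliness",
                                              "income", "employment")) {
  structure(list(thresholds = thresholds, modes = modes,
                 n_trees = n_trees, vars_per_split = vars_per_split,
                 train_frac = train_frac, n_permutations = n_permutations,
                 seed = as.integer(seed), rpt = rpt,
                 medmod_contextuals = medmod_contextuals),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a cohort's raw tables: exclusion filters,
#' STAI-S scoring, judgment-variable extraction, rating-based exclusions,
#' cohort assembly, classification at every threshold and mode (optionally
#' with the permutation null), Gini relative importance,
#' mediation/moderation screens, and the post hoc nonparametric tests.
#' Every stage logs its row count; outputs and a manifest (configuration,
#' seed, stage counts) are written to `out_dir` when given.
#'
#' @param survey Survey data frame (STAI items, contextual variables,
#'   completion time, diagnosis count).
#' @param ratings Long-format rating table.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param permutation_null Run the permutation calibration (slow).
#' @return List with `filter_report`, `rating_report`, `cohort`,
#'   `classification` (per threshold x mode), `importance`, `medmod`,
#'   `posthoc`, `manifest`.
#' @export
run_pipeline <- function(survey, ratings, config = run_config(),
                         out_dir = NULL, permutation_null = FALSE) {
  set.seed(config$seed)
  log_stage <- function(...) message("[pipeline] ", ...)
  manifest <- list(config = unclass(config)[setdiff(names(config), "rpt")],
                  seed = config$seed, stages = list())

  # 1. survey filters
  report <- apply_all_filters(survey, ratings)
  survey <- survey[survey$participant %in% report$retained, , drop = FALSE]
  ratings <- ratings[ratings$participant %in% report$retained, , drop = FALSE]
  manifest$stages$filtered <- report$n_retained
  log_stage("filters retained ", report$n_retained, "/", report$n_input)

  # 2. STAI scoring
  stai_cols <- paste0("stai_", 1:20)
  scores <- data.frame(participant = survey$participant,
                       stai_s = score_stai_s(survey[stai_cols]))
  scores <- scores[!is.na(scores$stai_s), , drop = FALSE]
  manifest$stages$scored <- nrow(scores)

  # 3. judgment profiles + rating exclusions
  profiles <- compute_profiles(ratings, config$rpt)
  rating_report <- apply_rating_exclusions(ratings, profiles, config$rpt)
  profiles <- profiles[profiles$participant %in% rating_report$retained, ,
                       drop = FALSE]
  manifest$stages$profiles <- nrow(profiles)
  log_stage("profiles complete and retained: ", nrow(profiles))

  # 4. cohort assembly
  contextual <- encode_contextuals(survey)
  contextual <- cbind(participant = survey$participant, contextual)
  cohort <- assemble_cohort_table(profiles, contextual, scores)
  manifest$stages$cohort <- nrow(cohort)
  # cheap numeric fingerprints: any change in retained rows or scores
  # shows up here, making silent drift across runs detectable
  manifest$stages$stai_checksum <- sum(scores$stai_s)
  manifest$stages$cohort_checksum <-
    round(sum(cohort$stai_s) + sum(cohort$LA), 6)
  log_stage("cohort rows: ", nrow(cohort))

  # 5. classification
  predictors <- c(judgment_variable_names(),
                  "loneliness", "age", "sex", "income", "marital",
                  "employment", "edu", "edu_years", "race_ethnicity",
                  "covid_test", "covid_diagnosis")
  classification <- list()
  importance <- list()
  for (th in config$thresholds) {
    for (mode in config$modes) {
      key <- paste0(mode, "_", th)
      run <- classify_cohort(cohort, th, mode, predictors,
                             train_frac = config$train_frac,
                             n_trees = config$n_trees,
                             vars_per_split = config$vars_per_split)
      classification[[key]] <- run
      importance[[key]] <- gini_importance(run$model)
      if (permutation_null && config$n_permutations > 0)
        classification[[key]]$null <- permutation_null(
          cohort, th, mode, n_iter = config$n_permutations,
          predictors = predictors, train_frac = config$train_frac,
          n_trees = config$n_trees,
          vars_per_split = config$vars_per_split)
      log_stage(key, ": accuracy ",
                round(run$metrics$accuracy, 2), ", AUC ",
                round(run$metrics$auc, 4))
    }
  }

  # 6. mediation/moderation screens
  medmod <- screen_all_pairs(cohort, config$medmod_contextuals)
  manifest$stages$medmod_rows <- nrow(medmod$mediation)

  # 7. post hoc tests
  posthoc <- list(contextual = contextual_differences(cohort),
                  judgment = judgment_differences(cohort,
                                                  config$thresholds))
  manifest$stages$posthoc_rows <- nrow(posthoc$judgment)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    for (key in names(classification)) {
      m <- classification[[key]]$metrics
      jsonlite::write_json(
        m[c("accuracy", "sensitivity", "specificity",
            "balanced_accuracy", "auc", "oob_accuracy")],
        file.path(out_dir, paste0("metrics_", key, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(feature = names(importance[[key]]$shares),
                   share = as.numeric(importance[[key]]$shares)),
        file.path(out_dir, paste0("importance_", key, ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(medmod$mediation, file.path(out_dir, "mediation.csv"),
                     row.names = FALSE)
    utils::write.csv(medmod$moderation, file.path(out_dir, "moderation.csv"),
                     row.names = FALSE)
    utils::write.csv(posthoc$contextual,
                     file.path(out_dir, "posthoc_contextual.csv"),
                     row.names = FALSE)
    utils::write.csv(posthoc$judgment,
                     file.path(out_dir, "posthoc_judgment.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(filter_report = report, rating_report = rating_report,
       cohort = cohort, classification = classification,
       importance = importance, medmod = medmod, posthoc = posthoc,
       manifest = manifest)
}
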