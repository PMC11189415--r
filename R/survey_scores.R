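#' Reverse-keyed STAI-S items (form Y-1 key)
#'
#' Item numbers whose responses are reverse-scored (`r -> 5 - r`) before
#' summing. The standard Y-1 key reverses the ten anxiety-absent items.
#' Exposed as a function so the key can be overridden in scoring calls
#' without a code change.
#' @return Integer vector of item positions (1-based).
#' @export
stai_reverse_items <- function() c(1L, 2L, 5L, 8L, 10L, 11L, 15L, 16L, 19L, 20L)

#' Score the 20-item state anxiety inventory (STAI-S)
#'
#' Responses on the 4-point Likert scale (1-4) are summed after mapping
#' reverse-keyed items `r -> 5 - r`, giving a score in `[20, 80]`. Records
#' with missing or out-of-range items are rejected (scored `NA`), never
#' imputed.
#'
#' @param items A numeric vector of length 20, or a matrix/data frame with
#'   20 columns (one row per participant).
#' @param reverse Integer positions of the reverse-keyed items.
#' @return An integer score (or vector of scores), `NA` for invalid records.
#' @export
score_stai_s <- function(items, reverse = stai_reverse_items()) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1L)
  if (ncol(items) != 20L) stop("STAI-S requires exactly 20 items")
  stopifnot(all(reverse %in% 1:20))
  keyed <- items
  keyed[, reverse] <- 5 - keyed[, reverse]
  valid <- apply(items, 1L, function(r) !anyNA(r) && all(r %in% 1:4))
  out <- as.integer(rowSums(keyed))
  out[!valid] <- NA_integer_
  out
}

#' Build a filter report
#'
#' @param flags Named list mapping participant id to a character vector of
#'   triggered exclusion rules (empty vector = retained).
#' @return A list of class `filter_report`: `flags`, `excluded` ids,
#'   `retained` ids, `rule_counts`, `n_input`, `n_retained`, `n_excluded`.
#' @export
filter_report <- function(flags) {
  excl <- names(flags)[lengths(flags) > 0]
  ret <- setdiff(names(flags), excl)
  counts <- table(unlist(flags))
  structure(list(flags = flags, excluded = excl, retained = ret,
                 rule_counts = counts,
                 n_input = length(flags), n_retained = length(ret),
                 n_excluded = length(excl)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "records,", x$n_retained, "retained,",
      x$n_excluded, "excluded\n")
  if (length(x$rule_counts))
    for (r in names(x$rule_counts))
      cat("  ", r, ": ", x$rule_counts[[r]], "\n", sep = "")
  invisible(x)
}

#' Education-level vs years-of-education consistency table
#'
#' Editable mapping from ordinal education level to the plausible range of
#' reported years of education; records outside the range are flagged as
#' mismatched.
#' @return Data frame with columns `edu`, `min_years`, `max_years`.
#' @export
edu_consistency_table <- function() {
  data.frame(
    edu = 1:6,
    label = c("less than high school", "high school", "some college",
              "college degree", "graduate degree", "doctoral degree"),
    min_years = c(0, 10, 12, 14, 16, 18),
    max_years = c(11, 13, 16, 18, 24, 30))
}

#' Apply the vendor participant-exclusion filters
#'
#' Flags participants who (1) straight-lined (zero response variance within
#' any declared question section), (2) reported ten or more of the 17
#' clinician-diagnosed illnesses, (3) reported an education level
#' inconsistent with their years of education, or (4) completed the
#' questionnaire in under `min_seconds` (default 800 s). A missing
#' completion time is unevaluable and excluded. Rules are checked
#' independently, so their application order never changes the retained set.
#'
#' @param survey Data frame with one row per participant: a `participant`
#'   id column, the section response columns, `diagnosis_count`, `edu`,
#'   `edu_years` and `completion_seconds`.
#' @param sections Named list of character vectors of column names, one per
#'   question section, used for the straight-lining rule. Default: the 20
#'   STAI item columns `stai_1..stai_20` when present.
#' @param edu_table Consistency table, see [edu_consistency_table()].
#' @param min_seconds Minimum acceptable completion time.
#' @param max_diagnoses Diagnosis count at or above which a record is
#'   excluded.
#' @return A [filter_report()] with rules among `straight_lining`,
#'   `excess_diagnoses`, `edu_mismatch`, `fast_completion`,
#'   `missing_completion_time`.
#' @export
apply_vendor_filters <- function(survey,
                                 sections = NULL,
                                 edu_table = edu_consistency_table(),
                                 min_seconds = 800,
                                 max_diagnoses = 10L) {
  stopifnot("participant" %in% names(survey))
  if (is.null(sections)) {
    stai_cols <- grep("^stai_\\d+$", names(survey), value = TRUE)
    sections <- if (length(stai_cols)) list(stai = stai_cols) else list()
  }
  flags <- stats::setNames(rep(list(character(0)), nrow(survey)),
                           as.character(survey$participant))
  for (i in seq_len(nrow(survey))) {
    f <- character(0)
    for (sec in sections) {
      resp <- as.numeric(survey[i, sec])
      if (length(resp) > 1L && !anyNA(resp) && stats::var(resp) == 0) {
        f <- c(f, "straight_lining"); break
      }
    }
    dc <- survey$diagnosis_count[i]
    if (!is.na(dc) && dc >= max_diagnoses) f <- c(f, "excess_diagnoses")
    row <- edu_table[match(survey$edu[i], edu_table$edu), ]
    if (!is.na(survey$edu[i]) && !is.na(survey$edu_years[i]) &&
        nrow(row) == 1L && !is.na(row$min_years) &&
        (survey$edu_years[i] < row$min_years ||
         survey$edu_years[i] > row$max_years))
      f <- c(f, "edu_mismatch")
    cs <- survey$completion_seconds[i]
    if (is.na(cs)) f <- c(f, "missing_completion_time")
    else if (cs < min_seconds) f <- c(f, "fast_completion")
    flags[[i]] <- f
  }
  filter_report(flags)
}

#' Declared level orders for ordinal/categorical contextual variables
#' @param loneliness_levels Number of loneliness response levels (default 5).
#' @return Named list of level vectors.
#' @export
contextual_levels <- function(loneliness_levels = 5L) {
  list(
    loneliness = as.character(seq_len(loneliness_levels)),
    sex = c("male", "female"),
    income = as.character(1:8),
    marital = c("single", "married", "living_with_partner", "separated",
                "divorced", "widowed"),
    employment = c("retired", "unemployed", "student", "part_time",
                   "full_time", "multiple_jobs"),
    edu = as.character(1:6),
    race_ethnicity = c("white", "african_american", "hispanic", "asian",
                       "mixed", "other"),
    covid_test = c("no", "yes"),
    covid_diagnosis = c("no", "yes"))
}

#' Bin age into three levels
#'
#' Younger adults are 18-39; the remaining boundary (default 55) splits
#' middle from older adulthood and is configurable.
#' @param age Numeric vector of ages in years.
#' @param middle_cut Upper bound of the middle bin.
#' @return Factor with levels `young`, `middle`, `older`.
#' @export
bin_age <- function(age, middle_cut = 55) {
  cut(age, breaks = c(-Inf, 39, middle_cut, Inf),
      labels = c("young", "middle", "older"))
}

#' Encode contextual variables with declared level orders
#'
#' Ordinal variables become integer codes following the declared order;
#' categorical variables become factors; age is additionally binned to
#' three levels. The encoding map is attached for audit.
#'
#' @param raw Data frame with the 11 contextual columns: `loneliness`,
#'   `age`, `sex`, `income`, `marital`, `employment`, `edu`, `edu_years`,
#'   `race_ethnicity`, `covid_test`, `covid_diagnosis`.
#' @param levels_map Level orders, see [contextual_levels()].
#' @param middle_cut Age-bin boundary passed to [bin_age()].
#' @return Data frame with encoded columns plus `age_bin`; attribute
#'   `encoding_map` holds the level orders used.
#' @export
encode_contextuals <- function(raw, levels_map = contextual_levels(),
                               middle_cut = 55) {
  need <- c("loneliness", "age", "sex", "income", "marital", "employment",
            "edu", "edu_years", "race_ethnicity", "covid_test",
            "covid_diagnosis")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing contextual columns: ", paste(missing_cols, collapse = ", "))
  out <- raw[need]
  ordinal <- c("loneliness", "income", "edu")
  categorical <- c("sex", "marital", "employment", "race_ethnicity",
                   "covid_test", "covid_diagnosis")
  for (v in c(ordinal, categorical)) {
    vals <- as.character(raw[[v]])
    bad <- setdiff(unique(vals[!is.na(vals)]), levels_map[[v]])
    if (length(bad))
      stop("unseen level(s) in '", v, "': ", paste(bad, collapse = ", "))
    if (v %in% ordinal)
      out[[v]] <- as.integer(factor(vals, levels = levels_map[[v]]))
    else
      out[[v]] <- factor(vals, levels = levels_map[[v]])
  }
  out$age <- as.numeric(raw$age)
  out$edu_years <- as.numeric(raw$edu_years)
  out$age_bin <- bin_age(out$age, middle_cut)
  attr(out, "encoding_map") <- levels_map
  out
}
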