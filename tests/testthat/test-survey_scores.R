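test_that("STAI-S scoring applies the reverse key and stays in [20, 80]", {
  expect_equal(score_stai_s(rep(1, 20)), 50L)  # 10*1 + 10*(5-1)
  direct <- setdiff(1:20, stai_reverse_items())
  resp_min <- integer(20); resp_min[direct] <- 1L
  resp_min[stai_reverse_items()] <- 4L
  expect_equal(score_stai_s(resp_min), 20L)
  resp_max <- integer(20); resp_max[direct] <- 4L
  resp_max[stai_reverse_items()] <- 1L
  expect_equal(score_stai_s(resp_max), 80L)
})

test_that("invalid STAI records are rejected, not imputed", {
  bad <- rep(2, 20); bad[7] <- NA
  expect_true(is.na(score_stai_s(bad)))
  bad2 <- rep(2, 20); bad2[3] <- 5
  expect_true(is.na(score_stai_s(bad2)))
  expect_error(score_stai_s(rep(2, 19)), "20 items")
})

test_that("scoring is monotone in the keyed direction", {
  set.seed(8)
  direct <- setdiff(1:20, stai_reverse_items())
  for (i in 1:25) {
    r <- sample(1:4, 20, replace = TRUE)
    s0 <- score_stai_s(r)
    j <- sample(direct, 1)
    if (r[j] < 4) {
      r2 <- r; r2[j] <- r[j] + 1L
      expect_gte(score_stai_s(r2), s0)
    }
    k <- sample(stai_reverse_items(), 1)
    if (r[k] < 4) {
      r3 <- r; r3[k] <- r[k] + 1L
      expect_lte(score_stai_s(r3), s0)
    }
  }
})

make_survey <- function(n = 4) {
  stai <- matrix(rep(c(1L, 2L, 3L, 4L), 5 * n), nrow = n,
                 dimnames = list(NULL, paste0("stai_", 1:20)))
  data.frame(participant = paste0("P", seq_len(n)), stai,
             diagnosis_count = 1L, edu = 3L, edu_years = 14,
             completion_seconds = 1200)
}

test_that("vendor filters enforce the four exclusion criteria", {
  sv <- make_survey(6)
  sv$completion_seconds[1] <- 799     # just under the floor
  sv$completion_seconds[2] <- 800     # boundary: retained
  sv$diagnosis_count[3] <- 10L        # at the diagnosis cap
  sv[4, paste0("stai_", 1:20)] <- 2L  # straight-lined section
  sv$edu[5] <- 4L; sv$edu_years[5] <- 5  # inconsistent education
  rep <- apply_vendor_filters(sv)
  expect_true("fast_completion" %in% rep$flags[["P1"]])
  expect_true("P2" %in% rep$retained)
  expect_true("excess_diagnoses" %in% rep$flags[["P3"]])
  expect_true("straight_lining" %in% rep$flags[["P4"]])
  expect_true("edu_mismatch" %in% rep$flags[["P5"]])
  expect_true("P6" %in% rep$retained)
  expect_equal(rep$n_retained + rep$n_excluded, rep$n_input)
})

test_that("missing completion time is unevaluable and excluded", {
  sv <- make_survey(2)
  sv$completion_seconds[2] <- NA
  rep <- apply_vendor_filters(sv)
  expect_true("missing_completion_time" %in% rep$flags[["P2"]])
})

test_that("filters are independent of row order", {
  sv <- make_survey(6)
  sv$completion_seconds[1] <- 100
  sv$diagnosis_count[3] <- 12L
  r1 <- apply_vendor_filters(sv)
  r2 <- apply_vendor_filters(sv[sample(6), ])
  expect_setequal(r1$retained, r2$retained)
})

test_that("contextual encoding binned age and rejects unknown labels", {
  raw <- data.frame(loneliness = "2", age = c(25, 40, 60), sex = "female",
                    income = "3", marital = "married",
                    employment = "full_time", edu = "3", edu_years = 14,
                    race_ethnicity = "white", covid_test = "no",
                    covid_diagnosis = "no")
  enc <- encode_contextuals(raw)
  expect_equal(as.character(enc$age_bin), c("young", "middle", "older"))
  expect_type(enc$loneliness, "integer")
  expect_s3_class(enc$marital, "factor")
  expect_false(is.null(attr(enc, "encoding_map")))

  raw$marital <- "xx"
  expect_error(encode_contextuals(raw), "xx")
  expect_error(encode_contextuals(raw[, -2]), "missing contextual")
})
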