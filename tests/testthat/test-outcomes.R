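pain_df <- function(day, score) data.frame(date = day, score = score)

test_that("extract_preop_pain uses the latest in-window day", {
  expect_equal(extract_preop_pain(pain_df(c(-3, -3), c(4, 6)), 0), 5)
  expect_true(is.na(extract_preop_pain(pain_df(-45, 3), 0)))
  expect_equal(extract_preop_pain(pain_df(c(-10, -2), c(8, 4)), 0), 4)
  expect_true(is.na(extract_preop_pain(pain_df(2, 5), 0))) # postop ignored
  expect_true(is.na(extract_preop_pain(pain_df(numeric(0), numeric(0)), 0)))
})

test_that("extract_discharge_pain averages the last inpatient day", {
  expect_equal(extract_discharge_pain(pain_df(5, 7), 5), 7)
  expect_equal(extract_discharge_pain(pain_df(c(5, 5, 4), c(6, 8, 1)), 5), 7)
  expect_true(is.na(extract_discharge_pain(pain_df(4, 6), 5)))
})

test_that("extract_followup_pain picks the closest day, earlier on ties", {
  expect_equal(extract_followup_pain(pain_df(22, 3), 0, 21), 3)
  expect_equal(extract_followup_pain(pain_df(c(19, 24), c(2, 9)), 0, 21), 2)
  expect_equal(extract_followup_pain(pain_df(c(20, 22), c(1, 9)), 0, 21), 1)
  expect_true(is.na(extract_followup_pain(pain_df(c(10, 30), c(1, 2)), 0, 21)))
  expect_equal(extract_followup_pain(pain_df(c(50, 63), c(4, 8)), 0, 56), 4)
})

test_that("compute_delta and the tie policy", {
  d <- compute_delta(2.29, 3.0)
  expect_equal(d$delta, 0.71)
  expect_true(d$worsened)
  d <- compute_delta(3, 3)
  expect_equal(d$delta, 0)
  expect_false(d$worsened)
  expect_true(is.na(compute_delta(NA, 3)$delta))
})

test_that("deltas are invariant to shifting every pain score", {
  ex <- small_extract()
  cb <- small_cohort()
  oc1 <- compute_outcomes(cb$cohort, ex$pain)
  shifted <- ex$pain
  shifted$score <- shifted$score + 1.5
  cb2 <- cb
  cb2$cohort$preop_pain <- cb$cohort$preop_pain + 1.5
  oc2 <- compute_outcomes(cb2$cohort, shifted)
  expect_equal(oc2$delta_discharge, oc1$delta_discharge)
  expect_equal(oc2$delta_wk3, oc1$delta_wk3)
  expect_equal(oc2$delta_wk8, oc1$delta_wk8)
})

test_that("missingness is monotone and per-time-point n is reported", {
  ex <- small_extract()
  cb <- small_cohort()
  oc <- compute_outcomes(cb$cohort, ex$pain)
  expect_lte(sum(!is.na(oc$delta_wk8)), nrow(cb$cohort))
  rep4 <- delta_report(oc)
  expect_identical(nrow(rep4), 6L)
  expect_true(all(rep4$n_pro + rep4$n_non <= nrow(cb$cohort)))
  expect_true(all(rep4$p_value >= 0 & rep4$p_value <= 1))
})

test_that("compare_groups on identical arms and degenerate input", {
  oc <- data.frame(
    group = rep(c("SSRI+/Pro+", "SSRI+/Pro-"), each = 50),
    delta_discharge = rep(c(1, 2, 3, 4, 5), 20))
  gc <- compare_groups(oc, "SSRI+", "discharge")
  expect_equal(gc$mean[["pro"]], gc$mean[["non"]])
  expect_gt(gc$p_value, 0.99)
  oc1 <- data.frame(group = c("SSRI+/Pro+", "SSRI+/Pro-", "SSRI+/Pro-"),
                    delta_discharge = c(1, 2, 3))
  expect_error(compare_groups(oc1, "SSRI+", "discharge"), "insufficient")
})

test_that("compare_groups separates arms drawn at the published parameters", {
  # power sanity check at Table-4-like parameters (unclamped normals)
  set.seed(99)
  hits <- 0
  for (r in 1:20) {
    oc <- data.frame(
      group = rep(c("SSRI+/Pro+", "SSRI+/Pro-"), c(606, 1285)),
      delta_discharge = c(rnorm(606, 0.720, 3.15), rnorm(1285, 0.161, 3.29)))
    if (compare_groups(oc, "SSRI+", "discharge")$p_value < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 17)
})
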