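test_that("select_surgeries keeps the first eligible surgery per patient", {
  enc <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    surgery_date = c(90, 0, 10, 5),
    age_at_surgery = c(50, 50, 17, 60),
    death_in_hospital = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  out <- select_surgeries(enc)
  expect_identical(out$patient_id, "A")
  expect_identical(out$surgery_date, 0)
  expect_identical(nrow(select_surgeries(enc[0, ])), 0L)
})

test_that("classify_opioid implements the two printed ingredient lists", {
  expect_identical(classify_opioid("hydrocodone"), "prodrug")
  expect_identical(classify_opioid(c("codeine", "tramadol")),
                   rep("prodrug", 2))
  expect_identical(classify_opioid(c("morphine", "fentanyl", "hydromorphone",
                                     "oxycodone", "methadone")),
                   rep("non_prodrug", 5))
  expect_identical(classify_opioid("acetaminophen"), "not_opioid")
  expect_identical(classify_opioid("Oxycodone"), "non_prodrug")
})

test_that("distill_ingredients resolves trade and combination names", {
  map <- read_drug_map()
  expect_setequal(distill_ingredients("Vicodin", map)[[1]],
                  c("hydrocodone", "acetaminophen"))
  expect_identical(distill_ingredients("morphine sulfate", map)[[1]],
                   "morphine")
  expect_warning(out <- distill_ingredients("zzz-unknown-drug", map),
                 "unknown drug")
  expect_identical(out[[1]], "zzz-unknown-drug")
  # trade name and generic spelling classify identically
  for (pair in list(c("Vicodin", "hydrocodone"),
                    c("Percocet", "oxycodone hcl"),
                    c("Ultram", "tramadol"))) {
    cls <- lapply(distill_ingredients(pair, map), function(x) {
      sort(unique(classify_opioid(x)[classify_opioid(x) != "not_opioid"]))
    })
    expect_identical(cls[[1]], cls[[2]], info = pair[1])
  }
})

test_that("compute_daily_ome applies conversion factors per inpatient day", {
  conv <- read_ome_table()
  adm <- function(ing, dose, route = "oral") {
    data.frame(ingredient = ing, dose_mg = dose, route = route)
  }
  expect_equal(compute_daily_ome(adm("morphine", 30), 1, conv), 30)
  expect_equal(compute_daily_ome(adm("oxycodone", 20), 1, conv), 30)
  expect_equal(compute_daily_ome(adm("morphine", c(30, 30)), 2, conv), 30)
  expect_equal(compute_daily_ome(adm("morphine", 10, "iv"), 1, conv), 30)
  expect_equal(compute_daily_ome(adm("morphine", 30)[0, ], 3, conv), 0)
  expect_warning(
    v <- compute_daily_ome(adm(c("morphine", "mystery"), c(30, 99)), 1, conv),
    "no OME conversion")
  expect_equal(v, 30)
})

test_that("flag_opioid_naive uses the 12-month pre-admission window", {
  expect_false(flag_opioid_naive(-100))
  expect_true(flag_opioid_naive(integer(0)))
  expect_true(flag_opioid_naive(-400))
  expect_false(flag_opioid_naive(-365))
  expect_true(flag_opioid_naive(c(-400, 5))) # day 0+ is not "prior"
})

test_that("Charlson scoring weights, windows and monotonicity", {
  expect_identical(compute_charlson_category(character(0))$category, "0-2")
  met <- compute_charlson_category("197.0")
  expect_identical(met$score, 6L)
  expect_identical(met$category, "3+")
  expect_identical(compute_charlson_category(c("585.9", "250.40"))$score, 4L)
  # complicated diabetes supersedes uncomplicated within the family
  expect_identical(compute_charlson_category(c("250.00", "250.40"))$score, 2L)
  expect_identical(compute_charlson_category("I10")$score, 0L)
  # adding a diagnosis never lowers the category
  set.seed(8)
  pool <- c("410.1", "428.0", "496", "585.9", "197.0", "C78.1", "I10",
            "F32.9", "K25.3", "C50.9")
  for (i in 1:20) {
    base <- sample(pool, sample(0:4, 1))
    more <- c(base, sample(pool, 1))
    expect_gte(compute_charlson_category(more)$score,
               compute_charlson_category(base)$score)
  }
})

test_that("assign_groups recovers the true group for every cohort patient", {
  ex <- small_extract()
  cb <- small_cohort()
  g <- ex$gold$patients
  truth <- g[g$in_cohort, c("patient_id", "group", "provenance")]
  m <- merge(cb$cohort[, c("patient_id", "group", "depression_source")],
             truth, by = "patient_id")
  # partition: groups are disjoint, union is the cohort
  expect_identical(nrow(cb$cohort), nrow(truth))
  expect_identical(sum(table(cb$cohort$group)), nrow(cb$cohort))
  expect_identical(m$group.x, m$group.y)
  # depression_source never empty, and consistent with gold provenance
  expect_true(all(nzchar(m$depression_source)))
  expect_true(all(grepl("icd", m$depression_source[m$provenance == "icd_only"])))
  expect_true(all(grepl("note", m$depression_source[m$provenance == "note_only"])))
  # attrition accounts for dropped patients
  expect_true(all(c("not_depressed", "no_discharge_opioid") %in%
                    cb$attrition$reason))
})

test_that("provenance reconciliation recovers the configured overlap", {
  ex <- small_extract()
  nlp <- small_nlp()
  counts <- depression_provenance_counts(ex, nlp$patient_flags)
  cfg <- small_config()
  expected <- largest_remainder(cfg$n_patients, cfg$icd_note_overlap)
  expect_identical(unname(counts[c("note_only", "icd_only", "both")]),
                   expected)
  expect_identical(unname(counts[["total"]]), sum(expected))
})

test_that("mixed discharge prescriptions follow the OME-based policy", {
  conv <- read_ome_table()
  mixed <- list(c("hydrocodone", "acetaminophen"), "oxycodone")
  # 10 mg hydrocodone (OME 10) vs 20 mg oxycodone (OME 30) -> non_prodrug
  expect_identical(
    painpheno:::classify_discharge(mixed, c(10, 20), conv, "ome"),
    "non_prodrug")
  # 30 mg hydrocodone (OME 30) vs 10 mg oxycodone (OME 15) -> prodrug
  expect_identical(
    painpheno:::classify_discharge(mixed, c(30, 10), conv, "ome"),
    "prodrug")
  # exact tie goes to non_prodrug (misclassification-conservative)
  expect_identical(
    painpheno:::classify_discharge(mixed, c(30, 20), conv, "ome"),
    "non_prodrug")
  expect_identical(
    painpheno:::classify_discharge(mixed, c(10, 20), conv, "prodrug"),
    "prodrug")
  expect_identical(painpheno:::classify_discharge(list(), numeric(0), conv),
                   "none")
})

test_that("feature matrix follows the manifest exactly", {
  manifest <- read_feature_manifest()
  expect_identical(nrow(manifest), 65L)
  cb <- small_cohort()
  X <- build_feature_matrix(cb$cohort)
  expect_identical(dim(X), c(nrow(cb$cohort), 65L))
  expect_identical(colnames(X), manifest$name)
  # vitals deviations are raw differences from the 120/80 normals
  i <- which(!is.na(cb$cohort$sbp_dev))[1]
  expect_equal(unname(X[i, "sbp_deviation"]), cb$cohort$sbp_dev[i])
  # missing preop pain -> NA value + indicator set
  j <- which(is.na(cb$cohort$preop_pain))
  expect_gt(length(j), 0)
  expect_true(all(is.na(X[j, "preop_pain"])))
  expect_true(all(X[j, "preop_pain_missing"] == 1))
  expect_true(all(X[-j, "preop_pain_missing"] == 0))
  # group one-hot matches group labels
  expect_equal(rowSums(X[, c("group_ssri_pro", "group_ssri_nonpro",
                             "group_nossri_pro", "group_nossri_nonpro")]),
               rep(1, nrow(X)))
})

test_that("imputation and standardization use training statistics only", {
  set.seed(2)
  tr <- matrix(rnorm(60), 20, 3)
  tr[1:4, 2] <- NA
  te <- matrix(rnorm(15), 5, 3)
  te[1, 2] <- NA
  out <- impute_standardize(tr, te)
  expect_false(anyNA(out$train))
  expect_false(anyNA(out$test))
  expect_equal(colMeans(out$train), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(out$train, 2, sd), rep(1, 3), tolerance = 1e-12)
  # the imputed test entry equals the training mean, standardized to ~0
  expect_equal(out$test[1, 2],
               (out$impute_means[2] - out$center[2]) / out$scale[2])
  # test columns are NOT re-centred on their own statistics
  expect_gt(max(abs(colMeans(out$test))), 1e-6)
})
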