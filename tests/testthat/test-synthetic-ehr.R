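test_that("generator config validates its invariants", {
  expect_error(generator_config(group_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(generator_config(preop_pain_sds = c(0, 1, 1, 1)), "positive")
  expect_error(generator_config(followup_retention = c(discharge = 0,
                                                       wk3 = 1, wk8 = 1)),
               "retention")
  expect_error(generator_config(n_patients = 100,
                                icd_note_overlap = c(10, 10, 10)),
               "sum to n_patients")
  expect_s3_class(small_config(), "generator_config")
})

test_that("deterministic group allocation reproduces the published counts", {
  # published proportions at the published cohort size
  counts <- largest_remainder(4306, c(0.1407, 0.2984, 0.1863, 0.3746))
  expect_identical(counts, c(606L, 1285L, 802L, 1613L))
  ex <- small_extract()
  g <- ex$gold$patients
  grp <- table(factor(g$group[g$in_cohort], levels = GROUP_LEVELS))
  n_cohort <- sum(g$in_cohort)
  expect_identical(as.integer(grp),
                   largest_remainder(n_cohort, small_config()$group_proportions))
  # provenance counts match the configured overlap exactly
  ov <- largest_remainder(small_config()$n_patients,
                          small_config()$icd_note_overlap)
  prov <- table(g$provenance[g$role == "universe"])
  expect_identical(as.integer(prov[c("note_only", "icd_only", "both")]), ov)
})

test_that("the extract is deterministic and n = 0 yields an empty extract", {
  cfg <- small_config(n = 40L, seed = 9L)
  e1 <- generate_cohort(cfg)
  e2 <- generate_cohort(cfg)
  expect_identical(e1, e2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_extract(e1, d1)
  write_extract(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # different seed changes the output
  expect_false(identical(generate_cohort(small_config(n = 40L, seed = 10L)),
                         e1))
  empty <- generate_cohort(generator_config(n_patients = 0L))
  expect_s3_class(empty, "ehr_extract")
  expect_identical(nrow(empty$patients), 0L)
  expect_identical(nrow(empty$notes), 0L)
})

test_that("round-trip through write_extract/read_extract preserves tables", {
  ex <- generate_cohort(small_config(n = 30L, seed = 4L))
  d <- withr::local_tempdir()
  write_extract(ex, d)
  back <- read_extract(d)
  for (nm in c("patients", "encounters", "medications", "pain")) {
    expect_equal(back[[nm]], ex[[nm]], ignore_attr = TRUE)
  }
  expect_identical(back$notes$text, ex$notes$text)
})

test_that("note gold labels obey their construction rules", {
  ex <- small_extract()
  g <- ex$gold$patients
  gn <- ex$gold$notes
  # every note-depressed patient has >= 1 Affirmed gold note in the window
  for (pid in g$patient_id[g$provenance %in% c("note_only", "both")]) {
    sub <- gn[gn$patient_id == pid, ]
    expect_true(any(sub$label == "Affirmed" & sub$rel_day >= -365 &
                      sub$rel_day <= 0), info = pid)
  }
  # patients not depressed by notes have no in-window Affirmed note
  for (pid in g$patient_id[!(g$provenance %in% c("note_only", "both"))]) {
    sub <- gn[gn$patient_id == pid, ]
    expect_false(any(sub$label == "Affirmed" & sub$rel_day >= -365 &
                       sub$rel_day <= 0), info = pid)
  }
  # exactly one gold label per note
  expect_identical(anyDuplicated(gn$note_id), 0L)
  expect_identical(sort(unique(ex$notes$note_id)), sort(gn$note_id))
})

test_that("decoy-only notes are never gold-Affirmed and note_noise=0 is clean", {
  tpl <- utils::read.delim(system.file("extdata", "note_templates.tsv",
                                       package = "painpheno"),
                           stringsAsFactors = FALSE)
  cfg0 <- small_config(n = 30L, seed = 11L, note_noise = 0)
  ex0 <- generate_cohort(cfg0)
  # with zero noise every sentence is a verbatim template instantiation
  sens <- unlist(lapply(ex0$notes$text, function(t) {
    trimws(strsplit(t, "(?<=[.])\\s+", perl = TRUE)[[1]])
  }))
  expect_true(all(sens %in% tpl$text))
  expect_false(any(sens %in% tpl$text[tpl$category == "decoy"]))
})

test_that("pain trajectories recover configured deltas after truncation correction", {
  cfg <- small_config(n = 4000L, seed = 77L,
                      preop_retention = 1,
                      followup_retention = c(discharge = 1, wk3 = 1, wk8 = 1))
  pats <- generate_cohort(cfg)$gold$patients
  for (gidx in c(1L, 4L)) {
    grp <- GROUP_LEVELS[gidx]
    sub <- pats[pats$group == grp, ]
    d <- sub$postop_discharge - sub$preop_recorded
    expected <- expected_clamped_delta(cfg$preop_pain_means[gidx],
                                       cfg$preop_pain_sds[gidx],
                                       cfg$delta_means[gidx, 1],
                                       cfg$delta_sds[gidx, 1])
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - expected), 3 * se)
  }
})

test_that("null effect: zero deltas and tiny SDs give postop == preop", {
  cfg <- small_config(
    n = 60L, seed = 5L,
    delta_means = matrix(0, 4, 3, dimnames = list(GROUP_LEVELS, TIME_POINTS)),
    delta_sds = matrix(1e-9, 4, 3,
                       dimnames = list(GROUP_LEVELS, TIME_POINTS)))
  g <- generate_cohort(cfg)$gold$patients
  sub <- g[g$in_cohort & !is.na(g$preop_recorded) & !is.na(g$postop_discharge), ]
  expect_gt(nrow(sub), 10)
  expect_lt(max(abs(sub$postop_discharge - sub$preop_recorded)), 1e-6)
})

test_that("retention thinning matches its binomial expectation", {
  cfg <- small_config(n = 3000L, seed = 13L,
                      followup_retention = c(discharge = 0.97, wk3 = 0.94,
                                             wk8 = 0.62))
  g <- generate_cohort(cfg)$gold$patients
  coh <- g[g$in_cohort, ]
  obs <- mean(!is.na(coh$postop_wk8))
  ci <- stats::binom.test(sum(!is.na(coh$postop_wk8)), nrow(coh))$conf.int
  expect_true(ci[1] <= 0.62 && 0.62 <= ci[2])
  expect_lt(abs(obs - 0.62), 0.03)
})

test_that("combination products appear in at least 10% of discharge orders", {
  ex <- small_extract()
  disch <- ex$medications[ex$medications$setting == "discharge", ]
  map <- read_drug_map()
  n_ing <- lengths(distill_ingredients(disch$drug_name, map))
  expect_gt(mean(n_ing > 1), 0.10)
})
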