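lex <- default_lexicon("depression")

test_that("preprocess normalizes case, whitespace and boundaries", {
  s <- preprocess("Major  Depressive Disorder.")
  expect_length(s, 1)
  expect_identical(s[[1]]$tokens[s[[1]]$keep],
                   c("major", "depressive", "disorder"))
  expect_length(preprocess(""), 0)
  two <- preprocess("Patient is well. Denies depression today.")
  expect_length(two, 2)
  expect_identical(two[[2]]$text, "denies depression today")
  # negation cues survive in the raw view even though dropped from the
  # concept view
  expect_true("denies" %in% two[[2]]$tokens)
})

test_that("match_concepts finds longest matches and applies exclusions", {
  m <- match_concepts("ecg shows st depression in leads ii", lex)
  expect_true(m$filtered)
  m <- match_concepts("stress and depression, need to continue medication",
                      lex)
  expect_false(m$filtered)
  expect_true("depression" %in% m$matches$term)
  m <- match_concepts("patient is doing well", lex)
  expect_identical(nrow(m$matches), 0L)
  # multiword concept wins over its single-word prefix
  m <- match_concepts("major depressive disorder, recurrent", lex)
  expect_identical(m$matches$term[1], "major depressive disorder")
})

test_that("classify_sentence reproduces the published sample annotations", {
  snippets <- c(
    "major depressive disorder, recurrent episode, moderate" = "Affirmed",
    "stress and depression, need to continue medication" = "Affirmed",
    "patient stating more depression recently, was at behavioral facility and is now more paranoid" = "Affirmed",
    "patient had no preinjury mental health issues or depression" = "Negated",
    "anxiety was situational, currently no symptoms of depression" = "Negated")
  for (s in names(snippets)) {
    expect_identical(classify_sentence(s, lex)$label, snippets[[s]],
                     info = s)
  }
})

test_that("negation scope honours window and termination terms", {
  expect_identical(classify_sentence("denies depression but reports anxiety",
                                     lex)$label, "Negated")
  # termination between trigger and concept cuts the scope
  expect_identical(classify_sentence(
    "no anxiety but depression is present", lex)$label, "Affirmed")
  # beyond the 5-token window the trigger no longer reaches
  expect_identical(classify_sentence(
    "no acute distress from one two three four five six depression", lex)$label,
    "Affirmed")
  # post-negation
  expect_identical(classify_sentence("depression ruled out", lex)$label,
                   "Negated")
})

test_that("adding a pre-negation trigger flips a lone affirmed concept", {
  sentences <- c("patient reports depression today",
                 "chronic depression with poor sleep",
                 "assessment includes anhedonia now")
  mlex <- micro_lexicon()
  for (s in sentences) {
    expect_identical(classify_sentence(s, mlex)$label, "Affirmed")
    expect_identical(classify_sentence(paste("denies", s), mlex)$label,
                     "Negated", info = s)
  }
})

test_that("filter precedence: excluded concepts are NoMention regardless of triggers", {
  out <- classify_sentence("no respiratory depression observed on monitoring",
                           lex)
  expect_identical(out$label, "NoMention")
  expect_true(out$filtered)
})

test_that("vote_note applies majority with Affirmed tie priority", {
  expect_identical(vote_note(c("Affirmed", "Affirmed", "Negated"))$label,
                   "Affirmed")
  expect_identical(vote_note(c("Affirmed", "Negated"))$label, "Affirmed")
  expect_identical(vote_note(rep("NoMention", 7))$label, "NoMention")
  expect_identical(vote_note(c("Negated", "Negated", "Affirmed"))$label,
                   "Negated")
  # idempotence under duplication
  set.seed(5)
  for (i in 1:20) {
    labs <- sample(c("Affirmed", "Negated", "NoMention"),
                   sample(1:9, 1), replace = TRUE)
    expect_identical(vote_note(c(labs, labs))$label, vote_note(labs)$label)
  }
})

test_that("phenotype_patient applies the 1-year pre-surgery window", {
  nl <- function(day, label) data.frame(date = day, label = label)
  expect_true(phenotype_patient(nl(-30, "Affirmed")))
  expect_false(phenotype_patient(nl(-30, "Negated")))
  expect_false(phenotype_patient(nl(-400, "Affirmed")))
  expect_true(phenotype_patient(nl(-365, "Affirmed")))
  expect_false(phenotype_patient(nl(10, "Affirmed")))
  expect_true(phenotype_patient(nl(10, "Affirmed"), include_after = TRUE))
  expect_false(phenotype_patient(nl(integer(0), character(0))))
})

test_that("detect_ssri_mentions respects negation and the window", {
  slex <- default_lexicon("ssri")
  note <- function(day, text) data.frame(date = day, text = text)
  expect_true(detect_ssri_mentions(note(-10, "continue sertraline 50 mg daily"),
                                   slex))
  expect_false(detect_ssri_mentions(
    note(-10, "discontinued prozac years ago, denies current use"), slex))
  expect_false(detect_ssri_mentions(
    note(-400, "continue sertraline 50 mg daily"), slex))
  expect_false(detect_ssri_mentions(note(integer(0), character(0)), slex))
})

test_that("classify_notes bulk path equals the per-note path", {
  ex <- small_extract()
  notes <- utils::head(ex$notes, 60)
  bulk <- classify_notes(notes, lex)
  for (i in seq_len(nrow(notes))) {
    single <- annotate_note(notes$text[i], lex)$note
    expect_identical(bulk$label[i], single$label, info = notes$note_id[i])
    expect_equal(bulk$n_affirmed[i], single$n_affirmed)
    expect_equal(bulk$n_negated[i], single$n_negated)
  }
})

test_that("evaluate_nlp computes precision, recall and F1", {
  pred <- data.frame(note_id = 1:5, label = rep("Affirmed", 5))
  expect_equal(evaluate_nlp(pred, pred)$f1, 1.0)
  # tp=9, fp=1, fn=3 by construction
  gold <- data.frame(note_id = 1:20,
                     label = c(rep("Affirmed", 12), rep("Negated", 8)))
  pred <- gold
  pred$label[10:12] <- "Negated"    # 3 false negatives
  pred$label[13] <- "Affirmed"      # 1 false positive
  m <- evaluate_nlp(pred, gold)
  expect_equal(m$tp, 9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / 1.65)
  # degenerate: no predicted positives
  pred$label <- "Negated"
  expect_warning(m <- evaluate_nlp(pred, gold), "undefined")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_error(evaluate_nlp(pred[1:10, ], gold), "mismatch")
})
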