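# Shared fixtures, built in code at test time.

# 30-word micro-lexicon for exhaustive NegEx checks
micro_lexicon <- function() {
  make_lexicon(
    concept = c("depression", "sadness", "anhedonia"),
    exclusion = c("st depression", "respiratory depression"),
    pre_neg = c("no", "denies", "without", "no evidence of"),
    post_neg = c("unlikely", "ruled out"),
    termination = c("but", "however")
  )
}

# vocabulary used to enumerate oracle sentences (single concept inserted)
micro_vocab <- c("patient", "has", "reports", "chronic", "mild", "severe",
                 "pain", "anxiety", "fatigue", "today", "history", "exam",
                 "stable", "improved", "and", "with")

# a small but complete synthetic extract reused by several test files
small_config <- function(n = 200L, seed = 20260909L, ...) {
  generator_config(
    n_patients = n,
    icd_note_overlap = c(note_only = 1912, icd_only = 2315, both = 1751) /
      5978,
    notes_per_patient = c(1L, 3L),
    sentences_per_note = c(3L, 10L),
    seed = seed, ...)
}

.fixture_env <- new.env()

small_extract <- function() {
  if (is.null(.fixture_env$extract)) {
    .fixture_env$extract <- generate_cohort(small_config())
  }
  .fixture_env$extract
}

small_nlp <- function() {
  if (is.null(.fixture_env$nlp)) {
    ex <- small_extract()
    enc <- select_surgeries(ex$encounters)
    .fixture_env$nlp <- run_nlp_stage(ex$notes,
                                      enc[, c("patient_id", "surgery_date")])
  }
  .fixture_env$nlp
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- build_cohort(small_extract(), small_nlp()$patient_flags)
  }
  .fixture_env$cohort
}

# random regression instance for elastic-net tests
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  beta <- stats::rnorm(p)
  y <- drop(X %*% beta) + stats::rnorm(n)
  list(X = X, y = y)
}
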