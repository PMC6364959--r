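Package: painpheno
Title: EHR Phenotyping and Prediction of Postoperative Pain Control Under
    SSRI and Prodrug Opioid Co-Prescription
Version: 0.1.0
Authors@R: person("painpheno", "maintainers", email = "maintainers@painpheno.dev",
    role = c("aut", "cre"))
Description: Tools to study whether selective serotonin reuptake inhibitor
    (SSRI) co-prescription blunts the analgesic effect of prodrug opioids
    (hydrocodone, codeine, tramadol) after surgery. Provides a synthetic
    electronic health record (EHR) generator with gold-standard labels,
    rule-based clinical NLP for depression and SSRI phenotyping (lexicon
    matching, sense-exclusion filters, a NegEx-style negation classifier,
    majority-vote note aggregation), cohort and exposure construction
    (opioid ingredient distillation, oral morphine equivalents, Charlson
    comorbidity category, a 65-feature predictor vector), pain-control
    outcome computation at discharge, 3 weeks and 8 weeks, and an
    elastic-net regression trained by coordinate descent with nested
    cross-validated AUC evaluation plus comparator models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
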