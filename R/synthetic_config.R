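GROUP_LEVELS <- c("SSRI+/Pro+", "SSRI+/Pro-", "SSRI-/Pro+", "SSRI-/Pro-")
TIME_POINTS <- c("discharge", "wk3", "wk8")

#' Configuration for the synthetic EHR generator
#'
#' Defaults reproduce the published cohort structure: a universe of 5978
#' depressed surgical patients of whom 4306 receive a discharge opioid and
#' form the four-group analysis cohort (606 / 1285 / 802 / 1613), a
#' notes-only / ICD-only / both depression-provenance split of
#' 1912 / 2315 / 1751, per-group pre- and postoperative pain parameters
#' matching the reported stratified change-in-pain table, and follow-up
#' retention matching the reported per-time-point sample sizes.
#'
#' @param n_patients Number of depressed patients in the universe.
#' @param group_proportions Length-4 proportions (summing to 1) over
#'   SSRI+/Pro+, SSRI+/Pro-, SSRI-/Pro+, SSRI-/Pro- among patients with a
#'   discharge opioid.
#' @param prop_no_discharge_opioid Fraction of depressed patients with no
#'   discharge opioid prescription (excluded from the 4-group cohort).
#' @param icd_note_overlap Length-3 counts or fractions (note_only,
#'   icd_only, both) controlling depression provenance; counts must sum to
#'   `n_patients`, fractions to 1.
#' @param delta_means,delta_sds 4 x 3 matrices (group x time point) of the
#'   mean and SD of the pain-score change added at discharge, 3 weeks and 8
#'   weeks (NRS units).
#' @param preop_pain_means,preop_pain_sds Per-group preoperative pain mean /
#'   SD on the 0-10 NRS.
#' @param preop_retention,followup_retention Fractions of the cohort with an
#'   observed preoperative score, and named length-3 fractions observed at
#'   each follow-up.
#' @param note_noise Fraction of note sentences drawn from decoy templates
#'   (irrelevant senses such as ECG ST depression).
#' @param notes_per_patient,sentences_per_note Integer ranges (min, max).
#' @param frac_ssri_note_only Among SSRI+ patients, fraction identifiable
#'   only from a note mention (no structured order in the 30-day window).
#' @param frac_combination_opioid Probability a discharge opioid order is a
#'   trade-name combination product (e.g. hydrocodone-acetaminophen).
#' @param mixed_rx_frac Probability of a mixed discharge prescription
#'   containing both a prodrug and a non-prodrug opioid (default 0).
#' @param prop_tolerant Fraction with an outpatient opioid order in the 12
#'   months before admission.
#' @param prop_charlson_3plus Fraction with Charlson score 3+.
#' @param prop_female,race_proportions,prop_married,insurance_proportions
#'   Demographic mix.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Demographic distributions.
#' @param ome_mean,ome_sd Daily oral-morphine-equivalent distribution (mg).
#' @param los_range Inpatient length of stay range in days.
#' @param frac_background Extra non-depressed patients (dropped during
#'   cohort assembly), as a fraction of `n_patients`.
#' @param frac_ineligible Extra ineligible patients (under 18 or in-hospital
#'   death), as a fraction of `n_patients`.
#' @param frac_second_surgery Fraction of patients given a second, later
#'   surgical encounter (the first must be selected).
#' @param seed Integer seed; the whole extract is deterministic given the
#'   config and seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 5978L,
    group_proportions = c(606, 1285, 802, 1613) / 4306,
    prop_no_discharge_opioid = 1672 / 5978,
    icd_note_overlap = c(note_only = 1912, icd_only = 2315, both = 1751) /
      5978,
    delta_means = matrix(c(0.720, 2.774, 0.861,
                           0.161, 1.658, 0.215,
                           0.492, 2.138, 0.798,
                           0.511, 2.126, 0.744),
                         nrow = 4, byrow = TRUE,
                         dimnames = list(GROUP_LEVELS, TIME_POINTS)),
    delta_sds = matrix(c(3.15, 3.22, 3.89,
                         3.29, 3.38, 3.89,
                         3.16, 3.18, 3.45,
                         3.20, 3.17, 3.44),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(GROUP_LEVELS, TIME_POINTS)),
    preop_pain_means = c(2.29, 2.93, 2.22, 2.70),
    preop_pain_sds = c(2.92, 3.22, 2.88, 3.05),
    preop_retention = 3326 / 4306,
    followup_retention = c(discharge = 4189 / 4306, wk3 = 4030 / 4306,
                           wk8 = 2682 / 4306),
    note_noise = 0.2,
    notes_per_patient = c(1L, 5L),
    sentences_per_note = c(5L, 40L),
    frac_ssri_note_only = 700 / 1891,
    frac_combination_opioid = 0.3,
    mixed_rx_frac = 0,
    prop_tolerant = 2470 / 4306,
    prop_charlson_3plus = 531 / 4306,
    prop_female = 3142 / 4306,
    race_proportions = c(white = 2969, black = 134, hispanic = 570,
                         asian = 254, other = 379) / 4306,
    prop_married = 2420 / 4306,
    insurance_proportions = c(private = 1372, medicaid = 502,
                              medicare = 2057, other = 375) / 4306,
    age_mean = 58.34, age_sd = 14.88,
    bmi_mean = 28.47, bmi_sd = 7.39,
    ome_mean = 61.91, ome_sd = 56.96,
    los_range = c(1L, 7L),
    frac_background = 0.03,
    frac_ineligible = 0.005,
    frac_second_surgery = 0.05,
    seed = 20090101L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    group_proportions = group_proportions,
    prop_no_discharge_opioid = prop_no_discharge_opioid,
    icd_note_overlap = icd_note_overlap,
    delta_means = delta_means, delta_sds = delta_sds,
    preop_pain_means = preop_pain_means, preop_pain_sds = preop_pain_sds,
    preop_retention = preop_retention,
    followup_retention = followup_retention,
    note_noise = note_noise,
    notes_per_patient = as.integer(notes_per_patient),
    sentences_per_note = as.integer(sentences_per_note),
    frac_ssri_note_only = frac_ssri_note_only,
    frac_combination_opioid = frac_combination_opioid,
    mixed_rx_frac = mixed_rx_frac,
    prop_tolerant = prop_tolerant,
    prop_charlson_3plus = prop_charlson_3plus,
    prop_female = prop_female,
    race_proportions = race_proportions,
    prop_married = prop_married,
    insurance_proportions = insurance_proportions,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    ome_mean = ome_mean, ome_sd = ome_sd,
    los_range = as.integer(los_range),
    frac_background = frac_background,
    frac_ineligible = frac_ineligible,
    frac_second_surgery = frac_second_surgery,
    seed = as.integer(seed)
  )
  validate_generator_config(structure(cfg, class = "generator_config"))
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop("n_patients must be non-negative")
  if (length(cfg$group_proportions) != 4L ||
      abs(sum(cfg$group_proportions) - 1) > 1e-9) {
    stop("group_proportions must be 4 fractions that sum to 1")
  }
  if (any(cfg$group_proportions < 0)) stop("group_proportions must be >= 0")
  ov <- cfg$icd_note_overlap
  if (length(ov) != 3L || any(ov < 0)) {
    stop("icd_note_overlap must be 3 non-negative counts or fractions")
  }
  if (all(ov <= 1)) {
    if (abs(sum(ov) - 1) > 1e-9) {
      stop("fractional icd_note_overlap must sum to 1")
    }
  } else if (cfg$n_patients > 0L && sum(ov) != cfg$n_patients) {
    stop("count icd_note_overlap must sum to n_patients (",
         sum(ov), " != ", cfg$n_patients, ")")
  }
  if (!all(dim(cfg$delta_means) == c(4L, 3L)) ||
      !all(dim(cfg$delta_sds) == c(4L, 3L))) {
    stop("delta_means and delta_sds must be 4 x 3 (group x time point)")
  }
  if (any(cfg$delta_sds < 0) || any(cfg$preop_pain_sds <= 0)) {
    stop("all SDs must be positive (delta SDs may be zero)")
  }
  ret <- c(cfg$preop_retention, cfg$followup_retention)
  if (any(ret <= 0) || any(ret > 1)) stop("retention fractions must be in (0, 1]")
  if (cfg$note_noise < 0 || cfg$note_noise >= 1) {
    stop("note_noise must be in [0, 1)")
  }
  if (any(cfg$preop_pain_means < 0) || any(cfg$preop_pain_means > 10)) {
    stop("preop pain means must lie on the 0-10 NRS")
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  n_cohort <- round(x$n_patients * (1 - x$prop_no_discharge_opioid))
  cat("<generator_config>\n",
      sprintf("  %d depressed patients (~%d in 4-group cohort), seed %d\n",
              x$n_patients, n_cohort, x$seed),
      sprintf("  group proportions: %s\n",
              paste(sprintf("%.4f", x$group_proportions), collapse = ", ")),
      sep = "")
  invisible(x)
}
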