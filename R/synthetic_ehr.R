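# Synthetic EHR generator. Every random draw happens under the config seed
# (generate_cohort) or an explicitly derived child seed (the standalone
# sub-generators), so identical config + seed gives identical extracts.

DEPRESSION_CODES <- data.frame(
  code = c("296.20", "296.30", "311", "F32.9", "F33.1", "F33.2"),
  system = c("ICD-9", "ICD-9", "ICD-9", "ICD-10", "ICD-10", "ICD-10"),
  stringsAsFactors = FALSE
)

SURGERY_TYPES <- c("orthopedic", "vascular", "general", "cardiothoracic",
                   "neurosurgery", "urology", "gynecology", "ent", "plastic",
                   "other")
SURGERY_WEIGHTS <- c(0.30, 0.10, 0.25, 0.07, 0.05, 0.06, 0.06, 0.04, 0.03,
                     0.04)

# discharge products by class; `combo` marks trade-name combination products
PRODRUG_PRODUCTS <- data.frame(
  name = c("hydrocodone bitartrate", "codeine sulfate", "tramadol hcl",
           "vicodin", "norco", "lortab", "tylenol with codeine no. 3",
           "ultracet"),
  combo = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)
NONPRODRUG_PRODUCTS <- data.frame(
  name = c("morphine sulfate", "ms contin", "oxycodone hcl", "oxycontin",
           "fentanyl transdermal system", "hydromorphone hcl", "methadone hcl",
           "percocet", "endocet"),
  combo = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

# inpatient analgesia agents used to realise the target daily OME
INPATIENT_AGENTS <- data.frame(
  name = c("morphine sulfate", "morphine sulfate", "oxycodone hcl",
           "hydromorphone hcl"),
  route = c("oral", "iv", "oral", "iv"),
  factor = c(1, 3, 1.5, 20),
  stringsAsFactors = FALSE
)

OTHER_MED_POOL <- c(
  "ibuprofen", "naproxen", "celecoxib", "acetaminophen", "gabapentin",
  "pregabalin", "lorazepam", "zolpidem", "quetiapine", "levetiracetam",
  "atorvastatin", "simvastatin", "metoprolol", "lisinopril", "losartan",
  "amlodipine", "furosemide", "warfarin", "aspirin", "insulin glargine",
  "metformin", "omeprazole", "prednisone", "cephalexin", "diphenhydramine",
  "albuterol", "levothyroxine", "cyclobenzaprine", "ondansetron", "bupropion"
)

SSRI_PRODUCTS <- c("sertraline", "zoloft", "fluoxetine", "prozac",
                   "citalopram", "celexa", "escitalopram", "lexapro",
                   "paroxetine", "paxil")

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

empty_extract <- function() {
  structure(list(
    patients = data.frame(patient_id = character(0)),
    encounters = data.frame(patient_id = character(0)),
    diagnoses = data.frame(patient_id = character(0)),
    medications = data.frame(patient_id = character(0)),
    vitals = data.frame(patient_id = character(0)),
    pain = data.frame(patient_id = character(0), date = integer(0),
                      score = numeric(0)),
    notes = data.frame(note_id = character(0), patient_id = character(0),
                       date = integer(0), type = character(0),
                       text = character(0)),
    gold = list(patients = data.frame(patient_id = character(0)),
                notes = data.frame(note_id = character(0)),
                sentences = data.frame(note_id = character(0)))
  ), class = "ehr_extract")
}

# ---- patient-level ground-truth allocation ----------------------------------

# Deterministic allocation of groups and provenance, random everything else.
assign_patients <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0L) return(NULL)

  ov <- cfg$icd_note_overlap
  ov_counts <- if (all(ov <= 1)) largest_remainder(n, ov) else as.integer(ov)
  provenance <- sample(rep(c("note_only", "icd_only", "both"), ov_counts))

  n_noop <- largest_remainder(
    n, c(cfg$prop_no_discharge_opioid, 1 - cfg$prop_no_discharge_opioid))[1]
  n_cohort <- n - n_noop
  in_cohort <- sample(rep(c(TRUE, FALSE), c(n_cohort, n_noop)))
  grp_counts <- largest_remainder(n_cohort, cfg$group_proportions)
  group <- rep("none", n)
  group[in_cohort] <- sample(rep(GROUP_LEVELS, grp_counts))

  ssri <- group %in% GROUP_LEVELS[1:2]
  prodrug <- group %in% GROUP_LEVELS[c(1, 3)]
  ssri_source <- ifelse(
    ssri,
    ifelse(stats::runif(n) < cfg$frac_ssri_note_only, "note_only",
           "structured"),
    "none")

  gi <- match(group, GROUP_LEVELS) # NA for non-cohort
  pre_mean <- ifelse(is.na(gi), 2.62, cfg$preop_pain_means[ifelse(is.na(gi), 1, gi)])
  pre_sd <- ifelse(is.na(gi), 3.07, cfg$preop_pain_sds[ifelse(is.na(gi), 1, gi)])
  p_latent <- clamp_nrs(stats::rnorm(n, pre_mean, pre_sd))

  df <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    role = "universe",
    depressed = TRUE,
    provenance = provenance,
    in_cohort = in_cohort,
    group = group,
    ssri = ssri,
    prodrug = prodrug,
    ssri_source = ssri_source,
    gender = ifelse(stats::runif(n) < cfg$prop_female, "F", "M"),
    race = sample(names(cfg$race_proportions), n, replace = TRUE,
                  prob = cfg$race_proportions),
    marital = ifelse(stats::runif(n) < cfg$prop_married, "married", "single"),
    insurance = sample(names(cfg$insurance_proportions), n, replace = TRUE,
                       prob = cfg$insurance_proportions),
    age = pmin(95L, pmax(18L, as.integer(round(
      stats::rnorm(n, cfg$age_mean, cfg$age_sd))))),
    bmi = round(pmin(60, pmax(15, stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd))), 1),
    surgery_date = sample(400:600, n, replace = TRUE),
    los = sample_range(n, cfg$los_range),
    surgery_type = sample(SURGERY_TYPES, n, replace = TRUE,
                          prob = SURGERY_WEIGHTS),
    second_surgery = stats::runif(n) < cfg$frac_second_surgery,
    tolerant = stats::runif(n) < cfg$prop_tolerant,
    charlson_3plus = stats::runif(n) < cfg$prop_charlson_3plus,
    ome_target = round(pmin(400, 1 + stats::rgamma(
      n, shape = (cfg$ome_mean / cfg$ome_sd)^2,
      scale = cfg$ome_sd^2 / cfg$ome_mean)), 2),
    p_latent = p_latent,
    death_in_hospital = FALSE,
    preop_obs = stats::runif(n) < cfg$preop_retention,
    disch_obs = stats::runif(n) < cfg$followup_retention[["discharge"]],
    wk3_obs = stats::runif(n) < cfg$followup_retention[["wk3"]],
    wk8_obs = stats::runif(n) < cfg$followup_retention[["wk8"]],
    stringsAsFactors = FALSE
  )

  extras <- function(k, role) {
    if (k == 0L) return(NULL)
    idx <- sample(n, k, replace = TRUE)
    e <- df[idx, ]
    e$role <- role
    e$depressed <- FALSE
    e$provenance <- "none"
    e$ssri <- FALSE
    e$prodrug <- role == "background" # background patients do get an opioid
    e$ssri_source <- "none"
    e$group <- "none"
    e$in_cohort <- FALSE
    e$second_surgery <- FALSE
    e
  }
  bg <- extras(round(cfg$frac_background * n), "background")
  inel <- extras(round(cfg$frac_ineligible * n), "ineligible")
  if (!is.null(inel)) {
    minor <- stats::runif(nrow(inel)) < 0.5
    inel$age[minor] <- sample(12:17, sum(minor), replace = TRUE)
    inel$death_in_hospital[!minor] <- TRUE
  }
  out <- rbind(df, bg, inel)
  out$patient_id <- sprintf("P%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# ---- notes ------------------------------------------------------------------

read_note_templates <- function() {
  utils::read.delim(pkg_extdata("note_templates.tsv"),
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Generate clinical notes with gold sentence and note labels
#'
#' Notes are built from fixed sentence templates: affirmed / negated
#' depression statements, decoy sentences instantiating irrelevant senses
#' (ECG ST depression, skull depression fracture, respiratory depression),
#' SSRI mention templates, and neutral filler. Patients whose depression
#' provenance includes notes receive at least one gold-Affirmed note dated
#' within a year before surgery; decoy sentences are NoMention in gold by
#' construction and can never make a note Affirmed.
#'
#' @param patients Patient truth table from the generator (the
#'   `gold$patients` component of an extract).
#' @param config A [generator_config()].
#' @param seed Integer seed for this stage.
#' @return List with `notes` (note_id, patient_id, date, type, text),
#'   `gold_notes` (note_id, patient_id, rel_day, label) and
#'   `gold_sentences` (note_id, position, label).
#' @export
generate_notes <- function(patients, config, seed = child_seed(config$seed, 2L)) {
  set.seed(seed)
  tpl <- read_note_templates()
  pool <- split(tpl$text, tpl$category)
  if (is.null(patients) || nrow(patients) == 0L) {
    return(list(notes = empty_extract()$notes,
                gold_notes = data.frame(note_id = character(0)),
                gold_sentences = data.frame(note_id = character(0))))
  }

  res_notes <- vector("list", nrow(patients))
  res_gold <- vector("list", nrow(patients))
  res_sent <- vector("list", nrow(patients))
  note_counter <- 0L

  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    n_notes <- sample_range(1L, config$notes_per_patient)
    dep_by_note <- p$provenance %in% c("note_only", "both")

    # relative day of each note; note 1 always inside the 1-year window
    rel_days <- c(-sample(1:365, 1L),
                  if (n_notes > 1L) sample(c(-(1:365), 1:90), n_notes - 1L,
                                           replace = TRUE))
    # occasionally an out-of-window affirmed note for ICD-only patients,
    # exercising the lookback rule without changing gold provenance
    old_affirmed <- p$provenance == "icd_only" && stats::runif(1) < 0.15
    if (old_affirmed) rel_days <- c(rel_days, -sample(370:500, 1L))

    ssri_note_idx <- 0L
    if (p$ssri_source == "note_only" ||
        (p$ssri_source == "structured" && stats::runif(1) < 0.5)) {
      ssri_note_idx <- 1L # note 1 is always in-window
    }
    ssri_neg_idx <- if (!p$ssri && stats::runif(1) < 0.1) 1L else 0L

    for (j in seq_along(rel_days)) {
      note_counter <- note_counter + 1L
      note_id <- sprintf("N%07d", note_counter)
      n_sent <- sample_range(1L, config$sentences_per_note)
      is_decoy <- stats::runif(n_sent) < config$note_noise
      cats <- ifelse(is_decoy, "decoy", "filler")

      affirm_here <- (dep_by_note && j == 1L) ||
        (j > length(rel_days) - old_affirmed) # the appended old note
      if (affirm_here) {
        n_aff <- sample(1:3, 1L)
        cats <- c(cats, rep("affirmed", n_aff))
      } else if (stats::runif(1) < 0.3) {
        # negated or no mention at all for patients not depressed by notes
        cats <- c(cats, rep("negated", sample(1:2, 1L)))
      }
      if (j == ssri_note_idx) cats <- c(cats, "ssri_affirmed")
      if (j == ssri_neg_idx && ssri_note_idx == 0L) {
        cats <- c(cats, "ssri_negated")
      }
      cats <- sample(cats)
      sents <- vapply(cats, function(cc) sample(pool[[cc]], 1L), character(1))

      gold_sent <- ifelse(cats == "affirmed", "Affirmed",
                          ifelse(cats == "negated", "Negated", "NoMention"))
      n_a <- sum(gold_sent == "Affirmed"); n_n <- sum(gold_sent == "Negated")
      gold_label <- if (n_a == 0L && n_n == 0L) "NoMention"
                    else if (n_a >= n_n) "Affirmed" else "Negated"

      res_notes[[i]] <- rbind(res_notes[[i]], data.frame(
        note_id = note_id, patient_id = p$patient_id,
        date = p$surgery_date + rel_days[j],
        type = sample(c("History & Physical", "progress",
                        "discharge summary"), 1L),
        text = paste(sents, collapse = " "),
        stringsAsFactors = FALSE))
      res_gold[[i]] <- rbind(res_gold[[i]], data.frame(
        note_id = note_id, patient_id = p$patient_id,
        rel_day = rel_days[j], label = gold_label, stringsAsFactors = FALSE))
      res_sent[[i]] <- rbind(res_sent[[i]], data.frame(
        note_id = note_id, position = seq_along(cats), label = gold_sent,
        stringsAsFactors = FALSE))
    }
  }
  list(notes = do.call(rbind, res_notes),
       gold_notes = do.call(rbind, res_gold),
       gold_sentences = do.call(rbind, res_sent))
}

# ---- pain trajectories ------------------------------------------------------

#' Generate pre- and postoperative pain observations
#'
#' For each cohort patient the recorded preoperative score is a clamped
#' normal draw from the group's preoperative distribution; each
#' postoperative score at time t is `clamp(preop + delta_mean[group, t] +
#' N(0, delta_sd[group, t]), 0, 10)` on the 0-10 numeric rating scale.
#' Clamping truncates the normal tails, so empirical change-in-pain means are
#' biased relative to the configured deltas; [expected_clamped_delta()] gives
#' the truncation-corrected expectation that recovery tests should target.
#' Observations are thinned by the configured retention fractions.
#'
#' @inheritParams generate_notes
#' @return List with `pain` (patient_id, date, score) and `draws`
#'   (patient_id plus the latent preop and drawn postop values, NA when
#'   unobserved).
#' @export
generate_pain_trajectories <- function(patients, config,
                                       seed = child_seed(config$seed, 3L)) {
  set.seed(seed)
  if (is.null(patients) || nrow(patients) == 0L) {
    return(list(pain = empty_extract()$pain,
                draws = data.frame(patient_id = character(0))))
  }
  n <- nrow(patients)
  gi <- match(patients$group, GROUP_LEVELS)
  cohort <- !is.na(gi)
  gi1 <- ifelse(cohort, gi, 1L) # safe index; non-cohort rows masked out below
  pid <- patients$patient_id
  sdate <- patients$surgery_date
  draws <- data.frame(patient_id = pid, preop = NA_real_,
                      discharge = NA_real_, wk3 = NA_real_, wk8 = NA_real_)
  parts <- list()

  # preoperative: the recorded score on the latest observed day is the
  # latent value; some patients get an earlier, superseded observation
  pre_day <- sdate - sample(1:20, n, replace = TRUE)
  has_pre <- patients$preop_obs
  draws$preop[has_pre] <- patients$p_latent[has_pre]
  parts$pre <- data.frame(patient_id = pid[has_pre], date = pre_day[has_pre],
                          score = patients$p_latent[has_pre])
  extra <- has_pre & stats::runif(n) < 0.3
  extra_day <- pre_day - sample(1:25, n, replace = TRUE)
  extra_score <- clamp_nrs(patients$p_latent + stats::rnorm(n, 0, 1))
  parts$pre_extra <- data.frame(patient_id = pid[extra],
                                date = extra_day[extra],
                                score = extra_score[extra])

  # interior inpatient days (exclude the discharge day)
  n_int <- ifelse(cohort, pmax(patients$los - 1L, 0L), 0L)
  ridx <- rep(seq_len(n), n_int)
  if (length(ridx)) {
    parts$inpatient <- data.frame(
      patient_id = pid[ridx],
      date = sdate[ridx] + sequence(n_int),
      score = clamp_nrs(patients$p_latent[ridx] +
                          config$delta_means[gi1[ridx], 1] +
                          stats::rnorm(length(ridx), 0, 1.5)))
  }

  tp_spec <- list(
    discharge = list(obs = cohort & patients$disch_obs,
                     day = sdate + patients$los, col = 1L),
    wk3 = list(obs = cohort & patients$wk3_obs,
               day = sdate + 21L + sample(-3:3, n, replace = TRUE), col = 2L),
    wk8 = list(obs = cohort & patients$wk8_obs,
               day = sdate + 56L + sample(-3:3, n, replace = TRUE), col = 3L))
  for (nm in names(tp_spec)) {
    tp <- tp_spec[[nm]]
    v <- clamp_nrs(patients$p_latent + config$delta_means[gi1, tp$col] +
                     stats::rnorm(n, 0, config$delta_sds[gi1, tp$col]))
    draws[[nm]][tp$obs] <- v[tp$obs]
    parts[[nm]] <- data.frame(patient_id = pid[tp$obs], date = tp$day[tp$obs],
                              score = v[tp$obs])
  }
  pain <- do.call(rbind, parts)
  if (is.null(pain) || nrow(pain) == 0L) pain <- empty_extract()$pain
  rownames(pain) <- NULL
  list(pain = pain, draws = draws)
}

#' Expected recorded pain change under NRS clamping
#'
#' Analytic (quadrature) expectation of `clamp(P + d + eps) - P` where
#' `P = clamp(P0, 0, 10)`, `P0 ~ N(preop_mean, preop_sd^2)` and
#' `eps ~ N(0, delta_sd^2)`, i.e. the mean change in recorded pain that the
#' generator induces once both scores are clamped to the 0-10 scale. Used as
#' the truncation-corrected target in parameter-recovery checks; computed
#' from the closed form for the mean of a clamped normal, independently of
#' the simulation path.
#'
#' @param preop_mean,preop_sd Preoperative latent normal parameters.
#' @param delta_mean,delta_sd Change distribution parameters.
#' @return Expected recorded change (scalar).
#' @export
expected_clamped_delta <- function(preop_mean, preop_sd, delta_mean,
                                   delta_sd) {
  # E[clamp(X)] for X ~ N(mu, sd^2), clamped to [0, 10]
  eclamp <- function(mu, sd) {
    if (sd == 0) return(clamp_nrs(mu))
    a <- (0 - mu) / sd; b <- (10 - mu) / sd
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
      sd * (stats::dnorm(b) - stats::dnorm(a)) +
      10 * (1 - stats::pnorm(b))
  }
  integrand <- function(p0) {
    p <- clamp_nrs(p0)
    post <- vapply(p, function(pp) eclamp(pp + delta_mean, delta_sd),
                   numeric(1))
    (post - p) * stats::dnorm(p0, preop_mean, preop_sd)
  }
  stats::integrate(integrand, preop_mean - 8 * preop_sd,
                   preop_mean + 8 * preop_sd, subdivisions = 500L,
                   rel.tol = 1e-9)$value
}

# ---- structured tables ------------------------------------------------------

generate_structured <- function(patients, config,
                                seed = child_seed(config$seed, 4L)) {
  set.seed(seed)
  n <- nrow(patients)
  pts <- data.frame(
    patient_id = patients$patient_id, gender = patients$gender,
    race = patients$race, marital_status = patients$marital,
    insurance = patients$insurance, bmi = patients$bmi,
    stringsAsFactors = FALSE)

  enc <- data.frame(
    encounter_id = sprintf("E%06d", seq_len(n)),
    patient_id = patients$patient_id,
    surgery_date = patients$surgery_date,
    admit_date = patients$surgery_date,
    discharge_date = patients$surgery_date + patients$los,
    surgery_type = patients$surgery_type,
    age_at_surgery = patients$age,
    death_in_hospital = patients$death_in_hospital,
    stringsAsFactors = FALSE)
  second <- which(patients$second_surgery)
  if (length(second)) {
    e2 <- enc[second, ]
    gap <- sample(60:200, length(second), replace = TRUE)
    e2$encounter_id <- sprintf("E%06dB", second)
    e2$surgery_date <- e2$surgery_date + gap
    e2$admit_date <- e2$surgery_date
    e2$discharge_date <- e2$surgery_date + 2L
    e2$death_in_hospital <- FALSE
    enc <- rbind(enc, e2)
  }

  diag_rows <- vector("list", n)
  med_rows <- vector("list", n)
  vit_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patients[i, ]
    sd0 <- p$surgery_date
    dg <- NULL
    if (p$provenance %in% c("icd_only", "both")) {
      k <- sample(1:2, 1L)
      pick <- DEPRESSION_CODES[sample(nrow(DEPRESSION_CODES), k), ]
      dg <- rbind(dg, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(1:365, k, replace = TRUE),
        code = pick$code, code_system = pick$system, stringsAsFactors = FALSE))
    } else if (p$provenance == "note_only" && stats::runif(1) < 0.1) {
      # out-of-window depression code: must NOT flag the patient
      pick <- DEPRESSION_CODES[sample(nrow(DEPRESSION_CODES), 1L), ]
      dg <- rbind(dg, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(370:500, 1L),
        code = pick$code, code_system = pick$system, stringsAsFactors = FALSE))
    }
    if (p$charlson_3plus) {
      codes <- if (stats::runif(1) < 0.5) {
        data.frame(code = "197.0", code_system = "ICD-9") # metastatic, wt 6
      } else {
        data.frame(code = c("585.9", "250.40"), # renal 2 + compl. diabetes 2
                   code_system = c("ICD-9", "ICD-9"))
      }
      dg <- rbind(dg, data.frame(
        patient_id = p$patient_id,
        date = sd0 - sample(1:365, nrow(codes), replace = TRUE),
        code = codes$code, code_system = codes$code_system,
        stringsAsFactors = FALSE))
    } else {
      u <- stats::runif(1)
      k <- if (u < 0.5) 0L else if (u < 0.85) 1L else 2L
      if (k > 0L) {
        wt1 <- c("496", "428.0", "250.00", "414.01") # weight <= 1 codes
        dg <- rbind(dg, data.frame(
          patient_id = p$patient_id,
          date = sd0 - sample(1:365, k, replace = TRUE),
          code = sample(wt1, k), code_system = "ICD-9",
          stringsAsFactors = FALSE))
      }
    }
    if (stats::runif(1) < 0.3) { # unrelated codes carrying no Charlson weight
      dg <- rbind(dg, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(1:365, 1L),
        code = sample(c("I10", "E78.5", "M54.5"), 1L), code_system = "ICD-10",
        stringsAsFactors = FALSE))
    }
    diag_rows[[i]] <- dg

    md <- NULL
    if (p$group != "none" || p$role == "background") {
      pool <- if (p$prodrug) PRODRUG_PRODUCTS else NONPRODRUG_PRODUCTS
      combo <- stats::runif(1) < config$frac_combination_opioid
      cand <- pool[pool$combo == combo, , drop = FALSE]
      if (!nrow(cand)) cand <- pool
      md <- rbind(md, data.frame(
        patient_id = p$patient_id, date = sd0 + p$los,
        drug_name = cand$name[sample(nrow(cand), 1L)],
        dose_mg = sample(c(5, 10, 15, 20, 30), 1L), route = "oral",
        setting = "discharge", stringsAsFactors = FALSE))
      if (config$mixed_rx_frac > 0 && stats::runif(1) < config$mixed_rx_frac) {
        other <- if (p$prodrug) NONPRODRUG_PRODUCTS else PRODRUG_PRODUCTS
        md <- rbind(md, data.frame(
          patient_id = p$patient_id, date = sd0 + p$los,
          drug_name = other$name[sample(nrow(other), 1L)],
          dose_mg = sample(c(5, 10), 1L), route = "oral",
          setting = "discharge", stringsAsFactors = FALSE))
      }
      # inpatient administrations realising the target daily OME exactly
      ag <- INPATIENT_AGENTS[sample(nrow(INPATIENT_AGENTS), 1L), ]
      md <- rbind(md, data.frame(
        patient_id = p$patient_id, date = sd0 + seq_len(p$los) - 1L,
        drug_name = ag$name, dose_mg = p$ome_target / ag$factor,
        route = ag$route, setting = "inpatient", stringsAsFactors = FALSE))
    }
    if (p$tolerant) {
      k <- sample(1:2, 1L)
      prods <- c(PRODRUG_PRODUCTS$name, NONPRODRUG_PRODUCTS$name)
      md <- rbind(md, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(1:365, k, replace = TRUE),
        drug_name = sample(prods, k), dose_mg = sample(c(5, 10), k, replace = TRUE),
        route = "oral", setting = "outpatient", stringsAsFactors = FALSE))
    } else if (stats::runif(1) < 0.1) {
      # opioid order outside the 12-month window: still opioid-naive
      md <- rbind(md, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(370:500, 1L),
        drug_name = "vicodin", dose_mg = 5, route = "oral",
        setting = "outpatient", stringsAsFactors = FALSE))
    }
    if (p$ssri_source == "structured") {
      md <- rbind(md, data.frame(
        patient_id = p$patient_id, date = sd0 - sample(1:30, 1L),
        drug_name = sample(SSRI_PRODUCTS, 1L), dose_mg = sample(c(10, 20, 50), 1L),
        route = "oral", setting = "outpatient", stringsAsFactors = FALSE))
    }
    k <- sample(0:4, 1L)
    if (k > 0L) {
      md <- rbind(md, data.frame(
        patient_id = p$patient_id,
        date = sd0 - sample(1:30, k, replace = TRUE),
        drug_name = sample(OTHER_MED_POOL, k),
        dose_mg = sample(c(5, 10, 20, 40, 100, 325, 500), k, replace = TRUE),
        route = "oral", setting = "outpatient", stringsAsFactors = FALSE))
    }
    med_rows[[i]] <- md

    kv <- sample(1:3, 1L)
    hr <- round(stats::rnorm(kv, 78, 14))
    hr[stats::runif(kv) < 0.05] <- NA
    vit_rows[[i]] <- data.frame(
      patient_id = p$patient_id, date = sd0 - sample(0:30, kv, replace = TRUE),
      systolic = round(stats::rnorm(kv, 126, 16)),
      diastolic = round(stats::rnorm(kv, 78, 10)),
      temperature = round(stats::rnorm(kv, 36.9, 0.5), 1),
      heart_rate = hr, stringsAsFactors = FALSE)
  }

  list(patients = pts, encounters = enc,
       diagnoses = do.call(rbind, diag_rows),
       medications = do.call(rbind, med_rows),
       vitals = do.call(rbind, vit_rows))
}

# ---- orchestrator -----------------------------------------------------------

#' Generate a complete synthetic EHR extract with gold labels
#'
#' Runs the patient allocator, the note generator, the pain-trajectory
#' generator and the structured-table generator under a single seed and
#' assembles an `ehr_extract`: patients, encounters, diagnoses, medications,
#' vitals, pain observations, notes, and a `gold` component holding the
#' ground truth (per-patient group, depression provenance, SSRI source,
#' latent pain values; per-note and per-sentence labels).
#'
#' @param config A [generator_config()].
#' @return An object of class `ehr_extract`. `n_patients = 0` yields an
#'   empty extract.
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  if (config$n_patients == 0L) return(empty_extract())
  set.seed(config$seed)
  patients <- assign_patients(config)
  nt <- generate_notes(patients, config, seed = child_seed(config$seed, 2L))
  pt <- generate_pain_trajectories(patients, config,
                                   seed = child_seed(config$seed, 3L))
  st <- generate_structured(patients, config,
                            seed = child_seed(config$seed, 4L))
  gold_patients <- patients
  gold_patients$preop_recorded <- pt$draws$preop
  gold_patients$postop_discharge <- pt$draws$discharge
  gold_patients$postop_wk3 <- pt$draws$wk3
  gold_patients$postop_wk8 <- pt$draws$wk8
  structure(list(
    patients = st$patients, encounters = st$encounters,
    diagnoses = st$diagnoses, medications = st$medications,
    vitals = st$vitals, pain = pt$pain, notes = nt$notes,
    gold = list(patients = gold_patients, notes = nt$gold_notes,
                sentences = nt$gold_sentences, config_seed = config$seed)
  ), class = "ehr_extract")
}

#' @export
print.ehr_extract <- function(x, ...) {
  cat("<ehr_extract>\n")
  for (nm in c("patients", "encounters", "diagnoses", "medications",
               "vitals", "pain", "notes")) {
    cat(sprintf("  %-12s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write an extract to delimited files
#'
#' Emits patients.csv, encounters.csv, diagnoses.csv, medications.csv,
#' vitals.csv, pain.csv, notes.jsonl (one JSON record per note) and
#' gold.json under `dir`. Output is byte-deterministic for a given extract.
#'
#' @param extract An `ehr_extract`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_extract <- function(extract, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "encounters", "diagnoses", "medications",
               "vitals", "pain")) {
    utils::write.csv(extract[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  con <- file(file.path(dir, "notes.jsonl"), "w")
  on.exit(close(con))
  if (nrow(extract$notes)) {
    for (i in seq_len(nrow(extract$notes))) {
      writeLines(jsonlite::toJSON(as.list(extract$notes[i, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  jsonlite::write_json(extract$gold, file.path(dir, "gold.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}

#' Read an extract written by [write_extract()]
#'
#' @param dir Directory containing the extract files.
#' @return An `ehr_extract`.
#' @export
read_extract <- function(dir) {
  out <- list()
  for (nm in c("patients", "encounters", "diagnoses", "medications",
               "vitals", "pain")) {
    out[[nm]] <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                 stringsAsFactors = FALSE)
  }
  lines <- readLines(file.path(dir, "notes.jsonl"))
  out$notes <- if (length(lines)) {
    do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  } else empty_extract()$notes
  gold <- jsonlite::read_json(file.path(dir, "gold.json"),
                              simplifyVector = TRUE)
  out$gold <- gold
  structure(out, class = "ehr_extract")
}
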