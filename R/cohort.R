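# Cohort and exposure construction from structured tables + NLP flags.

PRODRUG_INGREDIENTS <- c("hydrocodone", "codeine", "tramadol")
NONPRODRUG_INGREDIENTS <- c("morphine", "fentanyl", "hydromorphone",
                            "oxycodone", "methadone")

#' Load the drug name to ingredient/class map
#'
#' An RxNorm-style static table resolving trade names and combination
#' products (e.g. "vicodin" -> hydrocodone + acetaminophen) to ingredient
#' lists, with a therapeutic class per product.
#'
#' @param path TSV with columns name, ingredients (semicolon-separated),
#'   class; defaults to the shipped table.
#' @return data.frame with a list-column `ingredients`.
#' @export
read_drug_map <- function(path = pkg_extdata("drug_map.tsv")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  m$name <- tolower(m$name)
  m$ingredients <- strsplit(m$ingredients, ";", fixed = TRUE)
  m
}

#' Load the oral morphine equivalent conversion table
#'
#' @param path TSV with columns ingredient, route, factor.
#' @return data.frame.
#' @export
read_ome_table <- function(path = pkg_extdata("ome_factors.tsv")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Resolve medication order names to ingredient lists
#'
#' Unknown names pass through unchanged (as their own "ingredient") with a
#' warning, so downstream classification degrades gracefully.
#'
#' @param drug_names Character vector of product names.
#' @param map Drug map from [read_drug_map()].
#' @return A list of ingredient character vectors, one per input name.
#' @export
distill_ingredients <- function(drug_names, map = read_drug_map()) {
  idx <- match(tolower(drug_names), map$name)
  unknown <- unique(drug_names[is.na(idx)])
  if (length(unknown)) {
    warning("unknown drug name(s) passed through: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  out <- map$ingredients[idx]
  out[is.na(idx)] <- as.list(tolower(drug_names[is.na(idx)]))
  out
}

#' Classify an opioid ingredient as prodrug / non-prodrug / not an opioid
#'
#' Prodrug opioids require CYP-2D6 demethylation to their active form:
#' hydrocodone, codeine, tramadol. Direct-acting (non-prodrug) opioids:
#' morphine, fentanyl, hydromorphone, oxycodone, methadone. Anything else is
#' `not_opioid`.
#'
#' @param ingredient Character vector of ingredient names (any case).
#' @return Character vector in {"prodrug", "non_prodrug", "not_opioid"}.
#' @export
classify_opioid <- function(ingredient) {
  x <- tolower(ingredient)
  ifelse(x %in% PRODRUG_INGREDIENTS, "prodrug",
         ifelse(x %in% NONPRODRUG_INGREDIENTS, "non_prodrug", "not_opioid"))
}

#' Select eligible surgical encounters
#'
#' Keeps one encounter per patient (the earliest surgery), excludes patients
#' younger than 18 at surgery and in-hospital deaths. Concurrent procedures
#' on the same encounter are unaffected.
#'
#' @param encounters data.frame with patient_id, surgery_date,
#'   age_at_surgery, death_in_hospital (plus any other columns, retained).
#' @return Filtered one-row-per-patient data.frame.
#' @export
select_surgeries <- function(encounters) {
  if (nrow(encounters) == 0L) return(encounters)
  e <- encounters[order(encounters$patient_id, encounters$surgery_date), ]
  e <- e[!duplicated(e$patient_id), ]
  e <- e[e$age_at_surgery >= 18L & !e$death_in_hospital, ]
  rownames(e) <- NULL
  e
}

#' Average daily oral morphine equivalent for an inpatient stay
#'
#' Sums dose x conversion factor over administrations and divides by the
#' number of inpatient days. Administrations whose (ingredient, route) has
#' no conversion factor are skipped with a warning.
#'
#' @param administrations data.frame with ingredient, dose_mg, route.
#' @param inpatient_days Length of stay in days (>= 1).
#' @param conversion Conversion table from [read_ome_table()].
#' @return Daily OME in mg-morphine/day (0 for no administrations).
#' @export
compute_daily_ome <- function(administrations, inpatient_days,
                              conversion = read_ome_table()) {
  stopifnot(inpatient_days >= 1)
  if (is.null(administrations) || nrow(administrations) == 0L) return(0)
  key <- paste(tolower(administrations$ingredient),
               tolower(administrations$route))
  fac <- conversion$factor[match(key, paste(conversion$ingredient,
                                            conversion$route))]
  if (anyNA(fac)) {
    warning("no OME conversion factor for: ",
            paste(unique(key[is.na(fac)]), collapse = ", "),
            " (administrations skipped)")
  }
  sum(administrations$dose_mg * fac, na.rm = TRUE) / inpatient_days
}

#' Opioid-naive flag from outpatient order history
#'
#' Naive means no outpatient opioid order in the 365 days before admission
#' (window [-365, -1] in days relative to surgery).
#'
#' @param order_days Integer days (relative to surgery) of outpatient orders
#'   containing at least one opioid ingredient.
#' @param window_days Lookback length (default 365).
#' @return TRUE when naive.
#' @export
flag_opioid_naive <- function(order_days, window_days = 365L) {
  !any(order_days >= -window_days & order_days <= -1L)
}

#' Load the ICD to Charlson condition map
#'
#' @param path TSV with condition, family, weight and semicolon-separated
#'   ICD-9 / ICD-10 code prefixes.
#' @return data.frame.
#' @export
read_charlson_map <- function(path = pkg_extdata("charlson_icd.tsv")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

strip_code <- function(code) gsub(".", "", toupper(code), fixed = TRUE)

#' Charlson comorbidity score and category from diagnosis codes
#'
#' Matches codes (ICD-9 or ICD-10, dots ignored) against condition prefixes,
#' counts each condition family once at its highest triggered weight
#' (complicated diabetes supersedes uncomplicated, metastatic disease
#' supersedes localised malignancy, severe liver disease supersedes mild),
#' and bins the weighted sum into the categories 0-2 and 3+.
#'
#' @param codes Character vector of diagnosis codes (already restricted to
#'   the 12-month pre-surgery window by the caller).
#' @param map Charlson map from [read_charlson_map()].
#' @return List with `score` (integer) and `category` ("0-2" or "3+").
#' @export
compute_charlson_category <- function(codes, map = read_charlson_map()) {
  score <- 0L
  if (length(codes)) {
    sc <- strip_code(codes)
    fam_weight <- integer(0)
    for (i in seq_len(nrow(map))) {
      prefixes <- strip_code(strsplit(paste(map$icd9_prefix[i],
                                            map$icd10_prefix[i], sep = ";"),
                                      ";", fixed = TRUE)[[1]])
      prefixes <- prefixes[nzchar(prefixes)]
      hit <- any(vapply(prefixes, function(p) any(startsWith(sc, p)),
                        logical(1)))
      if (hit) {
        fam <- map$family[i]
        fam_weight[fam] <- max(fam_weight[fam], map$weight[i], na.rm = TRUE)
      }
    }
    score <- as.integer(sum(fam_weight))
  }
  list(score = score, category = if (score >= 3L) "3+" else "0-2")
}

# classify one discharge prescription (list of ingredient vectors with doses)
# into prodrug / non_prodrug / none, applying the mixed-prescription policy
classify_discharge <- function(ingredients, dose_mg, conversion,
                               mixed_policy = "ome") {
  if (length(ingredients) == 0L) return("none")
  cls <- lapply(ingredients, classify_opioid)
  has_pro <- vapply(cls, function(x) any(x == "prodrug"), logical(1))
  has_non <- vapply(cls, function(x) any(x == "non_prodrug"), logical(1))
  if (!any(has_pro) && !any(has_non)) return("none")
  if (any(has_pro) && !any(has_non)) return("prodrug")
  if (any(has_non) && !any(has_pro)) return("non_prodrug")
  # mixed: decide by total OME of each class (oral factors), tie -> non_prodrug
  if (mixed_policy == "prodrug") return("prodrug")
  if (mixed_policy == "non_prodrug") return("non_prodrug")
  ome <- c(prodrug = 0, non_prodrug = 0)
  for (k in seq_along(ingredients)) {
    for (ing in ingredients[[k]]) {
      cl <- classify_opioid(ing)
      if (cl == "not_opioid") next
      fac <- conversion$factor[match(paste(ing, "oral"),
                                     paste(conversion$ingredient,
                                           conversion$route))]
      if (is.na(fac)) fac <- 1
      ome[cl] <- ome[cl] + dose_mg[k] * fac
    }
  }
  if (ome["prodrug"] > ome["non_prodrug"]) "prodrug" else "non_prodrug"
}

#' Depression identification overlap between notes and ICD codes
#'
#' Reconciles the two identification routes over all eligible patients (not
#' just the final opioid cohort): NLP-only ("an additional N depressed
#' patients"), ICD-only, and both.
#'
#' @param extract An `ehr_extract`.
#' @param nlp_flags Patient flags from [run_nlp_stage()].
#' @param window_days Depression lookback (365).
#' @return Named integer vector: note_only, icd_only, both, total.
#' @export
depression_provenance_counts <- function(extract, nlp_flags,
                                         window_days = 365L) {
  enc <- select_surgeries(extract$encounters)
  sdate <- stats::setNames(enc$surgery_date, enc$patient_id)
  d <- extract$diagnoses
  d <- d[d$patient_id %in% enc$patient_id, , drop = FALSE]
  rel <- d$date - sdate[d$patient_id]
  icd_pat <- unique(d$patient_id[rel >= -window_days & rel <= -1L &
                                   grepl("^(296\\.?[23]|311|F3[23])", d$code)])
  nlp_pat <- nlp_flags$patient_id[nlp_flags$nlp_depressed]
  c(note_only = length(setdiff(nlp_pat, icd_pat)),
    icd_only = length(setdiff(icd_pat, nlp_pat)),
    both = length(intersect(nlp_pat, icd_pat)),
    total = length(union(nlp_pat, icd_pat)))
}

#' Assemble the four-group analysis cohort
#'
#' Applies eligibility (adult, survived, first surgery), reconciles
#' depression provenance from ICD codes (1-year window), NLP note
#' phenotyping and the antidepressant-plus-symptom rule, determines SSRI
#' exposure (structured order in the 30 days before surgery, or a
#' non-negated note mention), classifies the discharge opioid prescription
#' into prodrug / non-prodrug, and computes daily OME, the opioid-naive
#' flag, Charlson category, vitals deviations and preoperative pain.
#' Patients who are not depressed or have no discharge opioid are dropped
#' and tallied in the attrition log.
#'
#' @param extract An `ehr_extract` (or the equivalent list of tables).
#' @param nlp_flags data.frame with patient_id, nlp_depressed, ssri_note
#'   (from [phenotype_patient()] / [detect_ssri_mentions()], see
#'   [run_nlp_stage()]).
#' @param drug_map,ome_table,charlson_map Configuration tables; defaults are
#'   the shipped ones.
#' @param mixed_policy How to classify a discharge prescription containing
#'   both opioid classes: `"ome"` (larger total OME wins, tie to
#'   non-prodrug), `"prodrug"`, or `"non_prodrug"`.
#' @param ssri_window_days Structured SSRI lookback (default 30).
#' @param depression_window_days Depression lookback (default 365).
#' @return List with `cohort` (one row per retained patient) and
#'   `attrition` (stage, reason, n).
#' @export
build_cohort <- function(extract, nlp_flags,
                         drug_map = read_drug_map(),
                         ome_table = read_ome_table(),
                         charlson_map = read_charlson_map(),
                         mixed_policy = c("ome", "prodrug", "non_prodrug"),
                         ssri_window_days = 30L,
                         depression_window_days = 365L) {
  mixed_policy <- match.arg(mixed_policy)
  attrition <- data.frame(stage = character(0), reason = character(0),
                          n = integer(0))
  log_attr <- function(stage, reason, n) {
    rbind(attrition, data.frame(stage = stage, reason = reason,
                                n = as.integer(n)))
  }

  n_enc_pat <- length(unique(extract$encounters$patient_id))
  enc <- select_surgeries(extract$encounters)
  attrition <- log_attr("eligibility", "underage_or_death_or_duplicate",
                        n_enc_pat - nrow(enc))
  if (nrow(enc) == 0L) {
    return(list(cohort = data.frame(), attrition = attrition))
  }

  sdate <- stats::setNames(enc$surgery_date, enc$patient_id)
  ddate <- stats::setNames(enc$discharge_date, enc$patient_id)

  meds <- extract$medications
  meds <- meds[meds$patient_id %in% enc$patient_id, , drop = FALSE]
  if (nrow(meds)) {
    meds$rel_day <- meds$date - sdate[meds$patient_id]
    meds$ingredients <- distill_ingredients(meds$drug_name, drug_map)
    meds$class <- drug_map$class[match(tolower(meds$drug_name), drug_map$name)]
    meds$class[is.na(meds$class)] <- "unknown"
    meds$any_opioid <- vapply(meds$ingredients, function(x) {
      any(classify_opioid(x) != "not_opioid")
    }, logical(1))
  } else {
    meds$rel_day <- integer(0)
  }

  diag <- extract$diagnoses
  diag <- diag[diag$patient_id %in% enc$patient_id, , drop = FALSE]
  if (nrow(diag)) diag$rel_day <- diag$date - sdate[diag$patient_id]

  vit <- extract$vitals
  vit <- vit[vit$patient_id %in% enc$patient_id, , drop = FALSE]
  if (nrow(vit)) vit$rel_day <- vit$date - sdate[vit$patient_id]

  pain <- extract$pain
  if (nrow(pain)) {
    pain <- pain[pain$patient_id %in% enc$patient_id, , drop = FALSE]
  }

  med_by_pat <- split(seq_len(nrow(meds)), meds$patient_id)
  diag_by_pat <- split(seq_len(nrow(diag)), diag$patient_id)
  vit_by_pat <- split(seq_len(nrow(vit)), vit$patient_id)
  pain_by_pat <- split(seq_len(nrow(pain)), pain$patient_id)

  nlp_dep <- stats::setNames(nlp_flags$nlp_depressed, nlp_flags$patient_id)
  nlp_ssri <- stats::setNames(nlp_flags$ssri_note, nlp_flags$patient_id)

  rows <- vector("list", nrow(enc))
  n_not_depressed <- 0L
  n_no_opioid <- 0L
  for (i in seq_len(nrow(enc))) {
    pid <- enc$patient_id[i]
    m <- meds[med_by_pat[[pid]], , drop = FALSE]
    d <- diag[diag_by_pat[[pid]], , drop = FALSE]

    dep_icd <- FALSE
    if (nrow(d)) {
      in_win <- d$rel_day >= -depression_window_days & d$rel_day <= -1L
      dep_icd <- any(in_win & grepl("^(296\\.?[23]|311|F3[23])", d$code))
    }
    dep_nlp <- isTRUE(nlp_dep[pid])
    antidep_1yr <- nrow(m) > 0L &&
      any(m$class %in% c("ssri", "antidepressant_other") &
            m$rel_day >= -depression_window_days & m$rel_day <= -1L)
    dep_med_symptom <- antidep_1yr && dep_nlp # symptom evidence comes from notes
    src <- c("note", "icd", "medication")[c(dep_nlp, dep_icd, dep_med_symptom)]
    if (!length(src)) {
      n_not_depressed <- n_not_depressed + 1L
      next
    }

    ssri_structured <- nrow(m) > 0L &&
      any(m$class == "ssri" & m$setting == "outpatient" &
            m$rel_day >= -ssri_window_days & m$rel_day <= -1L)
    ssri_flag <- ssri_structured || isTRUE(nlp_ssri[pid])

    disch <- m[m$setting == "discharge", , drop = FALSE]
    opioid_cls <- classify_discharge(disch$ingredients, disch$dose_mg,
                                     ome_table, mixed_policy)
    if (opioid_cls == "none") {
      n_no_opioid <- n_no_opioid + 1L
      next
    }

    group <- paste0(if (ssri_flag) "SSRI+" else "SSRI-", "/",
                    if (opioid_cls == "prodrug") "Pro+" else "Pro-")

    inp <- m[m$setting == "inpatient", , drop = FALSE]
    inpatient_days <- max(1L, ddate[pid] - sdate[pid])
    daily_ome <- if (nrow(inp)) {
      adm <- do.call(rbind, lapply(seq_len(nrow(inp)), function(k) {
        data.frame(ingredient = inp$ingredients[[k]],
                   dose_mg = inp$dose_mg[k], route = inp$route[k])
      }))
      adm <- adm[classify_opioid(adm$ingredient) != "not_opioid", ,
                 drop = FALSE]
      compute_daily_ome(adm, inpatient_days, ome_table)
    } else 0

    opioid_days <- if (nrow(m)) {
      m$rel_day[m$setting == "outpatient" & m$any_opioid]
    } else integer(0)
    naive <- flag_opioid_naive(opioid_days)

    chy <- if (nrow(d)) {
      d$code[d$rel_day >= -365L & d$rel_day <= -1L]
    } else character(0)
    charlson <- compute_charlson_category(chy, charlson_map)

    v <- vit[vit_by_pat[[pid]], , drop = FALSE]
    v <- v[v$rel_day >= -30L & v$rel_day <= 0L, , drop = FALSE]
    sbp_dev <- if (nrow(v)) mean(v$systolic, na.rm = TRUE) - 120 else NA_real_
    dbp_dev <- if (nrow(v)) mean(v$diastolic, na.rm = TRUE) - 80 else NA_real_
    temp_dev <- if (nrow(v)) mean(v$temperature, na.rm = TRUE) - 37 else NA_real_
    hr <- if (nrow(v)) mean(v$heart_rate, na.rm = TRUE) else NaN
    hr_cat <- if (!is.finite(hr)) "unknown"
              else if (hr >= 60 && hr <= 100) "normal" else "abnormal"

    pp <- pain[pain_by_pat[[pid]], , drop = FALSE]
    preop <- extract_preop_pain(pp, sdate[pid])

    med_classes <- unique(m$class[m$rel_day >= -30L & m$rel_day <= -1L &
                                    m$setting == "outpatient"])

    pt <- extract$patients[extract$patients$patient_id == pid, , drop = FALSE]
    rows[[i]] <- data.frame(
      patient_id = pid,
      surgery_date = sdate[[pid]],
      discharge_date = ddate[[pid]],
      group = group,
      ssri = ssri_flag,
      prodrug = opioid_cls == "prodrug",
      depression_source = paste(src, collapse = ","),
      opioid_naive = naive,
      daily_ome = daily_ome,
      charlson_score = charlson$score,
      charlson_category = charlson$category,
      age = enc$age_at_surgery[i],
      gender = pt$gender[1],
      race = pt$race[1],
      marital_status = pt$marital_status[1],
      insurance = pt$insurance[1],
      bmi = pt$bmi[1],
      surgery_type = enc$surgery_type[i],
      sbp_dev = sbp_dev, dbp_dev = dbp_dev, temp_dev = temp_dev,
      hr_category = hr_cat,
      preop_pain = preop,
      med_classes = paste(sort(med_classes), collapse = ","),
      stringsAsFactors = FALSE)
  }
  attrition <- log_attr("depression", "not_depressed", n_not_depressed)
  attrition <- log_attr("exposure", "no_discharge_opioid", n_no_opioid)
  cohort <- do.call(rbind, rows)
  if (is.null(cohort)) cohort <- data.frame()
  rownames(cohort) <- NULL
  list(cohort = cohort, attrition = attrition)
}
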