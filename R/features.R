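# The 65-feature predictor vector. The manifest file is the single source
# of truth for feature names and order; length is validated at load time.

#' Load the feature manifest
#'
#' @param path TSV with columns name, kind, source.
#' @param expected_length Required number of features (65).
#' @return data.frame.
#' @export
read_feature_manifest <- function(path = pkg_extdata("feature_manifest.tsv"),
                                  expected_length = 65L) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(m) != expected_length) {
    stop("feature manifest must list exactly ", expected_length,
         " features, found ", nrow(m))
  }
  if (anyDuplicated(m$name)) stop("duplicate feature names in manifest")
  m
}

#' Build the manifest-ordered feature matrix for a cohort
#'
#' One row per cohort record, one column per manifest feature: one-hot
#' demographics, age and BMI, Charlson 3+ indicator, vitals deviations from
#' the 120/80 normals and heart-rate category, preoperative pain with its
#' missingness indicator, opioid tolerance, daily OME, surgery-type and
#' group indicators, and binary 30-day therapeutic-class medication
#' indicators. Continuous features may contain NA here; imputation happens
#' per training fold (see [impute_standardize()]), never globally.
#'
#' @param cohort Cohort data.frame from [build_cohort()].
#' @param manifest Feature manifest from [read_feature_manifest()].
#' @return Numeric matrix n x 65 with manifest column names.
#' @export
build_feature_matrix <- function(cohort, manifest = read_feature_manifest()) {
  n <- nrow(cohort)
  X <- matrix(0, n, nrow(manifest), dimnames = list(NULL, manifest$name))
  set <- function(col, val) X[, col] <<- val

  set("gender_male", as.numeric(cohort$gender == "M"))
  for (r in c("white", "black", "hispanic", "asian", "other")) {
    set(paste0("race_", r), as.numeric(cohort$race == r))
  }
  set("marital_married", as.numeric(cohort$marital_status == "married"))
  for (ins in c("private", "medicaid", "medicare", "other")) {
    set(paste0("insurance_", ins), as.numeric(cohort$insurance == ins))
  }
  set("age", cohort$age)
  set("bmi", cohort$bmi)
  set("charlson_3plus", as.numeric(cohort$charlson_category == "3+"))
  set("sbp_deviation", cohort$sbp_dev)
  set("dbp_deviation", cohort$dbp_dev)
  set("temp_deviation", cohort$temp_dev)
  set("hr_normal", as.numeric(cohort$hr_category == "normal"))
  set("hr_abnormal", as.numeric(cohort$hr_category == "abnormal"))
  set("hr_unknown", as.numeric(cohort$hr_category == "unknown"))
  set("preop_pain", cohort$preop_pain)
  set("preop_pain_missing", as.numeric(is.na(cohort$preop_pain)))
  set("opioid_tolerant", as.numeric(!cohort$opioid_naive))
  set("daily_ome", cohort$daily_ome)
  for (s in c("orthopedic", "vascular", "general", "cardiothoracic",
              "neurosurgery", "urology", "gynecology", "ent", "plastic",
              "other")) {
    set(paste0("surgery_", s), as.numeric(cohort$surgery_type == s))
  }
  grp <- c("group_ssri_pro" = "SSRI+/Pro+", "group_ssri_nonpro" = "SSRI+/Pro-",
           "group_nossri_pro" = "SSRI-/Pro+",
           "group_nossri_nonpro" = "SSRI-/Pro-")
  for (g in names(grp)) set(g, as.numeric(cohort$group == grp[[g]]))

  med_cols <- manifest$name[startsWith(manifest$name, "med_")]
  classes <- strsplit(cohort$med_classes, ",", fixed = TRUE)
  for (mc in med_cols) {
    cl <- sub("^med_", "", mc)
    set(mc, vapply(classes, function(x) as.numeric(cl %in% x), numeric(1)))
  }
  X
}

#' Impute and standardize using training-fold statistics only
#'
#' Continuous NA entries are replaced by the training-fold column mean
#' (computed over non-missing training values); every column is then
#' centred and scaled by training mean / SD (constant columns are left
#' centred with unit divisor). Test data, when supplied, is transformed
#' with the training statistics, never its own -- the leakage guard that
#' nested cross-validation relies on.
#'
#' @param train Numeric matrix.
#' @param test Optional numeric matrix with identical columns.
#' @return List with `train`, `test` (or NULL), `center`, `scale`,
#'   `impute_means`.
#' @export
impute_standardize <- function(train, test = NULL) {
  imp <- colMeans(train, na.rm = TRUE)
  imp[is.nan(imp)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- imp[j]
    }
    m
  }
  train <- fill(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  std <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = std(train),
       test = if (!is.null(test)) std(fill(test)) else NULL,
       center = ctr, scale = scl, impute_means = imp)
}
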