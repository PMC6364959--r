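# Pain-control outcomes: preop / discharge / follow-up extraction and the
# change statistic delta_t = postop_t - preop.

#' Preoperative pain score
#'
#' Mean of the scores recorded on the latest pre-surgery day that has any
#' observation within the 30-day lookback window; NA when none.
#'
#' @param pain data.frame with `date` and `score` for one patient.
#' @param surgery_date Surgery day (same scale as `date`).
#' @param window_days Lookback (default 30).
#' @return Numeric scalar or NA.
#' @export
extract_preop_pain <- function(pain, surgery_date, window_days = 30L) {
  if (is.null(pain) || nrow(pain) == 0L) return(NA_real_)
  rel <- pain$date - surgery_date
  w <- rel >= -window_days & rel <= -1L
  if (!any(w)) return(NA_real_)
  latest <- max(rel[w])
  mean(pain$score[rel == latest])
}

#' Discharge pain score
#'
#' Mean of all scores recorded on the last inpatient day.
#'
#' @param pain data.frame with `date` and `score` for one patient.
#' @param discharge_date The last inpatient day.
#' @return Numeric scalar or NA when no score that day.
#' @export
extract_discharge_pain <- function(pain, discharge_date) {
  if (is.null(pain) || nrow(pain) == 0L) return(NA_real_)
  s <- pain$score[pain$date == discharge_date]
  if (!length(s)) return(NA_real_)
  mean(s)
}

#' Follow-up pain score at 3 or 8 weeks
#'
#' Searches the +/- 7 day window around the target day; among days with
#' observations, uses the day closest to the target (ties to the earlier
#' day) and returns the mean of that day's scores.
#'
#' @param pain data.frame with `date` and `score` for one patient.
#' @param surgery_date Surgery day.
#' @param target_day 21 (3 weeks) or 56 (8 weeks) days after surgery.
#' @param tolerance_days Window half-width (default 7).
#' @return Numeric scalar or NA.
#' @export
extract_followup_pain <- function(pain, surgery_date, target_day,
                                  tolerance_days = 7L) {
  if (is.null(pain) || nrow(pain) == 0L) return(NA_real_)
  rel <- pain$date - surgery_date
  w <- rel >= target_day - tolerance_days & rel <= target_day + tolerance_days
  if (!any(w)) return(NA_real_)
  days <- sort(unique(rel[w]))
  dist <- abs(days - target_day)
  best <- days[dist == min(dist)][1] # earlier day wins ties
  mean(pain$score[rel == best])
}

#' Pain-control statistic
#'
#' `delta = postop - preop`; smaller is better pain control. `worsened` is
#' `delta > 0` (a tie counts as not worsened).
#'
#' @param preop,postop Numeric scalars (NA propagates).
#' @return List with `delta` and `worsened`.
#' @export
compute_delta <- function(preop, postop) {
  delta <- postop - preop
  list(delta = delta, worsened = !is.na(delta) & delta > 0)
}

#' Per-patient outcomes table for a cohort
#'
#' @param cohort Cohort data.frame from [build_cohort()].
#' @param pain Full pain observation table (patient_id, date, score).
#' @return data.frame: patient_id, group, preop_pain, postop at the three
#'   time points, delta_* and worsened_* columns (NA where unobserved).
#' @export
compute_outcomes <- function(cohort, pain) {
  idx <- split(seq_len(nrow(pain)), pain$patient_id)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    pp <- pain[idx[[pid]], , drop = FALSE]
    pre <- cohort$preop_pain[i]
    post <- c(
      discharge = extract_discharge_pain(pp, cohort$discharge_date[i]),
      wk3 = extract_followup_pain(pp, cohort$surgery_date[i], 21L),
      wk8 = extract_followup_pain(pp, cohort$surgery_date[i], 56L))
    d <- lapply(post, compute_delta, preop = pre)
    data.frame(
      patient_id = pid, group = cohort$group[i], preop_pain = pre,
      postop_discharge = post[["discharge"]], postop_wk3 = post[["wk3"]],
      postop_wk8 = post[["wk8"]],
      delta_discharge = d$discharge$delta, delta_wk3 = d$wk3$delta,
      delta_wk8 = d$wk8$delta,
      worsened_discharge = ifelse(is.na(d$discharge$delta), NA,
                                  d$discharge$worsened),
      worsened_wk3 = ifelse(is.na(d$wk3$delta), NA, d$wk3$worsened),
      worsened_wk8 = ifelse(is.na(d$wk8$delta), NA, d$wk8$worsened),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare prodrug arms within an SSRI stratum
#'
#' Two-sample comparison of the change-in-pain statistic between Prodrug+
#' and Prodrug- within one SSRI stratum at one time point, with per-arm
#' descriptive statistics and a Welch (default) or pooled t test.
#'
#' @param outcomes Outcome table from [compute_outcomes()].
#' @param stratum `"SSRI+"` or `"SSRI-"`.
#' @param time_point `"discharge"`, `"wk3"` or `"wk8"`.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return List of class `group_comparison`: stratum, time_point, per-arm n
#'   / mean / sd / min / max, t statistic, p_value.
#' @export
compare_groups <- function(outcomes, stratum = c("SSRI+", "SSRI-"),
                           time_point = c("discharge", "wk3", "wk8"),
                           var_equal = FALSE) {
  stratum <- match.arg(stratum)
  time_point <- match.arg(time_point)
  col <- paste0("delta_", time_point)
  pro <- outcomes[[col]][outcomes$group == paste0(stratum, "/Pro+")]
  non <- outcomes[[col]][outcomes$group == paste0(stratum, "/Pro-")]
  pro <- pro[!is.na(pro)]
  non <- non[!is.na(non)]
  if (length(pro) < 2L || length(non) < 2L) {
    stop("insufficient data for comparison: n = ", length(pro), " vs ",
         length(non))
  }
  tt <- stats::t.test(pro, non, var.equal = var_equal)
  structure(list(
    stratum = stratum, time_point = time_point,
    n = c(pro = length(pro), non = length(non)),
    mean = c(pro = mean(pro), non = mean(non)),
    sd = c(pro = stats::sd(pro), non = stats::sd(non)),
    min = c(pro = min(pro), non = min(non)),
    max = c(pro = max(pro), non = max(non)),
    statistic = unname(tt$statistic), p_value = tt$p.value),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s, %s: Pro+ %0.3f (%0.2f) n=%d vs Pro- %0.3f (%0.2f) n=%d, p=%0.4g\n",
              x$stratum, x$time_point, x$mean[["pro"]], x$sd[["pro"]],
              x$n[["pro"]], x$mean[["non"]], x$sd[["non"]], x$n[["non"]],
              x$p_value))
  invisible(x)
}

#' Stratified change-in-pain table (mean change by SSRI and prodrug arm)
#'
#' @param outcomes Outcome table from [compute_outcomes()].
#' @param var_equal Pooled t test instead of Welch.
#' @return data.frame with one row per time point x stratum: per-arm n,
#'   mean, sd, min, max, p_value.
#' @export
delta_report <- function(outcomes, var_equal = FALSE) {
  rows <- list()
  for (tp in c("discharge", "wk3", "wk8")) {
    for (st in c("SSRI+", "SSRI-")) {
      gc <- compare_groups(outcomes, st, tp, var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        time_point = tp, stratum = st,
        n_pro = gc$n[["pro"]], mean_pro = gc$mean[["pro"]],
        sd_pro = gc$sd[["pro"]], min_pro = gc$min[["pro"]],
        max_pro = gc$max[["pro"]],
        n_non = gc$n[["non"]], mean_non = gc$mean[["non"]],
        sd_non = gc$sd[["non"]], min_non = gc$min[["non"]],
        max_non = gc$max[["non"]],
        p_value = gc$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
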