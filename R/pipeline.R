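# Stage orchestration: simulate -> phenotype -> cohort -> outcomes ->
# predict, with per-stage outputs, an attrition/provenance trail and
# paper-style report rendering.

#' Run the NLP phenotyping stage over an extract's notes
#'
#' Classifies every note with the depression lexicon (and, separately, the
#' SSRI lexicon) and derives the two patient-level flags used by cohort
#' assembly: `nlp_depressed` (an Affirmed depression note within the 1-year
#' pre-surgery window) and `ssri_note` (a non-negated SSRI mention in the
#' same window).
#'
#' @param notes Note table (note_id, patient_id, date, text).
#' @param surgery_dates data.frame with patient_id, surgery_date.
#' @param dep_lexicon,ssri_lexicon Lexicons; default to the shipped ones.
#' @param window_days Lookback window (365).
#' @param include_after Accept post-surgery notes too (default FALSE).
#' @return List with `note_labels` (per-note depression labels, with
#'   rel_day), `ssri_labels`, and `patient_flags` (patient_id,
#'   nlp_depressed, ssri_note) covering every patient in `surgery_dates`.
#' @export
run_nlp_stage <- function(notes, surgery_dates,
                          dep_lexicon = default_lexicon("depression"),
                          ssri_lexicon = default_lexicon("ssri"),
                          window_days = 365L, include_after = FALSE) {
  sdate <- stats::setNames(surgery_dates$surgery_date,
                           surgery_dates$patient_id)
  notes <- notes[notes$patient_id %in% surgery_dates$patient_id, ,
                 drop = FALSE]
  dep <- classify_notes(notes, dep_lexicon)
  ssri <- classify_notes(notes, ssri_lexicon)
  rel <- notes$date - sdate[notes$patient_id]
  dep$rel_day <- rel
  ssri$rel_day <- rel
  in_win <- rel >= -window_days &
    (if (include_after) rel <= window_days else rel <= 0)

  dep_pat <- unique(dep$patient_id[in_win & dep$label == "Affirmed"])
  # an SSRI mention counts when any sentence is affirmed, independent of the
  # note-level vote
  ssri_pat <- unique(ssri$patient_id[in_win & ssri$n_affirmed > 0])
  flags <- data.frame(
    patient_id = surgery_dates$patient_id,
    nlp_depressed = surgery_dates$patient_id %in% dep_pat,
    ssri_note = surgery_dates$patient_id %in% ssri_pat,
    stringsAsFactors = FALSE)
  list(note_labels = dep, ssri_labels = ssri, patient_flags = flags)
}

#' Read a flat key-value run configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. Numeric-looking
#' values are converted. Recognised keys are the scalar
#' [generator_config()] fields plus `seed` and `out`.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full pipeline end to end
#'
#' simulate -> phenotype -> cohort -> outcomes -> predict, writing each
#' stage's outputs beneath `out_dir` plus a provenance manifest (seed,
#' config summary, per-stage record counts). Rerunning with the same config
#' and seed reproduces the outputs byte for byte.
#'
#' @param config A [generator_config()] (controls the simulated world and
#'   the seed).
#' @param out_dir Output directory.
#' @param grid Elastic-net hyperparameter grid; the default full grid is
#'   expensive, so small demo runs may pass a reduced one.
#' @param k_outer,k_inner Cross-validation fold counts.
#' @param comparators Also run the comparator models (slower; default
#'   FALSE).
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_all <- function(config = generator_config(n_patients = 500L),
                    out_dir, grid = default_hyper_grid(), k_outer = 10L,
                    k_inner = 5L, comparators = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  extract <- generate_cohort(config)
  write_extract(extract, file.path(out_dir, "extract"))
  counts$patients <- nrow(extract$patients)
  counts$notes <- nrow(extract$notes)

  enc <- select_surgeries(extract$encounters)
  nlp <- run_nlp_stage(extract$notes,
                       enc[, c("patient_id", "surgery_date")])
  utils::write.csv(nlp$note_labels, file.path(out_dir, "note_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(nlp$patient_flags, file.path(out_dir, "patient_flags.csv"),
                   row.names = FALSE)
  gold_notes <- extract$gold$notes
  gold_notes <- gold_notes[gold_notes$note_id %in% nlp$note_labels$note_id, ]
  metrics <- evaluate_nlp(nlp$note_labels[, c("note_id", "label")],
                          gold_notes[, c("note_id", "label")])
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$nlp_depressed <- sum(nlp$patient_flags$nlp_depressed)

  cb <- build_cohort(extract, nlp$patient_flags)
  utils::write.csv(cb$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cb$attrition, file.path(out_dir, "attrition_log.csv"),
                   row.names = FALSE)
  counts$cohort <- nrow(cb$cohort)
  X <- build_feature_matrix(cb$cohort)
  utils::write.csv(cbind(patient_id = cb$cohort$patient_id,
                         as.data.frame(X)),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  outcomes <- compute_outcomes(cb$cohort, extract$pain)
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  t4 <- delta_report(outcomes)
  utils::write.csv(t4, file.path(out_dir, "table4_report.csv"),
                   row.names = FALSE)
  counts$outcomes <- nrow(outcomes)

  cvs <- list()
  comp <- list()
  for (tp in TIME_POINTS) {
    delta <- outcomes[[paste0("delta_", tp)]]
    cvs[[tp]] <- nested_cv(X, delta, grid = grid, k_outer = k_outer,
                           k_inner = k_inner,
                           seed = child_seed(config$seed, match(tp, TIME_POINTS)),
                           time_point = tp)
    if (comparators) {
      comp[[tp]] <- run_comparators(
        X, delta, k_outer = k_outer,
        seed = child_seed(config$seed, match(tp, TIME_POINTS)),
        grid = grid, k_inner = k_inner, cv = cvs[[tp]])
      comp[[tp]]$time_point <- tp
    }
  }
  cv_json <- lapply(cvs, function(cv) {
    list(time_point = cv$time_point, fold_auc = cv$fold_auc,
         mean_auc = cv$mean_auc, sd_auc = cv$sd_auc, n = cv$n,
         hyper = cv$hyper)
  })
  jsonlite::write_json(cv_json, file.path(out_dir, "cv_results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  coef_tab <- do.call(rbind, lapply(cvs, function(cv) {
    rc <- rank_coefficients(cv)
    if (nrow(rc)) rc$time_point <- cv$time_point
    rc
  }))
  utils::write.csv(coef_tab, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  roc_tab <- do.call(rbind, lapply(cvs, function(cv) {
    data.frame(time_point = cv$time_point, fpr = cv$mean_roc$fpr,
               tpr = cv$mean_roc$tpr)
  }))
  utils::write.csv(roc_tab, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  if (comparators) {
    utils::write.csv(do.call(rbind, comp),
                     file.path(out_dir, "table5_report.csv"),
                     row.names = FALSE)
  }

  manifest <- list(seed = config$seed, n_patients = config$n_patients,
                   stages = c("simulate", "phenotype", "cohort", "outcomes",
                              "predict"),
                   record_counts = counts,
                   package_version = as.character(utils::packageVersion("painpheno")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(extract = extract, nlp = nlp, cohort = cb,
                 outcomes = outcomes, cv = cvs,
                 comparators = if (comparators) comp else NULL,
                 metrics = metrics))
}

#' Render paper-style summary tables from a run directory
#'
#' Formats counts as "n (%)" with half-up one-decimal percentages and
#' change-in-pain rows as "mean (SD), (min, max)". Pure formatting: every
#' number comes from a machine-readable stage output.
#'
#' @param run_dir Directory produced by [run_all()].
#' @return List of data.frames: `group_table` (cohort composition),
#'   `delta_table`, and `model_table` when comparator results exist; also
#'   written as rendered_*.csv in `run_dir`.
#' @export
render_reports <- function(run_dir) {
  cohort <- tryCatch(
    utils::read.csv(file.path(run_dir, "cohort.csv"),
                    stringsAsFactors = FALSE),
    error = function(e) data.frame()) # an empty cohort writes an empty file
  out <- list()
  if (nrow(cohort)) {
    tab <- table(factor(cohort$group, levels = GROUP_LEVELS))
    out$group_table <- data.frame(
      group = names(tab),
      n_pct = format_n_pct(as.integer(tab), sum(tab)),
      stringsAsFactors = FALSE)
  } else {
    out$group_table <- data.frame(group = character(0), n_pct = character(0))
  }
  t4p <- file.path(run_dir, "table4_report.csv")
  if (file.exists(t4p)) {
    t4 <- utils::read.csv(t4p, stringsAsFactors = FALSE)
    out$delta_table <- data.frame(
      time_point = t4$time_point, stratum = t4$stratum,
      prodrug = sprintf("%.3f (%.2f), (%.2f, %.2f)", t4$mean_pro, t4$sd_pro,
                        t4$min_pro, t4$max_pro),
      non_prodrug = sprintf("%.3f (%.2f), (%.2f, %.2f)", t4$mean_non,
                            t4$sd_non, t4$min_non, t4$max_non),
      p_value = signif(t4$p_value, 4), stringsAsFactors = FALSE)
  }
  t5p <- file.path(run_dir, "table5_report.csv")
  if (file.exists(t5p)) {
    t5 <- utils::read.csv(t5p, stringsAsFactors = FALSE)
    out$model_table <- data.frame(
      time_point = t5$time_point, model = t5$model,
      auc = ifelse(t5$available, sprintf("%.2f (+/-%.2f)", t5$mean_auc,
                                         t5$sd_auc), "unavailable"),
      stringsAsFactors = FALSE)
  }
  for (nm in names(out)) {
    utils::write.csv(out[[nm]],
                     file.path(run_dir, paste0("rendered_", nm, ".csv")),
                     row.names = FALSE)
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --n <int> --seed <int> --out <dir>`,
#' `run-all --config <file>` (keys: n_patients, seed, out), and
#' `report --run <dir>`. A thin wrapper over [generate_cohort()],
#' [run_all()] and [render_reports()] for shell use; R callers should use
#' those functions directly.
#'
#' @param args Character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0, invisibly.
#' @export
painpheno_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  cmd <- if (length(args)) args[1] else "help"
  if (cmd == "simulate") {
    cfg <- generator_config(
      n_patients = as.integer(get_opt("--n", "500")),
      seed = as.integer(get_opt("--seed", "1")))
    write_extract(generate_cohort(cfg), get_opt("--out", "extract"))
  } else if (cmd == "run-all") {
    cfgf <- get_opt("--config")
    opts <- if (!is.null(cfgf)) read_run_config(cfgf) else list()
    cfg <- generator_config(
      n_patients = as.integer(opts$n_patients %||% 500),
      seed = as.integer(opts$seed %||% 1))
    run_all(cfg, out_dir = as.character(opts$out %||% "run"))
  } else if (cmd == "report") {
    render_reports(get_opt("--run", "run"))
  } else {
    cat("usage: painpheno <simulate|run-all|report> [options]\n")
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
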