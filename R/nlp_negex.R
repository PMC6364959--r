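# ---- phrase scanning over token vectors -------------------------------------

# All occurrences of the phrases in `ph` (a tokenize_phrases() structure)
# within `tokens`. At each start position only the longest matching phrase is
# taken; occurrences starting at different positions may overlap. Returns a
# data.frame with columns start, end, term.
scan_phrases <- function(tokens, ph) {
  n <- length(tokens)
  out_s <- integer(0); out_e <- integer(0); out_t <- character(0)
  if (n == 0L || length(ph$phrases) == 0L) {
    return(data.frame(start = out_s, end = out_e, term = out_t,
                      stringsAsFactors = FALSE))
  }
  firsts <- vapply(ph$tokens, `[`, character(1), 1L)
  starts <- which(tokens %in% firsts)
  for (s in starts) {
    for (k in seq_along(ph$tokens)) {
      pt <- ph$tokens[[k]]
      e <- s + length(pt) - 1L
      if (e <= n && all(tokens[s:e] == pt)) {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        out_t <- c(out_t, ph$phrases[k])
        break # longest phrase wins at this start
      }
    }
  }
  data.frame(start = out_s, end = out_e, term = out_t, stringsAsFactors = FALSE)
}

# Greedy non-overlapping longest-match: at each position take the longest
# phrase and resume after it. Used for concept matching.
scan_phrases_greedy <- function(tokens, ph) {
  n <- length(tokens)
  out_s <- integer(0); out_e <- integer(0); out_t <- character(0)
  if (n > 0L && length(ph$phrases) > 0L) {
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (k in seq_along(ph$tokens)) {
        pt <- ph$tokens[[k]]
        e <- i + length(pt) - 1L
        if (e <= n && all(tokens[i:e] == pt)) { hit <- k; break }
      }
      if (hit > 0L) {
        e <- i + length(ph$tokens[[hit]]) - 1L
        out_s <- c(out_s, i); out_e <- c(out_e, e)
        out_t <- c(out_t, ph$phrases[hit])
        i <- e + 1L
      } else i <- i + 1L
    }
  }
  data.frame(start = out_s, end = out_e, term = out_t, stringsAsFactors = FALSE)
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# ---- concept matching -------------------------------------------------------

#' Locate lexicon concepts in a sentence and apply sense-exclusion filters
#'
#' Concepts are matched longest-first on the concept view (stop words,
#' punctuation and very short words removed); exclusion patterns are matched
#' on the full token sequence, where short tokens like "st" survive. The
#' sentence is flagged `filtered` when any exclusion pattern overlaps a
#' matched concept (e.g. "st depression" over the concept "depression"),
#' which forces the sentence to NoMention downstream.
#'
#' @param sentence A preprocessed sentence record (see [preprocess()]) or a
#'   single string.
#' @param lexicon A `pain_lexicon`.
#' @return List with `matches` (data.frame: term, start, end on the raw token
#'   scale) and `filtered` (logical).
#' @export
match_concepts <- function(sentence, lexicon) {
  sen <- as_sentence(sentence)
  raw_idx <- which(sen$keep)
  view <- sen$tokens[sen$keep]
  m <- scan_phrases_greedy(view, lexicon$tok$concept)
  if (nrow(m)) { # map view spans back to raw token positions
    m$start <- raw_idx[m$start]
    m$end <- raw_idx[m$end]
  }
  excl <- scan_phrases(sen$tokens, lexicon$tok$exclusion)
  filtered <- FALSE
  if (nrow(m) && nrow(excl)) {
    for (i in seq_len(nrow(m))) {
      if (any(spans_overlap(m$start[i], m$end[i], excl$start, excl$end))) {
        filtered <- TRUE
        break
      }
    }
  }
  list(matches = m, filtered = filtered)
}

as_sentence <- function(x) {
  if (is.character(x)) {
    sens <- preprocess(x)
    if (length(sens) != 1L) stop("expected exactly one sentence, got ",
                                 length(sens))
    return(sens[[1]])
  }
  x
}

# ---- NegEx-style negation ---------------------------------------------------

#' Classify one sentence as Affirmed / Negated / NoMention
#'
#' Implements a NegEx-style rule: a matched concept is negated when a
#' pre-negation trigger ends within `window` tokens before it, or a
#' post-negation trigger starts within `window` tokens after it, provided no
#' termination term ("but", "however", ...) lies between trigger and concept.
#' Scope never crosses a sentence boundary. The sentence is Negated when all
#' its concepts are negated, Affirmed when at least one concept is affirmed,
#' and NoMention when no (unfiltered) concept is present.
#'
#' @inheritParams match_concepts
#' @param window Maximum number of tokens (of any kind) between trigger and
#'   concept; default 5, the classical NegEx scope.
#' @return An object of class `sentence_annotation`: list with `text`,
#'   `tokens`, `matches` (with a `negated` column), `filtered`, `label`.
#' @export
classify_sentence <- function(sentence, lexicon, window = 5L) {
  sen <- as_sentence(sentence)
  mc <- match_concepts(sen, lexicon)
  m <- mc$matches
  if (mc$filtered || nrow(m) == 0L) {
    m$negated <- logical(nrow(m))
    return(structure(list(text = sen$text, tokens = sen$tokens, matches = m,
                          filtered = mc$filtered, label = "NoMention"),
                     class = "sentence_annotation"))
  }
  pre <- scan_phrases(sen$tokens, lexicon$tok$pre_neg)
  post <- scan_phrases(sen$tokens, lexicon$tok$post_neg)
  term <- scan_phrases(sen$tokens, lexicon$tok$termination)
  m$negated <- vapply(seq_len(nrow(m)), function(i) {
    concept_negated(m$start[i], m$end[i], pre, post, term, window)
  }, logical(1))
  label <- if (all(m$negated)) "Negated" else "Affirmed"
  structure(list(text = sen$text, tokens = sen$tokens, matches = m,
                 filtered = FALSE, label = label),
            class = "sentence_annotation")
}

# negation decision for one concept span [cs, ce]
concept_negated <- function(cs, ce, pre, post, term, window) {
  if (nrow(pre)) {
    for (i in seq_len(nrow(pre))) {
      te <- pre$end[i]
      gap <- cs - te - 1L
      if (te < cs && gap >= 0L && gap <= window &&
          !termination_between(te, cs, term)) {
        return(TRUE)
      }
    }
  }
  if (nrow(post)) {
    for (i in seq_len(nrow(post))) {
      ts <- post$start[i]
      gap <- ts - ce - 1L
      if (ts > ce && gap >= 0L && gap <= window &&
          !termination_between(ce, ts, term)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# any termination occurrence lying strictly between positions a and b?
termination_between <- function(a, b, term) {
  if (!nrow(term)) return(FALSE)
  any(term$start > a & term$end < b)
}

#' @export
print.sentence_annotation <- function(x, ...) {
  cat(sprintf("<%s%s> %s\n", x$label, if (x$filtered) " (filtered)" else "",
              x$text))
  invisible(x)
}

# ---- note-level aggregation -------------------------------------------------

#' Aggregate sentence labels to a note label by majority vote
#'
#' NoMention sentences do not vote. A tie between Affirmed and Negated goes
#' to Affirmed. A note with no voting sentence is NoMention.
#'
#' @param labels Character vector of sentence labels, or a list of
#'   `sentence_annotation` objects.
#' @return List with `label`, `n_affirmed`, `n_negated`.
#' @export
vote_note <- function(labels) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(a) a$label, character(1))
  }
  n_aff <- sum(labels == "Affirmed")
  n_neg <- sum(labels == "Negated")
  label <- if (n_aff == 0L && n_neg == 0L) "NoMention"
           else if (n_aff >= n_neg) "Affirmed" else "Negated"
  list(label = label, n_affirmed = n_aff, n_negated = n_neg)
}

#' Annotate every sentence of a note and vote
#'
#' @param text Note text.
#' @param lexicon A `pain_lexicon`.
#' @param window Negation scope window, see [classify_sentence()].
#' @return List with `sentences` (list of `sentence_annotation`) and `note`
#'   (the [vote_note()] result).
#' @export
annotate_note <- function(text, lexicon, window = 5L) {
  sens <- preprocess(text)
  keyset <- unique(unlist(lapply(lexicon$tok$concept$tokens, identity)))
  anns <- lapply(sens, function(sen) {
    if (!any(sen$tokens %in% keyset)) {
      structure(list(text = sen$text, tokens = sen$tokens,
                     matches = data.frame(term = character(0),
                                          start = integer(0), end = integer(0),
                                          negated = logical(0),
                                          stringsAsFactors = FALSE),
                     filtered = FALSE, label = "NoMention"),
                class = "sentence_annotation")
    } else {
      classify_sentence(sen, lexicon, window)
    }
  })
  list(sentences = anns, note = vote_note(anns))
}

#' Classify a table of notes
#'
#' Bulk equivalent of [annotate_note()] + [vote_note()] over many notes.
#' Sentences that cannot contain a concept (no concept word present, checked
#' with a single vectorized regex) are NoMention without running the full
#' engine; the result is identical to the per-note path.
#'
#' @param notes data.frame with columns `note_id`, `patient_id`, `date`
#'   (integer day relative to surgery or a Date), `text`.
#' @param lexicon A `pain_lexicon`.
#' @param window Negation scope window.
#' @return data.frame: note_id, patient_id, date, n_affirmed, n_negated,
#'   label.
#' @export
classify_notes <- function(notes, lexicon, window = 5L) {
  stopifnot(all(c("note_id", "patient_id", "date", "text") %in% names(notes)))
  n <- nrow(notes)
  base <- data.frame(note_id = notes$note_id, patient_id = notes$patient_id,
                     date = notes$date, n_affirmed = 0, n_negated = 0,
                     label = "NoMention", stringsAsFactors = FALSE)
  if (n == 0L) return(base)

  # vectorized preprocessing, mirroring preprocess()
  clean <- trimws(gsub("[[:space:]]+", " ", tolower(
    vapply(notes$text, function(t) {
      u <- iconv(t, from = "", to = "UTF-8", sub = "?")
      if (is.na(u)) iconv(t, from = "latin1", to = "UTF-8", sub = "?") else u
    }, character(1), USE.NAMES = FALSE))))
  sen_list <- strsplit(clean, "(?<=[.!?;])\\s+", perl = TRUE)
  sen_list <- lapply(sen_list, function(s) {
    s <- trimws(gsub("[.!?;]+$", "", s))
    s[nzchar(s)]
  })
  note_of <- rep(seq_len(n), lengths(sen_list))
  sens <- unlist(sen_list, use.names = FALSE)

  words <- unique(unlist(lexicon$tok$concept$tokens))
  hit <- if (length(words)) {
    grepl(paste0("\\b(", paste(words, collapse = "|"), ")\\b"), sens,
          perl = TRUE)
  } else rep(FALSE, length(sens))

  lab <- rep("NoMention", length(sens))
  for (k in which(hit)) {
    toks <- tokenize_words(sens[k])$tokens
    sen <- list(text = sens[k], tokens = toks,
                keep = concept_view_mask(toks))
    lab[k] <- classify_sentence(sen, lexicon, window)$label
  }
  n_aff <- tapply(lab == "Affirmed", note_of, sum)
  n_neg <- tapply(lab == "Negated", note_of, sum)
  idx <- as.integer(names(n_aff))
  base$n_affirmed[idx] <- as.numeric(n_aff)
  base$n_negated[idx] <- as.numeric(n_neg)
  base$label <- ifelse(
    base$n_affirmed == 0 & base$n_negated == 0, "NoMention",
    ifelse(base$n_affirmed >= base$n_negated, "Affirmed", "Negated"))
  base
}

# ---- patient-level phenotyping ----------------------------------------------

#' Flag a patient as NLP-depressed from note labels
#'
#' True when at least one note labelled Affirmed falls within the lookback
#' window before (and including the day of) surgery.
#'
#' @param note_labels data.frame with `date` (days relative to surgery,
#'   negative = before) and `label`, for one patient's notes.
#' @param window_days Lookback length in days (default 365).
#' @param include_after Also accept notes after surgery (default FALSE; the
#'   "within 1 year" rule is applied pre-surgery only).
#' @return Logical flag.
#' @export
phenotype_patient <- function(note_labels, window_days = 365L,
                              include_after = FALSE) {
  if (nrow(note_labels) == 0L) return(FALSE)
  d <- note_labels$date
  in_win <- d >= -window_days & (if (include_after) d <= window_days else d <= 0)
  any(in_win & note_labels$label == "Affirmed")
}

#' Detect non-negated SSRI mentions in a patient's notes
#'
#' Runs the same matching/negation engine with an SSRI name lexicon as the
#' concept list: the flag is true when any in-window note contains at least
#' one affirmed (unfiltered, non-negated) SSRI mention.
#'
#' @param notes data.frame with `date` and `text` for one patient.
#' @param ssri_lexicon A `pain_lexicon` of SSRI names (see
#'   [default_lexicon()]).
#' @param window_days,include_after Lookback window, as in
#'   [phenotype_patient()].
#' @param window Negation scope window.
#' @return Logical flag.
#' @export
detect_ssri_mentions <- function(notes, ssri_lexicon, window_days = 365L,
                                 include_after = FALSE, window = 5L) {
  if (nrow(notes) == 0L) return(FALSE)
  d <- notes$date
  in_win <- d >= -window_days & (if (include_after) d <= window_days else d <= 0)
  for (i in which(in_win)) {
    ann <- annotate_note(notes$text[i], ssri_lexicon, window)
    for (a in ann$sentences) {
      if (a$label == "Affirmed") return(TRUE)
    }
  }
  FALSE
}

# ---- evaluation -------------------------------------------------------------

#' Precision / recall / F1 of predicted note labels against gold
#'
#' The positive class is `Affirmed`. F1 (and precision) are reported as 0
#' with a warning in degenerate cases where they are undefined.
#'
#' @param pred data.frame with `note_id`, `label`.
#' @param gold data.frame with `note_id`, `label`.
#' @param positive Positive class label.
#' @return List: tp, fp, fn, tn, precision, recall, f1.
#' @export
evaluate_nlp <- function(pred, gold, positive = "Affirmed") {
  miss <- setdiff(gold$note_id, pred$note_id)
  extra <- setdiff(pred$note_id, gold$note_id)
  if (length(miss) || length(extra)) {
    stop("note id mismatch; missing from pred: ",
         paste(utils::head(miss, 5), collapse = ", "),
         "; not in gold: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  g <- gold$label[match(pred$note_id, gold$note_id)] == positive
  p <- pred$label == positive
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  if (tp + fp + fn == 0L) {
    warning("no positives in prediction or gold; F1 undefined, reporting 0")
    precision <- 0; recall <- 0; f1 <- 0
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else {
      warning("no predicted positives; precision undefined, reporting 0"); 0
    }
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}
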