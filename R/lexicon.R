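#' Load a phenotyping lexicon from a tab-delimited file
#'
#' A lexicon is a two-column TSV (`term`, `kind`) where `kind` is one of
#' `concept` (a clinical concept to detect), `exclusion` (a phrase marking an
#' irrelevant sense of a concept, e.g. "st depression" on an ECG report),
#' `pre_neg` / `post_neg` (negation triggers that scope forwards / backwards
#' over nearby concepts), and `termination` (phrases such as "but" that cut a
#' negation scope). Terms are lower-cased and pre-tokenized at load time.
#'
#' @param path Path to the TSV file.
#' @return An object of class `pain_lexicon`: a list with one character
#'   vector of terms per kind plus the tokenized phrases.
#' @seealso [default_lexicon()] for the lexicons shipped with the package.
#' @export
read_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("term", "kind") %in% names(raw))) {
    stop("lexicon file must have columns 'term' and 'kind': ", path)
  }
  kinds <- c("concept", "exclusion", "pre_neg", "post_neg", "termination")
  bad <- setdiff(unique(raw$kind), kinds)
  if (length(bad)) stop("unknown lexicon kind(s): ", paste(bad, collapse = ", "))
  raw$term <- tolower(trimws(raw$term))
  if (any(!nzchar(raw$term))) stop("lexicon contains empty terms")
  new_lexicon(split(raw$term, factor(raw$kind, levels = kinds)))
}

# build a pain_lexicon from a named list of term vectors
new_lexicon <- function(terms) {
  terms <- lapply(terms, function(x) unique(tolower(x)))
  for (k in c("concept", "exclusion", "pre_neg", "post_neg", "termination")) {
    if (is.null(terms[[k]])) terms[[k]] <- character(0)
  }
  triggers <- c(terms$pre_neg, terms$post_neg, terms$termination)
  clash <- intersect(terms$concept, triggers)
  if (length(clash)) {
    stop("terms cannot be both concept and trigger: ",
         paste(clash, collapse = ", "))
  }
  lex <- list(
    concept = terms$concept, exclusion = terms$exclusion,
    pre_neg = terms$pre_neg, post_neg = terms$post_neg,
    termination = terms$termination,
    # tokenized phrases, longest first, for greedy longest-match scanning
    tok = lapply(terms[c("concept", "exclusion", "pre_neg", "post_neg",
                         "termination")], tokenize_phrases)
  )
  structure(lex, class = "pain_lexicon")
}

tokenize_phrases <- function(x) {
  toks <- lapply(x, function(p) tokenize_words(p)$tokens)
  ord <- order(lengths(toks), decreasing = TRUE)
  list(phrases = x[ord], tokens = toks[ord])
}

#' Construct a lexicon from term vectors
#'
#' Programmatic counterpart of [read_lexicon()], mainly useful for tests and
#' for micro-lexicons.
#'
#' @param concept,exclusion,pre_neg,post_neg,termination Character vectors of
#'   (possibly multi-word) lower-case phrases.
#' @return A `pain_lexicon` object.
#' @export
make_lexicon <- function(concept, exclusion = character(0),
                         pre_neg = character(0), post_neg = character(0),
                         termination = character(0)) {
  new_lexicon(list(concept = concept, exclusion = exclusion,
                   pre_neg = pre_neg, post_neg = post_neg,
                   termination = termination))
}

#' Lexicons shipped with the package
#'
#' `"depression"` is a curated emulation of a UMLS-derived depression
#' diagnosis/symptom dictionary with sense-exclusion patterns (ECG ST
#' depression, depressed skull fracture, respiratory depression, ...).
#' `"ssri"` lists SSRI generic and trade names with medication-appropriate
#' negation triggers ("discontinued", "no longer taking").
#'
#' @param name `"depression"` or `"ssri"`.
#' @return A `pain_lexicon` object.
#' @export
default_lexicon <- function(name = c("depression", "ssri")) {
  name <- match.arg(name)
  read_lexicon(pkg_extdata("lexicons", paste0(name, ".tsv")))
}

#' @export
print.pain_lexicon <- function(x, ...) {
  cat("<pain_lexicon>",
      sprintf("%d concepts, %d exclusions, %d pre-neg, %d post-neg, %d termination",
              length(x$concept), length(x$exclusion), length(x$pre_neg),
              length(x$post_neg), length(x$termination)), "\n")
  invisible(x)
}
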