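# Small English stop list used only for the concept-matching token view.
# Deliberately excludes negation cues ("no", "not", "without", "denies"):
# those live in the raw view that the negation engine scans.
STOPWORDS <- c(
  "a", "an", "the", "and", "or", "of", "in", "on", "at", "to", "for", "with",
  "is", "are", "was", "were", "be", "been", "being", "has", "have", "had",
  "this", "that", "these", "those", "it", "its", "as", "by", "from", "her",
  "his", "their", "she", "he", "they", "them", "will", "would", "there",
  "which", "who", "whom", "what", "when", "where", "also", "than", "then",
  "into", "over", "under", "about", "after", "before", "during", "per"
)

# Tokenize one lower-case string. Words (letters/digits/apostrophes) and
# single punctuation marks become separate tokens; hyphens split words.
tokenize_words <- function(x) {
  m <- gregexpr("[a-z0-9']+|[[:punct:]]", x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(tokens = character(0)))
  list(tokens = regmatches(x, list(m))[[1]])
}

# Concept-view mask: drop punctuation, stop words, and words of <= 2 letters.
concept_view_mask <- function(tokens) {
  is_word <- grepl("^[a-z0-9']", tokens)
  is_word & nchar(tokens) > 2L & !(tokens %in% STOPWORDS)
}

#' Normalize and sentence-split a clinical note
#'
#' Applies the standard cleaning chain: coerce to UTF-8 (undecodable bytes
#' are replaced and a warning is raised), lower-case, collapse extraneous
#' whitespace, detect sentence boundaries, and tokenize each sentence. Every
#' sentence carries two token views: the full `tokens` vector (used by the
#' negation engine, which must see "no"/"not") and a logical `keep` mask
#' selecting the concept-matching view (stop words, punctuation and words of
#' two letters or fewer removed).
#'
#' @param text A single character string (one note).
#' @return A list with one element per sentence, each a list with `text`
#'   (cleaned sentence), `tokens` (character vector) and `keep` (logical
#'   mask for the concept view). Empty input yields an empty list.
#' @export
preprocess <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("text must be a single string")
  utf <- iconv(text, from = "", to = "UTF-8", sub = "?")
  if (is.na(utf)) {
    warning("undecodable bytes replaced with '?'")
    utf <- iconv(text, from = "latin1", to = "UTF-8", sub = "?")
  }
  clean <- tolower(utf)
  clean <- gsub("[[:space:]]+", " ", clean)
  clean <- trimws(clean)
  if (!nzchar(clean)) return(list())
  # boundary after ., !, ?, ; or newline (newlines already collapsed)
  parts <- strsplit(clean, "(?<=[.!?;])\\s+", perl = TRUE)[[1]]
  parts <- trimws(gsub("[.!?;]+$", "", parts))
  parts <- parts[nzchar(parts)]
  lapply(parts, function(s) {
    toks <- tokenize_words(s)$tokens
    list(text = s, tokens = toks, keep = concept_view_mask(toks))
  })
}
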