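#' Default English stop-word list
#'
#' Reads the stop-word file shipped with the package (one word per line,
#' UTF-8). Any such file can be substituted via the `stopwords` argument of
#' the cleaning functions. Because stop-word filtering happens after
#' punctuation has been replaced by spaces, contracted forms appear in the
#' list as their apostrophe-split parts (e.g. "don", "doesn").
#'
#' @param path Optional path to an alternative list.
#' @return A character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.stopword_cache$words)) return(.stopword_cache$words)
    path <- system.file("extdata", "stopwords_en.txt", package = "misinfonet")
    words <- readLines(path, encoding = "UTF-8", warn = FALSE)
    words <- words[nzchar(words)]
    .stopword_cache$words <- words
    return(words)
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words[nzchar(words)]
}

.stopword_cache <- new.env(parent = emptyenv())

#' Clean tweet-style text
#'
#' Applies the cleaning cascade in a fixed order: URL and @-mention removal,
#' lowercasing, punctuation replaced by a space (so hyphenated words and
#' hashtags keep their word bodies as separate tokens), character-wise digit
#' removal, whitespace tokenization, stop-word removal, and removal of
#' single-character tokens. The result is a string of lowercase alphabetic
#' tokens separated by single spaces, preserving the order of surviving
#' tokens; cleaning is idempotent.
#'
#' @param text Character vector of raw texts.
#' @param stopwords Character vector of stop words ([default_stopwords()]).
#' @return Character vector of cleaned texts (possibly empty strings).
#' @examples
#' clean_text("COVID-19 is REAL!!!")   # "covid real"
#' clean_text("5G!!")                  # "" (digits stripped, single char dropped)
#' @export
clean_text <- function(text, stopwords = default_stopwords()) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("@[[:alnum:]_]+", " ", x)
  x <- tolower(x)
  x <- gsub("[^a-z0-9[:space:]]+", " ", x)
  x <- gsub("[0-9]+", "", x)
  toks <- strsplit(x, "[[:space:]]+")
  vapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!tk %in% stopwords]
    tk <- tk[nchar(tk) > 1L]
    paste(tk, collapse = " ")
  }, character(1))
}

#' Tokenize cleaned text
#'
#' Whitespace split of an already-cleaned string; token order and
#' multiplicity are preserved.
#'
#' @param cleaned A single cleaned string (see [clean_text()]).
#' @return Character vector of tokens (length zero for an empty string).
#' @export
tokenize <- function(cleaned) {
  stopifnot(length(cleaned) == 1L)
  if (is.na(cleaned) || !nzchar(cleaned)) return(character())
  strsplit(cleaned, " ", fixed = TRUE)[[1]]
}

#' Clean and tokenize every document of a corpus
#'
#' @param corpus A corpus data.frame.
#' @param stopwords Stop-word list.
#' @return A named list (document id -> character vector of tokens).
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords()) {
  corpus <- as_corpus(corpus)
  cleaned <- clean_text(corpus$text, stopwords)
  toks <- strsplit(cleaned, " ", fixed = TRUE)
  toks <- lapply(toks, function(tk) tk[nzchar(tk)])
  names(toks) <- corpus$id
  toks
}

#' Drop duplicate documents
#'
#' Among documents whose *cleaned* text is identical, only the first in input
#' order is retained. Deduplication is idempotent and never increases the
#' corpus size. Documents that clean to the empty string are all considered
#' duplicates of the first empty one.
#'
#' @param corpus A corpus data.frame.
#' @param stopwords Stop-word list used for the cleaning comparison.
#' @return The corpus restricted to first occurrences.
#' @export
deduplicate <- function(corpus, stopwords = default_stopwords()) {
  corpus <- as_corpus(corpus)
  if (!nrow(corpus)) return(corpus)
  cleaned <- clean_text(corpus$text, stopwords)
  keep <- !duplicated(cleaned)
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
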