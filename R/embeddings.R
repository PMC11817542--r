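#' Word-embedding providers
#'
#' An embedding provider maps every word to a numeric vector of a fixed
#' dimension. Out-of-vocabulary words resolve to the zero vector, which is
#' also the padding value of the document matrices, so convolution treats
#' unknown words and padding identically (zero is the neutral element for
#' the convolution sums).
#'
#' @param dimension Positive integer vector length per word.
#' @param lookup A function `(words) -> matrix(length(words) x dimension)`.
#' @param vocabulary Optional character vector of known words.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(dimension, lookup, vocabulary = NULL) {
  stopifnot(is.numeric(dimension), length(dimension) == 1L, dimension >= 1,
            is.function(lookup))
  structure(list(dimension = as.integer(dimension), lookup = lookup,
                 vocabulary = vocabulary),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> dimension:", x$dimension,
      if (!is.null(x$vocabulary)) paste0("vocabulary: ", length(x$vocabulary),
                                         " words") else "(procedural)", "\n")
  invisible(x)
}

#' Look up word vectors
#'
#' @param provider An [embedding_provider()].
#' @param words Character vector.
#' @return A `length(words) x dimension` matrix, one row per word.
#' @export
lookup_vectors <- function(provider, words) {
  stopifnot(inherits(provider, "embedding_provider"))
  out <- provider$lookup(as.character(words))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(words), byrow = TRUE)
  out
}

#' Load pre-trained word vectors from GloVe/word2vec text format
#'
#' Parses the plain-text dialect: one word followed by D floats per line,
#' space-separated, with an optional leading "count dimension" header line
#' (tolerated and skipped). Inconsistent row widths raise an error naming
#' the offending line. Lookups of unlisted words return the zero vector.
#'
#' @param path Path to the vector file.
#' @return An [embedding_provider()].
#' @export
load_vectors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty vector file: ", path)
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  offset <- 0L
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    offset <- 1L  # word2vec-style "vocab dim" header
    lines <- lines[-1]
    if (!length(lines)) stop("vector file has a header but no rows: ", path)
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  dim <- length(fields[[1]]) - 1L
  if (dim < 1) stop("malformed vector row at line ", 1L + offset)
  env <- new.env(parent = emptyenv(), size = length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != dim + 1L) {
      stop("inconsistent row width at line ", i + offset, ": expected ",
           dim + 1L, " fields, found ", length(f))
    }
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric vector entry at line ", i + offset)
    assign(f[1], v, envir = env)
  }
  zero <- numeric(dim)
  lookup <- function(words) {
    out <- matrix(0, length(words), dim)
    for (j in seq_along(words)) {
      v <- get0(words[j], envir = env, ifnotfound = NULL)
      if (!is.null(v)) out[j, ] <- v
    }
    out
  }
  embedding_provider(dim, lookup, vocabulary = ls(env))
}

# 32-bit FNV-1a over UTF-8 bytes, mixed with a seed; arithmetic done in
# doubles with a 16-bit split so every intermediate stays exact.
.fnv1a32 <- function(word, seed) {
  h <- 2166136261
  bytes <- as.integer(charToRaw(enc2utf8(word)))
  p <- 16777619
  for (b in c(bytes, seed %% 256, seed %/% 256 %% 256)) {
    ## xor on the 32-bit value, via two 16-bit halves
    h <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536)) +
      65536 * bitwXor(as.integer(h %/% 65536), as.integer(b %/% 65536))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Deterministic seeded hash embeddings
#'
#' A download-free embedding provider: each word hashes (FNV-1a, mixed with
#' the seed) to a deterministic unit-norm Gaussian direction of the requested
#' dimension. The same word and seed yield bit-identical vectors across runs
#' and machines; distinct words yield distinct vectors with overwhelming
#' probability. Useful as the default test-time embedder; swap in
#' [load_vectors()] for pre-trained vectors.
#'
#' @param dimension Vector length per word (default 100).
#' @param seed Integer seed.
#' @return An [embedding_provider()].
#' @export
hash_provider <- function(dimension = 100, seed = 1L) {
  stopifnot(dimension >= 1)
  dimension <- as.integer(dimension)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  lookup <- function(words) {
    out <- matrix(0, length(words), dimension)
    for (j in seq_along(words)) {
      w <- words[j]
      if (!nzchar(w)) next
      v <- get0(w, envir = cache, ifnotfound = NULL)
      if (is.null(v)) {
        h <- .fnv1a32(w, seed)
        v <- with_local_seed(as.integer(h %% 2147483647), rnorm(dimension))
        v <- v / sqrt(sum(v^2))
        assign(w, v, envir = cache)
      }
      out[j, ] <- v
    }
    out
  }
  embedding_provider(dimension, lookup)
}

#' Build a fixed-shape document embedding matrix
#'
#' Stacks the word vectors of the first `max_tokens` tokens into a
#' `max_tokens x dimension` matrix: row *i* is the vector of token *i*,
#' rows beyond the document's token count are all-zero, and tokens beyond
#' `max_tokens` are ignored. The output shape is therefore constant
#' regardless of document length — the paragraph-level input plane of the
#' convolutional classifier (default geometry 100 tokens x 100 dimensions).
#'
#' @param tokens Character vector of tokens (one document).
#' @param provider An [embedding_provider()].
#' @param max_tokens Number of token rows (default 100).
#' @return A numeric `max_tokens x dimension` matrix.
#' @export
build_matrix <- function(tokens, provider, max_tokens = 100L) {
  stopifnot(inherits(provider, "embedding_provider"), max_tokens >= 1)
  d <- provider$dimension
  out <- matrix(0, max_tokens, d)
  n <- min(length(tokens), max_tokens)
  if (n > 0) out[seq_len(n), ] <- lookup_vectors(provider, tokens[seq_len(n)])
  out
}

#' Build the embedding array for a whole corpus
#'
#' @param token_list Named list of token vectors ([tokenize_corpus()]).
#' @param provider An [embedding_provider()].
#' @param max_tokens Number of token rows per document.
#' @return A numeric array of shape `max_tokens x dimension x n_documents`,
#'   with document ids as the third dimnames.
#' @export
build_matrices <- function(token_list, provider, max_tokens = 100L) {
  n <- length(token_list)
  d <- provider$dimension
  out <- array(0, dim = c(max_tokens, d, n),
               dimnames = list(NULL, NULL, names(token_list)))
  ## look up each distinct word once, then gather
  all_tok <- unlist(lapply(token_list, function(tk) {
    tk[seq_len(min(length(tk), max_tokens))]
  }), use.names = FALSE)
  vocab <- unique(all_tok)
  vecs <- if (length(vocab)) lookup_vectors(provider, vocab) else
    matrix(0, 0, d)
  idx <- new.env(parent = emptyenv(), size = max(1L, length(vocab)))
  for (i in seq_along(vocab)) assign(vocab[i], i, envir = idx)
  for (k in seq_len(n)) {
    tk <- token_list[[k]]
    m <- min(length(tk), max_tokens)
    if (m > 0) {
      rows <- vapply(tk[seq_len(m)], function(w) get(w, envir = idx), 1L)
      out[seq_len(m), , k] <- vecs[rows, , drop = FALSE]
    }
  }
  out
}
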