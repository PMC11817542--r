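#' Specification of a synthetic tweet corpus
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes about short health-related social-media texts: two topically
#' separated classes with a shared background vocabulary, strong class
#' imbalance (trustworthy information is the minority class), short
#' documents (at most 40 tokens), and optional label noise. Documents are
#' synthetic word-like strings (`"waab"`) disjoint from the stop-word list,
#' so pipeline behavior is isolated from linguistic artifacts. Class sizes
#' follow `minority_fraction` exactly (deterministic allocation, not
#' binomial draws), and everything is reproducible from `seed`.
#'
#' Optional noise switches (`duplicate_fraction`, `numeric_token_rate`,
#' `punct_burst_rate`), off by default, inject duplicates, numeric tokens
#' and punctuation bursts to exercise individual cleaning rules.
#'
#' @param n_docs Number of documents.
#' @param minority_fraction Fraction in (0, 0.5] of trustworthy (minority)
#'   documents.
#' @param vocab_size_per_class Words in each class-specific topic vocabulary
#'   (default 150).
#' @param shared_vocab_size Words in the shared background vocabulary
#'   (default 400). The background vocabulary is deliberately larger than a
#'   topic vocabulary, as in real text, which makes mean within-class cosine
#'   similarity increase with `topic_purity`.
#' @param doc_length_range Inclusive (min, max) token counts; max at most 40.
#' @param topic_purity Probability in `[0, 1]` that a token is drawn from
#'   the class vocabulary rather than the shared one.
#' @param label_noise Fraction in `[0, 0.5)` of observed labels flipped
#'   (ground truth is retained separately).
#' @param duplicate_fraction Fraction of documents replaced by copies of
#'   earlier documents.
#' @param numeric_token_rate Per-token probability of appending a numeric
#'   token.
#' @param punct_burst_rate Per-document probability of a punctuation burst.
#' @param seed Integer seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 2000L, minority_fraction = 0.15,
                        vocab_size_per_class = 150L, shared_vocab_size = 400L,
                        doc_length_range = c(8L, 30L), topic_purity = 0.9,
                        label_noise = 0, duplicate_fraction = 0,
                        numeric_token_rate = 0, punct_burst_rate = 0,
                        seed = 1L) {
  stopifnot(n_docs >= 1, minority_fraction > 0, minority_fraction <= 0.5,
            vocab_size_per_class >= 1, shared_vocab_size >= 0,
            length(doc_length_range) == 2L,
            doc_length_range[1] >= 1,
            doc_length_range[1] <= doc_length_range[2],
            doc_length_range[2] <= 40,
            topic_purity >= 0, topic_purity <= 1,
            label_noise >= 0, label_noise < 0.5,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            numeric_token_rate >= 0, numeric_token_rate <= 1,
            punct_burst_rate >= 0, punct_burst_rate <= 1)
  structure(list(n_docs = as.integer(n_docs),
                 minority_fraction = minority_fraction,
                 vocab_size_per_class = as.integer(vocab_size_per_class),
                 shared_vocab_size = as.integer(shared_vocab_size),
                 doc_length_range = as.integer(doc_length_range),
                 topic_purity = topic_purity, label_noise = label_noise,
                 duplicate_fraction = duplicate_fraction,
                 numeric_token_rate = numeric_token_rate,
                 punct_burst_rate = punct_burst_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# synthetic word-like token for integer i: "w" plus a base-26 letter code,
# all-alphabetic so tokens pass the cleaning cascade unchanged (digits
# would be stripped) and stay disjoint from the stop-word list
.word_id <- function(i) {
  vapply(i, function(k) {
    k <- k - 1L
    code <- character(3)
    for (j in 3:1) {
      code[j] <- letters[k %% 26L + 1L]
      k <- k %/% 26L
    }
    paste0("w", paste(code, collapse = ""))
  }, character(1))
}

# class vocabularies: trustworthy words, misinformation words, shared words
.spec_vocab <- function(spec) {
  v <- spec$vocab_size_per_class
  s <- spec$shared_vocab_size
  if (2L * v + s > 17576L) stop("vocabulary exhausted: reduce vocab sizes")
  list(trustworthy = .word_id(seq_len(v)),
       misinformation = .word_id(v + seq_len(v)),
       shared = if (s > 0) .word_id(2L * v + seq_len(s)) else character())
}

# sample one document's text for a given class; assumes RNG already seeded
.sample_doc <- function(spec, vocab, class) {
  len <- sample(seq(spec$doc_length_range[1], spec$doc_length_range[2]), 1L)
  own <- vocab[[class]]
  pool_shared <- length(vocab$shared) > 0
  from_own <- if (pool_shared) runif(len) < spec$topic_purity else
    rep(TRUE, len)
  toks <- character(len)
  toks[from_own] <- sample(own, sum(from_own), replace = TRUE)
  if (any(!from_own)) {
    toks[!from_own] <- sample(vocab$shared, sum(!from_own), replace = TRUE)
  }
  if (spec$numeric_token_rate > 0) {
    add <- runif(len) < spec$numeric_token_rate
    if (any(add)) {
      toks[add] <- paste0(toks[add], " ", sample(0:9999, sum(add),
                                                 replace = TRUE))
    }
  }
  txt <- paste(toks, collapse = " ")
  if (spec$punct_burst_rate > 0 && runif(1) < spec$punct_burst_rate) {
    txt <- paste0(txt, " !!!???")
  }
  txt
}

#' Generate a labeled synthetic corpus with ground truth
#'
#' Draws `n_docs` documents per [corpus_spec()]: exactly
#' `round(n_docs * minority_fraction)` trustworthy (minority) documents and
#' the rest misinformation, each a bag of class-topic and shared background
#' words. When `label_noise > 0`, exactly that (rounded) fraction of observed
#' labels is flipped; the unflipped truth is returned alongside. The same
#' spec and seed reproduce the corpus byte for byte.
#'
#' @param spec A [corpus_spec()].
#' @param id_prefix Prefix for document ids (default `"syn"`).
#' @return A list with `corpus` (observed labels) and `truth` (data.frame of
#'   id, true_label, flipped).
#' @export
generate_corpus <- function(spec, id_prefix = "syn") {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- .spec_vocab(spec)
  n <- spec$n_docs
  n_min <- max(1L, round(n * spec$minority_fraction))
  true_label <- rep(c("trustworthy", "misinformation"), c(n_min, n - n_min))
  with_local_seed(spec$seed, {
    true_label <- sample(true_label)  # interleave classes
    texts <- vapply(true_label, function(cl) .sample_doc(spec, vocab, cl),
                    character(1), USE.NAMES = FALSE)
    if (spec$duplicate_fraction > 0 && n > 1) {
      n_dup <- round(n * spec$duplicate_fraction)
      if (n_dup > 0) {
        tgt <- sample(2:n, min(n_dup, n - 1L))
        src <- vapply(tgt, function(i) sample(seq_len(i - 1L), 1L), 1L)
        texts[tgt] <- texts[src]
        true_label[tgt] <- true_label[src]
      }
    }
    flipped <- rep(FALSE, n)
    n_flip <- round(n * spec$label_noise)
    if (n_flip > 0) flipped[sample(n, n_flip)] <- TRUE
  })
  observed <- ifelse(flipped,
                     ifelse(true_label == "trustworthy", "misinformation",
                            "trustworthy"),
                     true_label)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  corpus <- as_corpus(data.frame(
    id = ids, text = texts, raw_label = true_label, label = observed,
    source = "synthetic", stringsAsFactors = FALSE))
  list(corpus = corpus,
       truth = data.frame(id = ids, true_label = true_label,
                          flipped = flipped, stringsAsFactors = FALSE))
}

#' Generate a verified seed sample and an unlabeled candidate pool
#'
#' Emulates the small manually fact-checked sample used for threshold
#' calibration: `verified_split[1]` verified-trustworthy plus
#' `verified_split[2]` verified-misinformation documents (default 180 + 70
#' = 250), drawn from the same class-conditional text model as
#' [generate_corpus()], together with a pool of unlabeled candidate
#' documents whose hidden ground truth is returned for calibration-recovery
#' tests.
#'
#' @param spec A [corpus_spec()]; its vocabularies, length range, purity and
#'   seed govern the generated texts.
#' @param n_verified Total verified sample size; must equal
#'   `sum(verified_split)`.
#' @param verified_split Integer pair (trustworthy count, misinformation
#'   count).
#' @param n_candidates Size of the unlabeled candidate pool (default 2000).
#' @param candidate_minority_fraction Fraction of candidates whose hidden
#'   truth is trustworthy (default 0.5).
#' @return A list with `verified` (corpus with verified labels), `candidates`
#'   (corpus labeled `"unlabeled"`), and `candidate_truth` (data.frame id,
#'   true_label).
#' @export
generate_seed_sets <- function(spec, n_verified = 250L,
                               verified_split = c(180L, 70L),
                               n_candidates = 2000L,
                               candidate_minority_fraction = 0.5) {
  stopifnot(inherits(spec, "corpus_spec"), length(verified_split) == 2L,
            all(verified_split >= 0), n_candidates >= 0)
  if (sum(verified_split) > n_verified) {
    stop("verified_split counts exceed n_verified")
  }
  if (sum(verified_split) != n_verified) {
    stop("verified_split must sum to n_verified")
  }
  vocab <- .spec_vocab(spec)
  ver_label <- rep(c("trustworthy", "misinformation"), verified_split)
  n_cand_min <- round(n_candidates * candidate_minority_fraction)
  cand_truth <- rep(c("trustworthy", "misinformation"),
                    c(n_cand_min, n_candidates - n_cand_min))
  with_local_seed(spec$seed + 1L, {
    ver_text <- vapply(ver_label, function(cl) .sample_doc(spec, vocab, cl),
                       character(1), USE.NAMES = FALSE)
    cand_truth <- sample(cand_truth)
    cand_text <- vapply(cand_truth, function(cl) .sample_doc(spec, vocab, cl),
                        character(1), USE.NAMES = FALSE)
  })
  verified <- as_corpus(data.frame(
    id = sprintf("seed%04d", seq_along(ver_label)), text = ver_text,
    raw_label = ver_label, label = ver_label, source = "verified",
    stringsAsFactors = FALSE))
  candidates <- as_corpus(data.frame(
    id = sprintf("cand%05d", seq_len(n_candidates)),
    text = if (n_candidates) cand_text else character(),
    raw_label = rep("", n_candidates),
    label = rep("unlabeled", n_candidates),
    source = rep("candidate_pool", n_candidates),
    stringsAsFactors = FALSE))
  list(verified = verified, candidates = candidates,
       candidate_truth = data.frame(id = candidates$id,
                                    true_label = cand_truth,
                                    stringsAsFactors = FALSE))
}
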