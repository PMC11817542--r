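#' Term-document statistics for TF-IDF weighting
#'
#' Computes the vocabulary and smoothed document frequencies of a cleaned,
#' tokenized corpus. The inverse-document-frequency uses the smoothed form
#' `idf(t) = log((1 + N) / (1 + df(t))) + 1`, which is strictly positive even
#' for a term present in every document.
#'
#' @param token_list Named list of token vectors ([tokenize_corpus()]).
#' @return A list with `vocabulary`, `df` (document frequencies), `idf`, and
#'   `n_docs`, of class `corpus_stats`.
#' @export
corpus_stats <- function(token_list) {
  stopifnot(is.list(token_list))
  vocab <- sort(unique(unlist(token_list, use.names = FALSE)))
  if (!length(vocab)) stop("empty vocabulary: no tokens in corpus")
  df <- integer(length(vocab))
  names(df) <- vocab
  for (tk in token_list) {
    u <- unique(tk)
    df[u] <- df[u] + 1L
  }
  n <- length(token_list)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = vocab, df = df, idf = idf, n_docs = n),
            class = "corpus_stats")
}

#' Sparse TF-IDF document vectors
#'
#' Represents each document as a sparse nonnegative term-weight vector over
#' the corpus vocabulary: raw term counts scaled by the smoothed inverse
#' document frequency from [corpus_stats()]. This is the representation used
#' both for the cosine-similarity augmentation step and for the classic
#' (tree/forest/SVM) baselines, so the two share one vocabulary. Terms absent
#' from `stats$vocabulary` are dropped.
#'
#' @param token_list Named list of token vectors.
#' @param stats A [corpus_stats()] object; defaults to statistics of
#'   `token_list` itself. Pass shared statistics when vectorizing several
#'   document sets into one space.
#' @return A `dgCMatrix` of shape documents x vocabulary with non-negative
#'   weights; rows named by document id.
#' @export
doc_vectors <- function(token_list, stats = corpus_stats(token_list)) {
  stopifnot(inherits(stats, "corpus_stats"))
  vocab <- stats$vocabulary
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(token_list)) {
    tk <- token_list[[k]]
    tk <- tk[tk %in% vocab]
    if (!length(tk)) next
    tab <- table(tk)
    j <- match(names(tab), vocab)
    ii <- c(ii, rep.int(k, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, as.numeric(tab) * stats$idf[j])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(token_list), length(vocab)),
                       dimnames = list(names(token_list), vocab))
}

#' Cosine similarity between document vectors
#'
#' For nonnegative term weights the cosine lies in `[0, 1]`. Rows that are
#' entirely zero (documents that cleaned to nothing) are an error, since
#' their direction is undefined.
#'
#' @param x A documents x terms matrix (sparse or dense), or a single vector.
#' @param y Optional second matrix/vector over the same vocabulary; defaults
#'   to `x`.
#' @return A `nrow(x) x nrow(y)` dense matrix of similarities (a 1x1 matrix
#'   collapses to a scalar).
#' @export
cosine_similarity <- function(x, y = NULL) {
  as_rows <- function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1) else m
  }
  x <- as_rows(x)
  y <- if (is.null(y)) x else as_rows(y)
  nx <- sqrt(Matrix::rowSums(x^2))
  ny <- sqrt(Matrix::rowSums(y^2))
  if (any(nx == 0) || any(ny == 0)) {
    stop("zero document vector (empty document) has no cosine direction")
  }
  s <- as.matrix(Matrix::tcrossprod(x, y)) / outer(nx, ny)
  ## clamp tiny floating-point excursions
  s[s > 1] <- 1; s[s < 0] <- 0
  if (all(dim(s) == c(1L, 1L))) s[1, 1] else s
}

#' Similarity of documents to a verified seed set
#'
#' Scores each candidate document against a set of verified trustworthy seed
#' documents. The default aggregation is the maximum cosine over seeds — a
#' nearest-trustworthy-example criterion — with mean aggregation available.
#'
#' @param docs Documents x terms weight matrix (or single vector).
#' @param seeds Seeds x terms weight matrix over the same vocabulary.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @param exclude_self Set the diagonal to `NA` before aggregating when
#'   `docs` and `seeds` are the same set (leave-one-out scoring); requires
#'   equal row counts.
#' @return Numeric vector of scores in `[0, 1]`, one per document row.
#' @export
similarity_to_seeds <- function(docs, seeds, aggregate = c("max", "mean"),
                                exclude_self = FALSE) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  if (nrow(seeds) == 0) stop("empty seed set")
  s <- cosine_similarity(docs, seeds)
  if (is.null(dim(s))) s <- matrix(s, 1, 1)
  if (exclude_self) {
    if (nrow(s) != ncol(s)) stop("exclude_self needs docs == seeds")
    diag(s) <- NA_real_
  }
  f <- if (aggregate == "max") function(r) max(r, na.rm = TRUE) else
    function(r) mean(r, na.rm = TRUE)
  apply(s, 1, f)
}

#' Calibrate the similarity threshold on a verified sample
#'
#' Given similarity scores of verified documents against the trustworthy seed
#' set, tallies — for each candidate threshold `t` — how many verified
#' trustworthy (`true_count`) and verified misinformation (`false_count`)
#' documents score strictly above `t`, and the resulting precision
#' `true / (true + false)`, the fraction of would-be injected documents that
#' are verified trustworthy. Precision is undefined (NA) where no document
#' exceeds the threshold, and such thresholds are excluded from the choice.
#' The chosen threshold maximizes precision, with ties broken toward the
#' larger injected count, subject to a configurable minimum injected count;
#' if no threshold qualifies, `chosen` is `NA` with a warning.
#'
#' @param scores Numeric similarity scores of the verified documents.
#' @param labels Their verified labels, `"trustworthy"`/`"misinformation"`.
#' @param thresholds Strictly increasing candidate thresholds (default grid
#'   `0.1, 0.15, ..., 0.4`).
#' @param min_injected Minimum number of verified documents that must exceed
#'   a threshold for it to be eligible (default 1).
#' @return An object of class `similarity_calibration`: a list with `table`
#'   (threshold, true_count, false_count, precision) and `chosen`.
#' @export
calibrate_threshold <- function(scores, labels,
                                thresholds = c(0.1, 0.15, 0.2, 0.25,
                                               0.3, 0.35, 0.4),
                                min_injected = 1L) {
  stopifnot(length(scores) == length(labels))
  if (any(!labels %in% c("trustworthy", "misinformation"))) {
    stop("verified labels must be trustworthy or misinformation")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  tc <- vapply(thresholds, function(t) {
    sum(scores > t & labels == "trustworthy")
  }, integer(1))
  fc <- vapply(thresholds, function(t) {
    sum(scores > t & labels == "misinformation")
  }, integer(1))
  tot <- tc + fc
  prec <- ifelse(tot > 0, tc / tot, NA_real_)
  eligible <- which(tot >= max(1L, min_injected) & !is.na(prec))
  if (!length(eligible)) {
    warning("no verified document exceeds any threshold; 'chosen' is NA")
    chosen <- NA_real_
  } else {
    best <- max(prec[eligible])
    tied <- eligible[prec[eligible] == best]
    chosen <- thresholds[tied[which.max(tot[tied])]]
  }
  structure(list(
    table = data.frame(threshold = thresholds, true_count = tc,
                       false_count = fc, precision = prec),
    chosen = chosen, min_injected = min_injected),
    class = "similarity_calibration")
}

#' @export
print.similarity_calibration <- function(x, digits = 2, ...) {
  cat("Similarity-threshold calibration (verified counts above threshold)\n")
  tab <- x$table
  tab$precision <- round(tab$precision, digits)
  tab$chosen <- ifelse(tab$threshold == x$chosen & !is.na(x$chosen), "*", "")
  print(tab, row.names = FALSE)
  cat("chosen threshold:", x$chosen, "\n")
  invisible(x)
}

#' Write a calibration table to CSV
#'
#' Columns: threshold, true_count, false_count, precision, chosen.
#'
#' @param calibration A [calibrate_threshold()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "similarity_calibration"))
  tab <- calibration$table
  tab$chosen <- !is.na(calibration$chosen) &
    tab$threshold == calibration$chosen
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Inject high-similarity candidates into the trustworthy class
#'
#' Appends every candidate whose similarity score is *strictly* greater than
#' the threshold to the corpus with label `"trustworthy"` and provenance flag
#' `injected = TRUE`. Pre-existing documents are never altered, removed, or
#' relabeled. Candidates whose id already exists in the corpus are skipped
#' and reported, not duplicated.
#'
#' @param corpus Corpus data.frame to augment.
#' @param candidates Corpus data.frame of candidate documents.
#' @param scores Similarity score per candidate row.
#' @param threshold Injection threshold (> 0); since similarities are at
#'   most 1, any threshold of 1 or more injects nothing.
#' @return A list with `corpus` (augmented; gains a logical `injected`
#'   column), `report` (data.frame of injected id and score) and
#'   `skipped` (ids skipped due to collision).
#' @export
inject_trustworthy <- function(corpus, candidates, scores, threshold) {
  stopifnot(length(scores) == nrow(candidates),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  corpus <- as_corpus(corpus)
  candidates <- as_corpus(candidates)
  if (is.null(corpus$injected)) corpus$injected <- rep(FALSE, nrow(corpus))
  sel <- scores > threshold
  dup <- candidates$id %in% corpus$id
  skipped <- candidates$id[sel & dup]
  if (length(skipped)) {
    message("skipping ", length(skipped),
            " candidate(s) whose id already exists in the corpus")
  }
  take <- sel & !dup
  add <- candidates[take, , drop = FALSE]
  report <- data.frame(id = add$id, score = scores[take],
                       stringsAsFactors = FALSE)
  if (nrow(add)) {
    add$label <- "trustworthy"
    add$injected <- TRUE
    corpus <- rbind(corpus, add)
    rownames(corpus) <- NULL
  }
  list(corpus = corpus, report = report, skipped = skipped)
}

#' Write an injection report as JSON-lines
#'
#' @param report The `report` data.frame from [inject_trustworthy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_injection_report <- function(report, path) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    as.character(jsonlite::toJSON(as.list(report[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
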