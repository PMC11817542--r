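#' End-to-end desk run: simulate, calibrate, augment, train, evaluate
#'
#' Runs the full analysis on a synthetic corpus: generate labeled documents
#' plus a verified seed sample and an unlabeled candidate pool; clean and
#' tokenize; score the verified sample and the candidates against the
#' verified-trustworthy seed documents by maximum TF-IDF cosine (seeds are
#' scored leave-one-out so their trivial self-similarity of 1 does not
#' inflate the calibration); calibrate the similarity threshold on the
#' verified sample; inject qualifying candidates into the *training*
#' portion as additional trustworthy documents; embed; train the
#' four-pathway convolutional classifier; and evaluate on a class-balanced
#' held-out test set (equal documents per class, so the majority-class
#' baseline is 50% and headroom above it is meaningful under class
#' imbalance). Injection is restricted to the training split to keep the
#' held-out evaluation free of label contamination.
#'
#' @param spec A [corpus_spec()] describing the synthetic corpus.
#' @param config A [tcn_config()]; its seed defaults to `seed`.
#' @param seed Master seed for splitting and modeling.
#' @param augment Inject similar candidates into the minority class
#'   (`TRUE`) or run the unaugmented control (`FALSE`).
#' @param provider Embedding provider (defaults to the seeded
#'   [hash_provider()] at the configured dimension).
#' @param n_candidates Size of the candidate pool (default 2000: a pool on the corpus scale, so augmentation can achieve its purpose of approximately balancing the classes).
#' @param n_verified,verified_split Verified sample composition, default
#'   250 split 180 trustworthy / 70 misinformation.
#' @param test_fraction Fraction of the *minority* class held out per class
#'   for the balanced test set (default 0.3).
#' @param thresholds Candidate threshold grid for calibration.
#' @param validation Validation fraction during training (default 0.15).
#' @param verbose Print progress.
#' @return An object of class `misinfo_pipeline` collecting the
#'   calibration, injection report, trained model, history, and evaluation
#'   (accuracy, majority baseline, AUC, per-class report, confusion).
#' @export
run_pipeline <- function(spec = corpus_spec(), config = NULL, seed = 1L,
                         augment = TRUE, provider = NULL,
                         n_candidates = 2000L, n_verified = 250L,
                         verified_split = c(180L, 70L),
                         test_fraction = 0.3,
                         thresholds = c(0.1, 0.15, 0.2, 0.25, 0.3,
                                        0.35, 0.4),
                         validation = 0.15, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(config)) config <- tcn_config(seed = seed)
  if (is.null(provider)) provider <- hash_provider(config$dims, seed)

  say("simulate: ", spec$n_docs, " documents")
  gen <- generate_corpus(spec)
  seeds <- generate_seed_sets(spec, n_verified = n_verified,
                              verified_split = verified_split,
                              n_candidates = n_candidates)
  corpus <- gen$corpus

  ## clean + tokenize everything into one shared vocabulary space
  toks_corpus <- tokenize_corpus(corpus)
  toks_verified <- tokenize_corpus(seeds$verified)
  toks_cand <- tokenize_corpus(seeds$candidates)
  stats <- corpus_stats(c(toks_corpus, toks_verified, toks_cand))

  ## similarity scoring against verified-trustworthy seeds
  say("calibrate: scoring verified sample and candidate pool")
  ver_vec <- doc_vectors(toks_verified, stats)
  seed_rows <- which(seeds$verified$label == "trustworthy")
  seed_vec <- ver_vec[seed_rows, , drop = FALSE]
  ver_scores <- numeric(nrow(ver_vec))
  ## leave-one-out for the trustworthy seeds themselves
  sim_all <- cosine_similarity(ver_vec, seed_vec)
  for (i in seq_len(nrow(ver_vec))) {
    s <- sim_all[i, ]
    j <- match(i, seed_rows)
    if (!is.na(j)) s[j] <- NA
    ver_scores[i] <- max(s, na.rm = TRUE)
  }
  calibration <- calibrate_threshold(ver_scores, seeds$verified$label,
                                     thresholds = thresholds)
  threshold <- calibration$chosen
  if (is.na(threshold)) threshold <- 0.3

  cand_vec <- doc_vectors(toks_cand, stats)
  nonzero <- Matrix::rowSums(cand_vec) > 0
  cand_scores <- rep(0, nrow(cand_vec))
  if (any(nonzero)) {
    cand_scores[nonzero] <- similarity_to_seeds(
      cand_vec[nonzero, , drop = FALSE], seed_vec)
  }

  ## balanced held-out test split (stratified, seeded)
  y_all <- ifelse(corpus$label == "misinformation", 1, 0)
  n_test_per_class <- max(1L, round(min(table(y_all)) * test_fraction))
  test_idx <- with_local_seed(seed + 101L, {
    c(sample(which(y_all == 0), n_test_per_class),
      sample(which(y_all == 1), n_test_per_class))
  })
  train_corpus <- corpus[-test_idx, , drop = FALSE]
  test_corpus <- corpus[test_idx, , drop = FALSE]

  injection <- NULL
  if (augment) {
    say("augment: injecting candidates with similarity > ", threshold)
    inj <- inject_trustworthy(train_corpus, seeds$candidates,
                              cand_scores, threshold)
    train_corpus <- inj$corpus
    injection <- inj$report
  }

  say("embed: building ", config$max_tokens, "x", config$dims, " matrices")
  toks_train <- tokenize_corpus(train_corpus)
  toks_test <- toks_corpus[test_corpus$id]
  x_train <- build_matrices(toks_train, provider, config$max_tokens)
  x_test <- build_matrices(toks_test, provider, config$max_tokens)
  y_train <- ifelse(train_corpus$label == "misinformation", 1, 0)
  y_test <- ifelse(test_corpus$label == "misinformation", 1, 0)

  say("train: ", length(y_train), " documents, ", config$epochs, " epochs")
  model <- textconvonet(config)
  model <- train_textconvonet(model, x_train, y_train,
                              validation = validation, verbose = verbose)

  say("evaluate: ", length(y_test), " balanced test documents")
  scores <- predict(model, x_test)
  pred <- ifelse(scores > 0.5, "misinformation", "trustworthy")
  truth <- test_corpus$label
  cm <- confusion(truth, pred, positive = "misinformation")
  overall <- metrics(cm)
  per_class <- per_class_report(truth, pred,
                                classes = c("trustworthy",
                                            "misinformation"))
  auc <- roc_auc(scores, truth, positive = "misinformation")
  majority <- max(table(truth)) / length(truth)

  structure(list(
    spec = spec, config = config, seed = seed, augment = augment,
    calibration = calibration, threshold = threshold,
    injection = injection,
    n_injected = if (is.null(injection)) 0L else nrow(injection),
    model = model, history = model$history,
    scores = scores, truth = truth,
    accuracy = overall$accuracy, metrics = overall,
    per_class = per_class, confusion = cm, roc_auc = auc,
    majority_accuracy = majority,
    minority_recall = per_class$recall[per_class$class == "trustworthy"],
    n_train = length(y_train), n_test = length(y_test)),
    class = "misinfo_pipeline")
}

#' @export
print.misinfo_pipeline <- function(x, ...) {
  cat("End-to-end misinformation classification run",
      if (x$augment) "(augmented)" else "(unaugmented control)", "\n")
  cat(sprintf("corpus: %d docs (minority fraction %.2f), train %d / test %d\n",
              x$spec$n_docs, x$spec$minority_fraction, x$n_train, x$n_test))
  cat(sprintf("threshold %.2f, injected %d candidates\n",
              x$threshold, x$n_injected))
  cat(sprintf("test accuracy %.4f (majority baseline %.4f), AUC %.4f\n",
              x$accuracy, x$majority_accuracy, x$roc_auc))
  cat(sprintf("minority (trustworthy) recall %.4f\n", x$minority_recall))
  invisible(x)
}
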