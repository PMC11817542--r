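test_that("classic features equal the augmentation document vectors", {
  toks <- list(d1 = c("covid", "real", "covid"), d2 = c("mask", "real"))
  st <- corpus_stats(toks)
  f <- featurize_classic(toks, st)
  v <- as.matrix(doc_vectors(toks, st))
  expect_equal(unname(f), unname(v))
  expect_equal(nrow(f), 2)
  ## identical documents vectorize identically
  toks2 <- list(a = c("x1", "y1"), b = c("x1", "y1"))
  f2 <- featurize_classic(toks2)
  expect_equal(f2[1, ], f2[2, ])
  expect_error(featurize_classic(list()), "empty")
})

test_that("a decision tree memorizes a small consistent training set", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(0, 0, 1, 1)  # depends on f1 alone
  fit <- fit_baseline(baseline_spec("decision_tree", seed = 1), x, y,
                      control = rpart::rpart.control(minsplit = 2, cp = 0))
  expect_equal(as.numeric(predict(fit, x) > 0.5), y)
})

test_that("baselines are deterministic given spec and seed", {
  sep <- make_separable_tokens(80, seed = 3, purity = 0.8)
  x <- featurize_classic(sep$tokens)
  for (kind in c("decision_tree", "random_forest", "svm")) {
    f1 <- fit_baseline(baseline_spec(kind, seed = 5), x, sep$y)
    f2 <- fit_baseline(baseline_spec(kind, seed = 5), x, sep$y)
    expect_identical(predict(f1, x), predict(f2, x))
  }
})

test_that("every baseline beats the majority class on separable data", {
  sep <- make_separable_tokens(240, seed = 4, purity = 0.9)
  x <- featurize_classic(sep$tokens)
  y <- sep$y
  tr <- seq_len(180); te <- 181:240
  majority <- max(mean(y[te]), 1 - mean(y[te]))
  accs <- c()
  for (kind in c("decision_tree", "random_forest", "svm", "stacking")) {
    fit <- fit_baseline(baseline_spec(kind, seed = 2),
                        x[tr, , drop = FALSE], y[tr])
    acc <- mean((predict(fit, x[te, , drop = FALSE]) > 0.5) == (y[te] > 0.5))
    accs[kind] <- acc
    expect_gt(acc, majority)
    ## single-document prediction works for every kind
    expect_length(predict(fit, x[te[1], , drop = FALSE]), 1)
  }
  ## stacking is at least as good as its best base learner - 2 points
  expect_gte(accs["stacking"],
             max(accs[c("decision_tree", "random_forest", "svm")]) - 0.02)

  ## recurrent baselines on token-index sequences (small settings)
  vocab <- corpus_stats(sep$tokens)$vocabulary
  ids <- token_indices(sep$tokens, vocab, max_tokens = 20)
  for (kind in c("gru", "lstm")) {
    fit <- fit_baseline(baseline_spec(kind, recurrent_layers = 1, cells = 8,
                                      seed = 2),
                        ids[tr, ], y[tr],
                        epochs = 4, batch_size = 32, learning_rate = 0.02,
                        embed_dim = 8)
    acc <- mean((predict(fit, ids[te, ]) > 0.5) == (y[te] > 0.5))
    expect_gt(acc, majority)
  }
})

test_that("recurrent models train reproducibly with valid histories", {
  sep <- make_separable_tokens(60, seed = 6, purity = 0.9)
  vocab <- corpus_stats(sep$tokens)$vocabulary
  ids <- token_indices(sep$tokens, vocab, max_tokens = 15)
  f1 <- fit_rnn(ids, sep$y, kind = "gru", layers = 2, cells = 6,
                epochs = 3, batch_size = 16, learning_rate = 0.01,
                embed_dim = 6, validation = 0.2, seed = 8)
  f2 <- fit_rnn(ids, sep$y, kind = "gru", layers = 2, cells = 6,
                epochs = 3, batch_size = 16, learning_rate = 0.01,
                embed_dim = 6, validation = 0.2, seed = 8)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(f1$history$loss >= 0))
  expect_true(all(f1$history$val_accuracy >= 0 &
                    f1$history$val_accuracy <= 1))
  p <- predict(f1, ids)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict(f1, ids))
  ## lstm path too
  fl <- fit_rnn(ids, sep$y, kind = "lstm", layers = 1, cells = 6,
                epochs = 2, batch_size = 16, embed_dim = 6, seed = 8)
  expect_equal(nrow(fl$history), 2)
  expect_error(fit_rnn(ids, rep(1, nrow(ids)), kind = "gru"),
               "single class")
})

test_that("token indices pad, truncate, and mask out-of-vocabulary", {
  toks <- list(a = c("x", "y", "z"), b = c("y", "unknown"))
  ids <- token_indices(toks, vocabulary = c("x", "y", "z"), max_tokens = 4)
  expect_equal(dim(ids), c(2, 4))
  expect_equal(ids[1, ], c(1, 2, 3, 0))
  expect_equal(ids[2, ], c(2, 0, 0, 0))
})

test_that("spec construction guards recurrent-only fields", {
  expect_error(baseline_spec("svm", cells = 32), "recurrent")
  s <- baseline_spec("lstm", recurrent_layers = 2, cells = 64)
  expect_equal(s$cells, 64)
})

test_that("the overfitting detector applies gap and patience rules", {
  conv <- data.frame(epoch = 1:3, loss = c(0.6, 0.4, 0.3),
                     accuracy = c(0.90, 0.95, 0.99),
                     val_loss = c(0.62, 0.45, 0.33),
                     val_accuracy = c(0.88, 0.93, 0.97))
  expect_false(detect_overfitting(conv)$flag)

  div <- data.frame(epoch = 1:4, loss = c(0.6, 0.4, 0.3, 0.25),
                    accuracy = c(0.80, 0.95, 0.99, 0.99),
                    val_loss = c(0.62, 0.70, 0.80, 0.90),
                    val_accuracy = c(0.75, 0.70, 0.66, 0.64))
  verdict <- detect_overfitting(div)
  expect_true(verdict$flag)
  expect_equal(verdict$epoch, 2)

  single <- data.frame(epoch = 1, loss = 0.6, accuracy = 0.99,
                       val_loss = 0.9, val_accuracy = 0.5)
  expect_false(detect_overfitting(single)$flag)

  ## rising validation loss with falling training loss also counts
  leak <- data.frame(epoch = 1:4, loss = c(0.6, 0.5, 0.4, 0.3),
                     accuracy = c(0.7, 0.75, 0.8, 0.85),
                     val_loss = c(0.6, 0.65, 0.7, 0.75),
                     val_accuracy = c(0.7, 0.69, 0.68, 0.70))
  expect_true(detect_overfitting(leak)$flag)
})
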