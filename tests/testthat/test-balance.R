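test_that("TF-IDF document vectors behave as specified", {
  ## single-document corpus: two positive weights
  v <- doc_vectors(list(d1 = c("covid", "real")))
  expect_equal(Matrix::nnzero(v), 2)
  expect_true(all(v@x > 0))

  ## a term present in every document keeps a strictly positive weight
  toks <- list(a = c("covid", "hoax"), b = c("covid", "cure"),
               c = c("covid", "mask"))
  st <- corpus_stats(toks)
  expect_true(st$idf[["covid"]] > 0)
  m <- doc_vectors(toks, st)
  expect_true(all(m[, "covid"] > 0))

  ## disjoint vocabularies are orthogonal
  dv <- doc_vectors(list(x = c("alpha", "beta"), y = c("gamma", "delta")))
  expect_equal(cosine_similarity(dv[1, ], dv[2, ]), 0)

  expect_error(corpus_stats(list(a = character())), "empty vocabulary")
})

test_that("cosine similarity matches hand calculations and bounds", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("seed similarity aggregates by maximum (or mean) over seeds", {
  seeds <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(similarity_to_seeds(c(1, 0, 0), seeds), 1)
  expect_equal(similarity_to_seeds(c(0, 0, 1) * 2, seeds), 1)
  doc <- c(2, 1, 0)
  expected <- max(cosine_similarity(doc, seeds[1, ]),
                  cosine_similarity(doc, seeds[2, ]),
                  cosine_similarity(doc, seeds[3, ]))
  expect_equal(unname(similarity_to_seeds(doc, seeds)), expected)
  expect_equal(unname(similarity_to_seeds(doc, seeds, aggregate = "mean")),
               mean(c(cosine_similarity(doc, seeds[1, ]),
                      cosine_similarity(doc, seeds[2, ]),
                      cosine_similarity(doc, seeds[3, ]))))
  expect_error(similarity_to_seeds(doc, seeds[0, , drop = FALSE]),
               "empty seed")
})

test_that("threshold calibration equals a brute-force tally exactly", {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(31)
  ## synthetic verified set with known class-conditional score distributions
  scores <- c(rbeta(180, 5, 2), rbeta(70, 2, 5))
  labels <- rep(c("trustworthy", "misinformation"), c(180, 70))
  grid <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4)
  cal <- calibrate_threshold(scores, labels, grid)
  for (i in seq_along(grid)) {
    tc <- sum(scores > grid[i] & labels == "trustworthy")
    fc <- sum(scores > grid[i] & labels == "misinformation")
    expect_identical(cal$table$true_count[i], tc)
    expect_identical(cal$table$false_count[i], fc)
    expect_equal(cal$table$precision[i], tc / (tc + fc))
  }
  ## counts are non-increasing in the threshold
  expect_true(all(diff(cal$table$true_count) <= 0))
  expect_true(all(diff(cal$table$false_count) <= 0))
  ## chosen = argmax precision, ties toward the larger injected count
  tot <- cal$table$true_count + cal$table$false_count
  best <- max(cal$table$precision, na.rm = TRUE)
  tied <- which(cal$table$precision == best & tot >= 1)
  expect_equal(cal$chosen, grid[tied[which.max(tot[tied])]])
})

test_that("empirical calibration precision tracks its analytic value", {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(99)
  n1 <- 1800; n0 <- 700  # larger sample tightens the standard error
  scores <- c(rbeta(n1, 5, 2), rbeta(n0, 2, 5))
  labels <- rep(c("trustworthy", "misinformation"), c(n1, n0))
  grid <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  cal <- calibrate_threshold(scores, labels, grid)
  for (i in seq_along(grid)) {
    s1 <- 1 - pbeta(grid[i], 5, 2)
    s0 <- 1 - pbeta(grid[i], 2, 5)
    analytic <- n1 * s1 / (n1 * s1 + n0 * s0)
    n_exc <- cal$table$true_count[i] + cal$table$false_count[i]
    se <- sqrt(analytic * (1 - analytic) / n_exc)
    expect_lt(abs(cal$table$precision[i] - analytic), 3 * se + 1e-12)
  }
})

test_that("degenerate calibrations warn and withhold a choice", {
  expect_warning(
    cal <- calibrate_threshold(c(0.01, 0.02), c("trustworthy",
                                                "misinformation"),
                               thresholds = c(0.5, 0.9)),
    "no verified document")
  expect_true(is.na(cal$chosen))
  expect_true(all(is.na(cal$table$precision)))
  expect_error(calibrate_threshold(0.5, "trustworthy", c(0.3, 0.2)),
               "increasing")
})

test_that("injection is strict, conservative, and monotone in threshold", {
  corpus <- as_corpus(data.frame(id = paste0("c", 1:4),
                                 text = paste("text", 1:4),
                                 label = c("trustworthy", rep("misinformation", 3))))
  cands <- as_corpus(data.frame(id = paste0("k", 1:3),
                                text = paste("cand", 1:3)))
  ## "over the threshold" is strict: 0.30 exactly does not qualify
  out <- inject_trustworthy(corpus, cands, c(0.31, 0.30, 0.05), 0.3)
  expect_equal(out$report$id, "k1")
  expect_equal(nrow(out$corpus), 5)
  added <- out$corpus[out$corpus$id == "k1", ]
  expect_equal(added$label, "trustworthy")
  expect_true(added$injected)
  ## pre-existing documents are untouched
  expect_equal(out$corpus$id[1:4], corpus$id)
  expect_equal(out$corpus$label[1:4], corpus$label)
  ## minority share strictly increases when something is injected
  share_before <- mean(corpus$label == "trustworthy")
  share_after <- mean(out$corpus$label == "trustworthy")
  expect_gt(share_after, share_before)

  ## nothing exceeds a threshold of 1
  none <- inject_trustworthy(corpus, cands, c(0.9, 1.0, 0.99), 1.0)
  expect_equal(nrow(none$report), 0)

  ## monotonicity: the injected set at a higher threshold is a subset
  scores <- c(0.15, 0.35, 0.55, 0.75, 0.95)
  cands5 <- as_corpus(data.frame(id = paste0("m", 1:5),
                                 text = paste("c", 1:5)))
  lo <- inject_trustworthy(corpus, cands5, scores, 0.2)$report$id
  hi <- inject_trustworthy(corpus, cands5, scores, 0.4)$report$id
  expect_true(all(hi %in% lo))
  expect_lte(length(hi), length(lo))

  ## id collisions are skipped with a message, never duplicated
  clash <- as_corpus(data.frame(id = c("c1", "k9"), text = c("dup", "new")))
  expect_message(res <- inject_trustworthy(corpus, clash, c(0.9, 0.9), 0.5),
                 "skipping")
  expect_equal(res$skipped, "c1")
  expect_equal(sum(res$corpus$id == "c1"), 1)
})

test_that("calibration tables round-trip through their CSV report", {
  cal <- calibrate_threshold(c(0.8, 0.6, 0.2, 0.9),
                             c("trustworthy", "misinformation",
                               "trustworthy", "trustworthy"),
                             thresholds = c(0.3, 0.5, 0.7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, f)
  back <- read.csv(f)
  expect_equal(back$true_count, cal$table$true_count)
  expect_equal(back$threshold[back$chosen], cal$chosen)
})
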