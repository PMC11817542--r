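test_that("confusion counts come out of direct enumeration", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1), positive = 1)
  expect_equal(cm[c("TP", "FN", "TN", "FP")],
               list(TP = 1, FN = 1, TN = 1, FP = 1))
  perfect <- confusion(c("a", "b", "a"), c("a", "b", "a"), positive = "a")
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_error(confusion(character(), character()), "no labels")
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("the four metrics follow their defining formulas", {
  cm <- structure(list(TP = 3, TN = 4, FP = 1, FN = 2, positive = 1),
                  class = "confusion_matrix")
  m <- metrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)

  allpos <- structure(list(TP = 9, TN = 0, FP = 0, FN = 0, positive = 1),
                      class = "confusion_matrix")
  expect_equal(unlist(metrics(allpos)), c(accuracy = 1, precision = 1,
                                          recall = 1, f1 = 1))

  ## zero denominators are absent, never zero
  nopred <- structure(list(TP = 0, TN = 5, FP = 0, FN = 3, positive = 1),
                      class = "confusion_matrix")
  mn <- metrics(nopred)
  expect_true(is.na(mn$precision))
  expect_true(is.na(mn$f1))
  expect_equal(mn$recall, 0)
})

test_that("the F measure is the harmonic mean at any scale", {
  ## printed per-class pair: precision 0.88, recall 0.94 rounds to 0.91
  expect_equal(round(f1_score(0.88, 0.94), 2), 0.91)
  ## scale equivariance (percent vs fraction)
  expect_equal(f1_score(88, 94) / 100, f1_score(0.88, 0.94))
  expect_true(is.na(f1_score(0, 0)))
  ## vectorized
  expect_equal(f1_score(c(0.5, 1), c(0.5, 1)), c(0.5, 1))
})

test_that("AUC is the Mann-Whitney concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(1, 0), 3), positive = 1), 0.5)
  ## positives {0.9, 0.4}, negatives {0.5, 0.1}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0), positive = 1),
               0.75)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1), positive = 1), "both classes")
})

test_that("AUC equals brute-force all-pairs concordance on random sets", {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    truth <- sample(c("pos", "neg"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) truth[1:2] <- c("pos", "neg")
    ## discretized scores force ties to exercise the half-weight rule
    scores <- round(runif(n), 2)
    expect_equal(roc_auc(scores, truth, positive = "pos"),
                 auc_bruteforce(scores, truth, positive = "pos"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(5)
  truth <- rep(c(1, 0), c(30, 50))
  scores <- c(rnorm(30, 1), rnorm(50))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth, positive = 1), ref,
               tolerance = 1e-12)
})

test_that("ROC points span (0,0) to (1,1) monotonically", {
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.2)
  truth <- c(1, 1, 0, 1, 0)
  pts <- roc_points(scores, truth, positive = 1)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("stratified k-fold tests every document once and averages folds", {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(2)
  y <- rep(c("misinformation", "trustworthy"), c(60, 40))
  x <- ifelse(y == "misinformation", 1, 0) + rnorm(100, sd = 0.6)
  train_fun <- function(idx) mean(x[idx][y[idx] == "misinformation"]) / 2 +
    mean(x[idx][y[idx] == "trustworthy"]) / 2
  predict_fun <- function(model, idx) as.numeric(x[idx] > model)
  res <- kfold_cv(y, train_fun, predict_fun, k = 5, seed = 9)
  expect_equal(nrow(res$folds), 5)
  expect_equal(sum(res$folds$n), 100)
  expect_equal(sort(unique(res$assignment)), 1:5)
  expect_equal(as.vector(table(res$assignment)), rep(20, 5))
  ## aggregate is the unweighted mean of per-fold metrics
  expect_equal(unname(res$aggregate["accuracy"]),
               mean(res$folds$accuracy))
  ## identical seed reproduces the assignment
  res2 <- kfold_cv(y, train_fun, predict_fun, k = 5, seed = 9)
  expect_identical(res$assignment, res2$assignment)
  ## a class smaller than k is refused
  expect_error(kfold_cv(rep(c("a", "b"), c(97, 3)), train_fun,
                        predict_fun, k = 5), "fewer than k")
})

test_that("per-class reports are one-vs-rest and symmetric", {
  pc <- per_class_report(c("m", "m", "t", "t"), c("m", "t", "t", "m"),
                         classes = c("m", "t"))
  expect_equal(pc$precision, c(0.5, 0.5))
  perfect <- per_class_report(c("m", "t"), c("m", "t"),
                              classes = c("m", "t"))
  expect_true(all(unlist(perfect[, -1]) == 1))
  ## swapping the positive class relabels the same confusion counts
  truth <- c("m", "m", "m", "t", "t")
  pred <- c("m", "t", "m", "t", "m")
  a <- metrics(confusion(truth, pred, positive = "m"))
  b <- metrics(confusion(truth, pred, positive = "t"))
  cm_a <- confusion(truth, pred, positive = "m")
  cm_b <- confusion(truth, pred, positive = "t")
  expect_equal(cm_a$TP, cm_b$TN)
  expect_equal(cm_a$FP, cm_b$FN)
  expect_equal(a$accuracy, b$accuracy)
})
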