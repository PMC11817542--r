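#' Confusion counts for binary classification
#'
#' @param truth True labels.
#' @param pred Predicted labels (same length, same label space).
#' @param positive The label counted as the positive class.
#' @return An object of class `confusion_matrix`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, pred, positive = "misinformation") {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths")
  }
  if (!length(truth)) stop("cannot build a confusion matrix from no labels")
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion (positive =", x$positive, ")\n")
  print(matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
               dimnames = list(truth = c("positive", "negative"),
                               predicted = c("positive", "negative"))))
  invisible(x)
}

#' F-measure from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`; `NA` where either input is
#' missing or both are zero. Vectorized.
#'
#' @param precision,recall Numeric vectors on the same scale (fractions or
#'   percentages — the harmonic mean is scale-equivariant).
#' @return Numeric vector of F-scores.
#' @export
f1_score <- function(precision, recall) {
  out <- 2 * precision * recall / (precision + recall)
  out[!is.na(precision + recall) & (precision + recall) == 0] <- NA_real_
  out
}

#' Accuracy, precision, recall and F-score from a confusion matrix
#'
#' Ratios with a zero denominator are reported as `NA` ("absent"), never as
#' zero, so they can be excluded from fold averages instead of corrupting
#' them.
#'
#' @param cm A [confusion()] result.
#' @return A list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  p <- ratio(cm$TP, cm$TP + cm$FP)
  r <- ratio(cm$TP, cm$TP + cm$FN)
  list(accuracy = (cm$TP + cm$TN) / tot,
       precision = p,
       recall = r,
       f1 = if (!is.na(p) && !is.na(r)) f1_score(p, r) else NA_real_)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the chance that a
#' randomly chosen positive document scores above a randomly chosen negative
#' one, with ties counted one half. Both classes must be present.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth True labels.
#' @param positive Label of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, positive = "misinformation") {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Emits (false positive rate, true positive rate, threshold) triples for
#' every distinct score cutoff, suitable for plotting.
#'
#' @inheritParams roc_auc
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth, positive = "misinformation") {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = cuts,
    fpr = vapply(cuts, function(t) sum(scores >= t & !pos) / n0, 1),
    tpr = vapply(cuts, function(t) sum(scores >= t & pos) / n1, 1))
}

#' Stratified k-fold cross-validation
#'
#' Partitions documents into `k` stratified folds (every document tested
#' exactly once; per-class fold sizes differ by at most one), trains a model
#' from scratch per fold via `train_fun` on the other `k - 1` folds, scores
#' the held-out fold via `predict_fun`, and aggregates metrics as the
#' unweighted arithmetic mean across folds (NA metrics excluded).
#'
#' @param y Label vector for all documents.
#' @param train_fun Function `(train_idx) -> model`.
#' @param predict_fun Function `(model, test_idx) -> positive-class scores`.
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed Integer seed controlling the fold assignment.
#' @param positive Positive-class label.
#' @param cutoff Probability cutoff for hard labels (default 0.5).
#' @return An object of class `fold_result`: list with `folds` (per-fold
#'   metric data.frame), `aggregate` (mean metrics), `assignment` (fold id
#'   per document).
#' @export
kfold_cv <- function(y, train_fun, predict_fun, k = 5L, seed = 1L,
                     positive = "misinformation", cutoff = 0.5) {
  stopifnot(k >= 2)
  classes <- unique(y)
  cnt <- table(y)
  if (any(cnt < k)) {
    stop("class '", names(cnt)[which.min(cnt)], "' has fewer than k = ", k,
         " documents")
  }
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  negative <- setdiff(classes, positive)[1]
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    model <- train_fun(tr)
    sc <- predict_fun(model, te)
    pred <- ifelse(sc > cutoff, positive, negative)
    m <- metrics(confusion(y[te], pred, positive))
    rows[[f]] <- data.frame(fold = f, n = length(te),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1)
  }
  folds <- do.call(rbind, rows)
  aggregate <- colMeans(folds[, c("accuracy", "precision", "recall", "f1")],
                        na.rm = TRUE)
  structure(list(folds = folds, aggregate = aggregate, assignment = fold,
                 k = k),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$k, "-fold cross-validation\n", sep = "")
  print(x$folds, row.names = FALSE, digits = 4)
  cat("mean: ", paste(sprintf("%s %.4f", names(x$aggregate), x$aggregate),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Per-class one-vs-rest metric report
#'
#' Treats each class as the positive class in turn and reports the one-vs-rest
#' confusion-derived accuracy, precision, recall and F-score — the per-class
#' layout used to compare performance on the trustworthy-information class
#' against the misinformation class.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param classes Classes to report (defaults to those present in `truth`).
#' @return A data.frame with one row per class.
#' @export
per_class_report <- function(truth, pred, classes = sort(unique(truth))) {
  rows <- lapply(classes, function(cl) {
    m <- metrics(confusion(truth, pred, positive = cl))
    data.frame(class = cl, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
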