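#' Specification of a comparison classifier
#'
#' The six comparison models: decision tree, random forest, support-vector
#' machine, their stacking ensemble, and one/two-layer GRU and LSTM
#' recurrent networks. Classic models use their library defaults (recorded
#' in the fitted object for reproducibility); recurrent models take a layer
#' count and a cell count from the study grid.
#'
#' @param kind One of `"decision_tree"`, `"random_forest"`, `"svm"`,
#'   `"stacking"`, `"gru"`, `"lstm"`.
#' @param recurrent_layers 1 or 2 (recurrent kinds only).
#' @param cells Hidden units, one of 16/32/64/128 typically (recurrent kinds
#'   only).
#' @param seed Integer seed.
#' @param ... Extra arguments stored and passed to the underlying fitter
#'   (e.g. `epochs`, `learning_rate`, `dropout` for recurrent kinds).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("decision_tree", "random_forest", "svm",
                                   "stacking", "gru", "lstm"),
                          recurrent_layers = NULL, cells = NULL, seed = 1L,
                          ...) {
  kind <- match.arg(kind)
  recurrent <- kind %in% c("gru", "lstm")
  if (recurrent) {
    if (is.null(recurrent_layers)) recurrent_layers <- 1L
    if (is.null(cells)) cells <- 32L
    stopifnot(recurrent_layers %in% c(1L, 2L), cells >= 1)
  } else if (!is.null(recurrent_layers) || !is.null(cells)) {
    stop("recurrent_layers/cells apply only to gru or lstm specs")
  }
  structure(list(kind = kind, recurrent_layers = recurrent_layers,
                 cells = cells, seed = as.integer(seed), args = list(...)),
            class = "baseline_spec")
}

#' TF-IDF feature matrix for the classic models
#'
#' The fixed-length document representation given to the decision tree,
#' random forest, SVM and stacking ensemble: the same smoothed TF-IDF
#' weights (and vocabulary) as [doc_vectors()] in the augmentation step,
#' returned dense with syntactic column names.
#'
#' @param token_list Named list of token vectors.
#' @param stats Optional shared [corpus_stats()].
#' @return A dense numeric matrix, documents x vocabulary.
#' @export
featurize_classic <- function(token_list, stats = corpus_stats(token_list)) {
  if (!length(token_list)) stop("empty corpus")
  m <- as.matrix(doc_vectors(token_list, stats))
  colnames(m) <- make.names(colnames(m))
  m
}

.as_factor_y <- function(y) {
  factor(ifelse(y > 0.5, "misinformation", "trustworthy"),
         levels = c("trustworthy", "misinformation"))
}

#' Fit a comparison classifier
#'
#' Uniform train interface over the six baselines, so the evaluation
#' machinery is model-agnostic. Classic kinds (`decision_tree` via rpart,
#' `random_forest` via randomForest, `svm` via e1071 with probability
#' output) are fitted with their library default parameters. `stacking`
#' trains the three classic models as base learners and a logistic meta
#' classifier on their out-of-fold predicted probabilities (5-fold internal
#' split — the standard leak-free construction), then refits the base
#' models on all data. Recurrent kinds call [fit_rnn()] on token-index
#' sequences.
#'
#' @param spec A [baseline_spec()].
#' @param x Feature matrix ([featurize_classic()]) for classic kinds, or an
#'   integer token-index matrix ([token_indices()]) for recurrent kinds.
#' @param y Numeric 0/1 labels (1 = misinformation); both classes required.
#' @param ... Overrides forwarded to the underlying fitter.
#' @return An object of class `misinfo_baseline` with a
#'   [predict.misinfo_baseline()] method returning misinformation
#'   probabilities.
#' @export
fit_baseline <- function(spec, x, y, ...) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  yf <- .as_factor_y(y)
  args <- utils::modifyList(spec$args, list(...))
  fit_one <- function(kind) {
    with_local_seed(spec$seed, switch(
      kind,
      decision_tree = do.call(rpart::rpart, c(list(
        label ~ ., data = data.frame(label = yf, x, check.names = FALSE),
        method = "class"), args)),
      random_forest = do.call(randomForest::randomForest,
                              c(list(x, yf), args)),
      svm = do.call(e1071::svm, c(list(x, yf, probability = TRUE), args))))
  }
  if (spec$kind %in% c("decision_tree", "random_forest", "svm")) {
    model <- fit_one(spec$kind)
    out <- list(spec = spec, model = model)
  } else if (spec$kind == "stacking") {
    base_kinds <- c("decision_tree", "random_forest", "svm")
    k <- 5L
    fold <- with_local_seed(spec$seed, {
      f <- integer(length(y))
      for (cl in unique(y)) {
        i <- sample(which(y == cl))
        f[i] <- rep_len(seq_len(k), length(i))
      }
      f
    })
    oof <- matrix(NA_real_, length(y), length(base_kinds),
                  dimnames = list(NULL, base_kinds))
    for (f in seq_len(k)) {
      tr <- fold != f
      for (bk in base_kinds) {
        sub <- fit_baseline(baseline_spec(bk, seed = spec$seed),
                            x[tr, , drop = FALSE], y[tr])
        oof[!tr, bk] <- predict(sub, x[!tr, , drop = FALSE])
      }
    }
    meta_df <- data.frame(y = y, oof)
    ## complete separation of the base probabilities is legitimate (and
    ## common on cleanly separable corpora); the glm warning is noise here
    meta <- suppressWarnings(
      stats::glm(y ~ ., data = meta_df, family = stats::binomial()))
    bases <- lapply(base_kinds, fit_one)
    names(bases) <- base_kinds
    out <- list(spec = spec, base_models = bases, meta = meta)
  } else {
    stopifnot(is.matrix(x))
    rnn_args <- c(list(x = x, y = y, kind = spec$kind,
                       layers = spec$recurrent_layers, cells = spec$cells,
                       seed = spec$seed), args)
    out <- list(spec = spec, model = do.call(fit_rnn, rnn_args))
  }
  class(out) <- "misinfo_baseline"
  out
}

#' Predict misinformation probabilities from a baseline
#'
#' @param object A fitted [fit_baseline()] model.
#' @param x New data in the representation the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the misinformation class.
#' @export
predict.misinfo_baseline <- function(object, x, ...) {
  kind <- object$spec$kind
  prob_of <- function(model, kind, x) {
    switch(kind,
      decision_tree = stats::predict(
        model, data.frame(x, check.names = FALSE))[, "misinformation"],
      random_forest = stats::predict(model, x,
                                     type = "prob")[, "misinformation"],
      svm = {
        pr <- stats::predict(model, x, probability = TRUE)
        attr(pr, "probabilities")[, "misinformation"]
      })
  }
  if (kind %in% c("decision_tree", "random_forest", "svm")) {
    unname(prob_of(object$model, kind, x))
  } else if (kind == "stacking") {
    base_p <- vapply(names(object$base_models), function(bk) {
      prob_of(object$base_models[[bk]], bk, x)
    }, numeric(nrow(x)))
    if (is.null(dim(base_p))) {
      base_p <- matrix(base_p, nrow = 1,
                       dimnames = list(NULL, names(object$base_models)))
    }
    nd <- as.data.frame(base_p)
    unname(stats::predict(object$meta, newdata = nd, type = "response"))
  } else {
    unname(stats::predict(object$model, x))
  }
}

#' @export
print.misinfo_baseline <- function(x, ...) {
  cat("<misinfo_baseline>", x$spec$kind)
  if (!is.null(x$spec$cells)) {
    cat(" (", x$spec$recurrent_layers, " layer(s), ", x$spec$cells,
        " cells)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Run the recurrent-baseline grid
#'
#' Trains GRU and LSTM models with one and two recurrent layers over a grid
#' of cell counts (default 16/32/64/128), collecting each model's training
#' history and its [detect_overfitting()] verdict.
#'
#' @param x Token-index matrix.
#' @param y 0/1 labels.
#' @param cells_grid Cell counts to sweep.
#' @param layers_grid Layer counts to sweep.
#' @param kinds Recurrent kinds to sweep.
#' @param seed Integer seed.
#' @param ... Passed to [fit_rnn()] (e.g. `epochs`, `validation`).
#' @return A data.frame with one row per spec (kind, layers, cells, final
#'   metrics, overfitting flag) and the fitted models in attribute
#'   `"models"`.
#' @export
recurrent_grid <- function(x, y, cells_grid = c(16L, 32L, 64L, 128L),
                           layers_grid = c(1L, 2L),
                           kinds = c("gru", "lstm"), seed = 1L, ...) {
  grid <- expand.grid(kind = kinds, layers = layers_grid,
                      cells = cells_grid, stringsAsFactors = FALSE)
  models <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- fit_baseline(baseline_spec(g$kind, recurrent_layers = g$layers,
                                      cells = g$cells, seed = seed),
                        x, y, ...)
    h <- fit$model$history
    ov <- detect_overfitting(h)
    models[[i]] <- fit
    rows[[i]] <- data.frame(
      kind = g$kind, layers = g$layers, cells = g$cells,
      final_loss = h$loss[nrow(h)], final_accuracy = h$accuracy[nrow(h)],
      final_val_accuracy = h$val_accuracy[nrow(h)],
      overfit = ov$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Detect overfitting in a training history
#'
#' Flags a run as overfitted when the train/validation accuracy gap exceeds
#' `gap` for at least `patience` consecutive epochs, or when validation
#' loss rises while training loss falls for at least `patience` consecutive
#' epoch-to-epoch transitions. The reported epoch is the first epoch of the
#' earliest qualifying run; histories shorter than the patience cannot be
#' flagged.
#'
#' @param history A data.frame with columns `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy` (one row per epoch), as produced by the model trainers.
#' @param gap Accuracy-gap threshold (default 0.15).
#' @param patience Consecutive epochs required (default 2).
#' @return A list with `flag` (logical) and `epoch` (first offending epoch,
#'   `NA` if not flagged).
#' @export
detect_overfitting <- function(history, gap = 0.15, patience = 2L) {
  stopifnot(nrow(history) >= 1, patience >= 1)
  first_run <- function(cond, need) {
    if (!length(cond)) return(NA_integer_)
    r <- rle(cond)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= need)
    if (length(hit)) starts[hit[1]] else NA_integer_
  }
  gap_exceeded <- (history$accuracy - history$val_accuracy) > gap
  gap_exceeded[is.na(gap_exceeded)] <- FALSE
  e1 <- first_run(gap_exceeded, patience)
  if (nrow(history) >= 2) {
    div <- diff(history$val_loss) > 0 & diff(history$loss) < 0
    div[is.na(div)] <- FALSE
    ## a qualifying run of transitions first shows divergence at the epoch
    ## after the run starts
    e2 <- first_run(div, patience) + 1L
  } else {
    e2 <- NA_integer_
  }
  epoch <- suppressWarnings(min(e1, e2, na.rm = TRUE))
  if (!is.finite(epoch)) {
    list(flag = FALSE, epoch = NA_integer_)
  } else {
    list(flag = TRUE, epoch = as.integer(epoch))
  }
}
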