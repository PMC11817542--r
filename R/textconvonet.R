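#' Configuration of the four-pathway convolutional text classifier
#'
#' Collects the hyperparameters of the TextConvoNet-style classifier: a
#' single-channel `max_tokens x dims` embedding plane fed through four
#' parallel convolutional pathways. The first pathway pair targets
#' intra-sentence token patterns, the second pair inter-sentence patterns;
#' mechanically all four kernels are applied to the same plane, and the
#' intra/inter distinction is wiring metadata governing how pathway outputs
#' are concatenated. Each pathway stacks three same-padded stride-1 2-D
#' convolutions, then dropout (placed before the rectification, a deliberate
#' modification to curb overfitting), a ReLU, and 2x2 max pooling. The
#' concatenated, flattened pathway outputs pass through one rectified dense
#' layer and a single sigmoid unit whose output is the probability of the
#' misinformation class.
#'
#' Defaults: 100x100 input, kernels 12x12 and 2x2
#' (inter-sentence main/sub) and 11x2 and 1x3 (intra-sentence main/sub),
#' dropout 0.5, 128 dense units, Adam with learning rate 1e-4, binary
#' cross-entropy, batch size 128, five training epochs. The filter count per
#' convolution is a free capacity knob; the default of 4 keeps
#' desk-scale CPU training in the minutes range and is freely configurable.
#'
#' @param max_tokens,dims Input plane geometry (default 100 x 100).
#' @param filters Filters per convolutional layer (default 4).
#' @param kernels Named list of four integer pairs: `inter_main`,
#'   `inter_sub`, `intra_main`, `intra_sub`.
#' @param dense_units Width of the fully connected layer (default 128).
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Training epochs (default 5).
#' @param pool Max-pooling window and stride (default 2).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return An object of class `tcn_config`.
#' @export
tcn_config <- function(max_tokens = 100L, dims = 100L, filters = 4L,
                       kernels = list(inter_main = c(12L, 12L),
                                      inter_sub = c(2L, 2L),
                                      intra_main = c(11L, 2L),
                                      intra_sub = c(1L, 3L)),
                       dense_units = 128L, dropout = 0.5,
                       learning_rate = 1e-4, batch_size = 128L,
                       epochs = 5L, pool = 2L, seed = 1L) {
  stopifnot(max_tokens >= 2, dims >= 2, filters >= 1, dense_units >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1,
            epochs >= 1, pool >= 1)
  need <- c("inter_main", "inter_sub", "intra_main", "intra_sub")
  if (!all(need %in% names(kernels))) {
    stop("kernels must name: ", paste(need, collapse = ", "))
  }
  km <- do.call(rbind, lapply(kernels[need], as.integer))
  for (i in seq_len(4)) {
    if (km[i, 1] > max_tokens || km[i, 2] > dims) {
      stop("kernel ", need[i], " (", km[i, 1], "x", km[i, 2],
           ") does not fit the ", max_tokens, "x", dims, " input plane")
    }
  }
  structure(list(max_tokens = as.integer(max_tokens),
                 dims = as.integer(dims), filters = as.integer(filters),
                 kernels = kernels[need], kernel_matrix = km,
                 dense_units = as.integer(dense_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), pool = as.integer(pool),
                 seed = as.integer(seed)),
            class = "tcn_config")
}

#' Architecture summary for a configuration
#'
#' Lists every layer with its output shape and parameter count; the total
#' parameter count depends only on the configuration, never on data.
#'
#' @param config A [tcn_config()].
#' @return A data.frame with attribute `"total_params"`.
#' @export
tcn_architecture <- function(config) {
  stopifnot(inherits(config, "tcn_config"))
  h <- config$max_tokens; w <- config$dims; f <- config$filters
  h2 <- h %/% config$pool; w2 <- w %/% config$pool
  rows <- list(data.frame(layer = "input", pathway = "",
                          output_shape = sprintf("%dx%dx1", h, w),
                          params = 0L, stringsAsFactors = FALSE))
  pn <- names(config$kernels)
  for (i in seq_len(4)) {
    kh <- config$kernel_matrix[i, 1]; kw <- config$kernel_matrix[i, 2]
    k1 <- kh * kw
    shp <- sprintf("%dx%dx%d", h, w, f)
    rows[[length(rows) + 1]] <- data.frame(
      layer = c(sprintf("conv %dx%d (1)", kh, kw),
                sprintf("conv %dx%d (2)", kh, kw),
                sprintf("conv %dx%d (3)", kh, kw),
                "dropout", "relu",
                sprintf("maxpool %dx%d", config$pool, config$pool)),
      pathway = pn[i],
      output_shape = c(shp, shp, shp, shp, shp,
                       sprintf("%dx%dx%d", h2, w2, f)),
      params = c(k1 * f + f, k1 * f * f + f, k1 * f * f + f, 0L, 0L, 0L),
      stringsAsFactors = FALSE)
  }
  p_flat <- 4L * f * h2 * w2
  rows[[length(rows) + 1]] <- data.frame(
    layer = c("concatenate+flatten", "dense (relu)", "output (sigmoid)"),
    pathway = "",
    output_shape = c(as.character(p_flat),
                     as.character(config$dense_units), "1"),
    params = c(0L, p_flat * config$dense_units + config$dense_units,
               config$dense_units + 1L),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_params") <- sum(out$params)
  out
}

#' Build an untrained four-pathway convolutional classifier
#'
#' Initializes the weights deterministically from `config$seed`
#' (Glorot-uniform); building twice from the same configuration yields
#' identical weights, architecture summaries and parameter counts.
#'
#' @param config A [tcn_config()].
#' @return An object of class `textconvonet` with elements `config`,
#'   `weights`, `history` (`NULL` until trained) and `trained`.
#' @export
textconvonet <- function(config = tcn_config()) {
  stopifnot(inherits(config, "tcn_config"))
  weights <- tcn_init_cpp(config)
  structure(list(config = config, weights = weights, history = NULL,
                 trained = FALSE),
            class = "textconvonet")
}

#' @export
print.textconvonet <- function(x, ...) {
  arch <- tcn_architecture(x$config)
  cat("Four-pathway 2-D convolutional text classifier",
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("input:", x$config$max_tokens, "x", x$config$dims,
      " filters:", x$config$filters,
      " parameters:", attr(arch, "total_params"), "\n")
  cat("pathway kernels:",
      paste(vapply(x$config$kernels, paste, "", collapse = "x"),
            collapse = ", "), "\n")
  if (x$trained) {
    h <- x$history
    cat("trained", nrow(h), "epochs; final loss",
        sprintf("%.4f", h$loss[nrow(h)]), "acc",
        sprintf("%.4f", h$accuracy[nrow(h)]), "\n")
  }
  invisible(x)
}

#' @export
summary.textconvonet <- function(object, ...) {
  arch <- tcn_architecture(object$config)
  print(arch, row.names = FALSE)
  cat("total parameters:", attr(arch, "total_params"), "\n")
  invisible(arch)
}

.check_xy <- function(x, y, config) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a max_tokens x dims x n array")
  if (d[1] != config$max_tokens || d[2] != config$dims) {
    stop("input shape ", d[1], "x", d[2], " does not match the configured ",
         config$max_tokens, "x", config$dims, " plane")
  }
  if (!is.null(y)) {
    if (length(y) != d[3]) stop("length(y) must equal dim(x)[3]")
    if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  }
  invisible(TRUE)
}

#' Train the convolutional classifier
#'
#' Runs exactly `config$epochs` epochs of mini-batch Adam on binary
#' cross-entropy, recording train and validation loss/accuracy per epoch.
#' Labels are 0/1 with 1 = misinformation (the positive class). All
#' randomness — weight initialization, epoch shuffling, dropout masks — is
#' driven by `config$seed`, so a rerun with the same data and seed
#' reproduces the run. Dropout is active only during training; inference is
#' deterministic.
#'
#' @param model An untrained (or previously trained) [textconvonet()] model.
#' @param x `max_tokens x dims x n` embedding array ([build_matrices()]).
#' @param y Numeric 0/1 labels, both classes present.
#' @param validation Either a fraction in (0, 1) split off (stratified,
#'   seeded) for validation, a list `list(x=, y=)`, or `NULL`.
#' @param ids,validation_ids Optional document ids; when both given they
#'   must be disjoint.
#' @param verbose Print per-epoch progress.
#' @return The model with updated `weights`, logical `trained`, and
#'   `history`: a data.frame of epoch, loss, accuracy, val_loss,
#'   val_accuracy (class `tcn_history`).
#' @export
train_textconvonet <- function(model, x, y, validation = 0.15,
                               ids = NULL, validation_ids = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(model, "textconvonet"))
  config <- model$config
  .check_xy(x, y, config)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class")
  }
  if (!is.null(ids) && !is.null(validation_ids) &&
      length(intersect(ids, validation_ids))) {
    stop("training and validation sets share document ids")
  }
  if (is.list(validation)) {
    .check_xy(validation$x, validation$y, config)
    xv <- validation$x; yv <- validation$y
  } else if (is.numeric(validation) && length(validation) == 1L &&
             validation > 0 && validation < 1) {
    idx <- with_local_seed(config$seed, {
      unlist(lapply(split(seq_along(y), y), function(i) {
        sample(i, max(1L, round(length(i) * validation)))
      }), use.names = FALSE)
    })
    xv <- x[, , idx, drop = FALSE]; yv <- y[idx]
    x <- x[, , -idx, drop = FALSE]; y <- y[-idx]
  } else if (is.null(validation)) {
    xv <- array(0, c(config$max_tokens, config$dims, 0)); yv <- numeric()
  } else stop("validation must be a fraction, a list(x, y), or NULL")
  fit <- tcn_train_cpp(config, model$weights, x, as.numeric(y), xv,
                       as.numeric(yv), isTRUE(verbose))
  hist <- as.data.frame(fit$history)
  names(hist) <- c("loss", "accuracy", "val_loss", "val_accuracy")
  hist <- cbind(epoch = seq_len(nrow(hist)), hist)
  class(hist) <- c("tcn_history", "data.frame")
  model$weights <- fit$weights
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predict misinformation probabilities
#'
#' @param object A [textconvonet()] model.
#' @param x `max_tokens x dims x n` embedding array.
#' @param type `"prob"` for probabilities of the misinformation class (in
#'   (0, 1)), `"class"` for hard 0/1 labels at the 0.5 cutoff.
#' @param ... Unused.
#' @return Numeric vector of length `n`.
#' @export
predict.textconvonet <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  .check_xy(x, NULL, object$config)
  p <- as.numeric(tcn_predict_cpp(object$config, object$weights, x))
  names(p) <- dimnames(x)[[3]]
  if (type == "class") ifelse(p > 0.5, 1, 0) else p
}
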