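# Recurrent (GRU / LSTM) baselines, implemented directly on matrix algebra.
# Sequences enter as padded/truncated token-index matrices (0 = padding or
# out-of-vocabulary); a learned embedding feeds one or two recurrent layers
# whose final hidden state drives a sigmoid output unit. Training follows
# the convolutional model's regime: mini-batch Adam on binary cross-entropy.

.sigm <- function(x) 1 / (1 + exp(-x))

# parameter initialization; gates concatenated column-wise
.rnn_init <- function(kind, layers, cells, vocab_size, embed_dim, seed) {
  ngate <- if (kind == "gru") 3L else 4L
  with_local_seed(seed, {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    par <- list(E = rbind(0, glorot(vocab_size, embed_dim)))
    for (l in seq_len(layers)) {
      d <- if (l == 1) embed_dim else cells
      b <- matrix(0, 1, ngate * cells)
      if (kind == "lstm") b[1, cells + seq_len(cells)] <- 1  # forget bias
      par[[paste0("Wx", l)]] <- glorot(d, ngate * cells)
      par[[paste0("Wh", l)]] <- glorot(cells, ngate * cells)
      par[[paste0("b", l)]] <- b
    }
    par$Wo <- glorot(cells, 1L)
    par$bo <- matrix(0, 1, 1)
    par
  })
}

# forward one layer across time; returns final hidden state and (optionally)
# the caches needed for backpropagation through time
.rnn_layer_fwd <- function(kind, X_list, Wx, Wh, b, cells, keep_cache) {
  B <- nrow(X_list[[1]])
  Tn <- length(X_list)
  h <- matrix(0, B, cells)
  cstate <- matrix(0, B, cells)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    A <- X_list[[t]] %*% Wx + h %*% Wh
    A <- sweep(A, 2, b[1, ], "+")
    if (kind == "gru") {
      z <- .sigm(A[, seq_len(cells), drop = FALSE])
      r <- .sigm(A[, cells + seq_len(cells), drop = FALSE])
      ## candidate uses the reset-gated previous state
      an <- X_list[[t]] %*% Wx[, 2 * cells + seq_len(cells), drop = FALSE] +
        (r * h) %*% Wh[, 2 * cells + seq_len(cells), drop = FALSE]
      an <- sweep(an, 2, b[1, 2 * cells + seq_len(cells)], "+")
      nn <- tanh(an)
      hn <- (1 - z) * nn + z * h
      if (keep_cache) cache[[t]] <- list(z = z, r = r, nn = nn, h_prev = h)
      h <- hn
    } else {
      i <- .sigm(A[, seq_len(cells), drop = FALSE])
      f <- .sigm(A[, cells + seq_len(cells), drop = FALSE])
      g <- tanh(A[, 2 * cells + seq_len(cells), drop = FALSE])
      o <- .sigm(A[, 3 * cells + seq_len(cells), drop = FALSE])
      cn <- f * cstate + i * g
      tc <- tanh(cn)
      hn <- o * tc
      if (keep_cache) {
        cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cstate,
                           tc = tc, h_prev = h)
      }
      cstate <- cn
      h <- hn
    }
    out[[t]] <- h
  }
  list(h = h, out = out, cache = cache)
}

# backpropagate one layer through time. Incoming gradients: `dh_last` on the
# final hidden state (top layer) and/or `dout`, a per-timestep list of
# gradients on every output (stacked layers). Returns parameter gradients
# and the gradient on the layer's input sequence.
.rnn_layer_bwd <- function(kind, X_list, out, cache, Wx, Wh, cells,
                           dh_last = NULL, dout = NULL) {
  Tn <- length(X_list)
  d <- ncol(X_list[[1]])
  B <- nrow(X_list[[1]])
  gWx <- matrix(0, d, ncol(Wx)); gWh <- matrix(0, cells, ncol(Wh))
  gb <- matrix(0, 1, ncol(Wx))
  dX <- vector("list", Tn)
  dh <- if (is.null(dh_last)) matrix(0, B, cells) else dh_last
  dc <- NULL
  ci <- seq_len(cells)
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dout)) dh <- dh + dout[[t]]
    cc <- cache[[t]]
    if (kind == "gru") {
      z <- cc$z; r <- cc$r; nn <- cc$nn; h_prev <- cc$h_prev
      dz <- dh * (h_prev - nn)
      dn <- dh * (1 - z)
      dh_prev <- dh * z
      dan <- dn * (1 - nn^2)
      daz <- dz * z * (1 - z)
      drh <- dan %*% t(Wh[, 2 * cells + ci, drop = FALSE])
      dr <- drh * h_prev
      dh_prev <- dh_prev + drh * r
      dar <- dr * r * (1 - r)
      dA <- cbind(daz, dar, dan)
      gWh[, ci] <- gWh[, ci] + t(h_prev) %*% daz
      gWh[, cells + ci] <- gWh[, cells + ci] + t(h_prev) %*% dar
      gWh[, 2 * cells + ci] <- gWh[, 2 * cells + ci] + t(r * h_prev) %*% dan
      dh_prev <- dh_prev + daz %*% t(Wh[, ci, drop = FALSE]) +
        dar %*% t(Wh[, cells + ci, drop = FALSE])
    } else {
      i <- cc$i; f <- cc$f; g <- cc$g; o <- cc$o
      if (is.null(dc)) dc <- matrix(0, nrow(dh), cells)
      dov <- dh * cc$tc
      dc <- dc + dh * o * (1 - cc$tc^2)
      div <- dc * g
      df <- dc * cc$c_prev
      dg <- dc * i
      dc <- dc * f  # becomes dc_prev
      dA <- cbind(div * i * (1 - i), df * f * (1 - f),
                  dg * (1 - g^2), dov * o * (1 - o))
      gWh <- gWh + t(cc$h_prev) %*% dA
      dh_prev <- dA %*% t(Wh)
    }
    gWx <- gWx + t(X_list[[t]]) %*% dA
    gb <- gb + colSums(dA)
    dX[[t]] <- dA %*% t(Wx)
    dh <- dh_prev
  }
  list(gWx = gWx, gWh = gWh, gb = gb, dX = dX)
}

.rnn_forward_batch <- function(par, kind, layers, cells, ids, keep_cache) {
  Tn <- ncol(ids)
  X_list <- lapply(seq_len(Tn), function(t) {
    par$E[ids[, t] + 1L, , drop = FALSE]
  })
  inputs <- X_list
  layer_out <- vector("list", layers)
  for (l in seq_len(layers)) {
    fw <- .rnn_layer_fwd(kind, inputs, par[[paste0("Wx", l)]],
                         par[[paste0("Wh", l)]], par[[paste0("b", l)]],
                         cells, keep_cache)
    layer_out[[l]] <- fw
    inputs <- fw$out
  }
  h_final <- layer_out[[layers]]$h
  prob <- .sigm(as.vector(h_final %*% par$Wo) + par$bo[1, 1])
  list(prob = prob, X_list = X_list, layer_out = layer_out)
}

#' Train a recurrent (GRU or LSTM) sequence classifier
#'
#' One- or two-layer recurrent network over padded token-index sequences,
#' with a learned word embedding and a sigmoid output on the final hidden
#' state. Trained with mini-batch Adam on binary cross-entropy, mirroring
#' the convolutional model's regime (default learning rate 1e-4, batch size
#' 128, five epochs) for comparability; dropout on the final hidden state
#' and L2 weight decay are exposed as options. Records per-epoch training
#' and validation loss/accuracy, the input for [detect_overfitting()].
#'
#' @param x Integer matrix `n x max_tokens` of token indices
#'   ([token_indices()]); 0 marks padding or out-of-vocabulary.
#' @param y Numeric 0/1 labels (1 = misinformation).
#' @param kind `"gru"` or `"lstm"`.
#' @param layers 1 or 2 recurrent layers.
#' @param cells Hidden units per layer (the study grid uses 16/32/64/128).
#' @param vocab_size Largest token index in use.
#' @param embed_dim Learned embedding width (default 16).
#' @param epochs,batch_size,learning_rate Training regime.
#' @param dropout Dropout rate on the final hidden state during training.
#' @param l2 L2 penalty coefficient on recurrent and dense weights.
#' @param validation `NULL`, a fraction in (0,1), or `list(x=, y=)`.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @return An object of class `rnn_model` with `parameters`, `history`
#'   (data.frame epoch/loss/accuracy/val_loss/val_accuracy) and the
#'   architecture fields.
#' @export
fit_rnn <- function(x, y, kind = c("gru", "lstm"), layers = 1L, cells = 32L,
                    vocab_size = max(x), embed_dim = 16L, epochs = 5L,
                    batch_size = 128L, learning_rate = 1e-4, dropout = 0,
                    l2 = 0, validation = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(x), layers %in% c(1L, 2L), cells >= 1,
            length(y) == nrow(x), all(y %in% c(0, 1)),
            dropout >= 0, dropout < 1, l2 >= 0)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (is.numeric(validation) && length(validation) == 1L &&
      validation > 0 && validation < 1) {
    idx <- with_local_seed(seed, {
      unlist(lapply(split(seq_along(y), y), function(i) {
        sample(i, max(1L, round(length(i) * validation)))
      }), use.names = FALSE)
    })
    validation <- list(x = x[idx, , drop = FALSE], y = y[idx])
    x <- x[-idx, , drop = FALSE]; y <- y[-idx]
  }
  par <- .rnn_init(kind, layers, cells, vocab_size, embed_dim, seed)
  mstate <- lapply(par, function(p) p * 0)
  vstate <- lapply(par, function(p) p * 0)
  tstep <- 0
  n <- nrow(x)
  hist <- matrix(NA_real_, epochs, 4)
  with_local_seed(seed + 13L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = batch_size)) {
        bi <- ord[start:min(n, start + batch_size - 1)]
        ids <- x[bi, , drop = FALSE]
        fw <- .rnn_forward_batch(par, kind, layers, cells, ids, TRUE)
        h_final <- fw$layer_out[[layers]]$h
        hmask <- NULL
        if (dropout > 0) {
          hmask <- matrix(ifelse(runif(length(h_final)) < dropout, 0,
                                 1 / (1 - dropout)), nrow(h_final))
          h_drop <- h_final * hmask
          prob <- .sigm(as.vector(h_drop %*% par$Wo) + par$bo[1, 1])
        } else {
          h_drop <- h_final
          prob <- fw$prob
        }
        pc <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - sum(y[bi] * log(pc) + (1 - y[bi]) * log(1 - pc))
        ep_correct <- ep_correct + sum((prob > 0.5) == (y[bi] > 0.5))
        ## backward
        grads <- lapply(par, function(p) p * 0)
        dlogit <- (prob - y[bi]) / length(bi)
        grads$Wo <- t(h_drop) %*% dlogit
        grads$bo[1, 1] <- sum(dlogit)
        dh <- dlogit %*% t(par$Wo)
        if (dropout > 0) dh <- dh * hmask
        douts <- NULL
        for (l in rev(seq_len(layers))) {
          X_in <- if (l == 1) fw$X_list else fw$layer_out[[l - 1]]$out
          bw <- .rnn_layer_bwd(kind, X_in, fw$layer_out[[l]]$out,
                               fw$layer_out[[l]]$cache,
                               par[[paste0("Wx", l)]],
                               par[[paste0("Wh", l)]], cells,
                               dh_last = if (l == layers) dh else NULL,
                               dout = douts)
          grads[[paste0("Wx", l)]] <- bw$gWx
          grads[[paste0("Wh", l)]] <- bw$gWh
          grads[[paste0("b", l)]] <- bw$gb
          douts <- bw$dX  # per-timestep gradients for the layer below
        }
        gE <- par$E * 0
        for (t in seq_len(ncol(ids))) {
          agg <- rowsum(douts[[t]], ids[, t] + 1L)
          ri <- as.integer(rownames(agg))
          gE[ri, ] <- gE[ri, ] + agg
        }
        gE[1, ] <- 0  # padding row stays zero
        grads$E <- gE
        ## L2 penalty
        if (l2 > 0) {
          for (nm in names(par)) {
            if (grepl("^(Wx|Wh|Wo)", nm)) {
              grads[[nm]] <- grads[[nm]] + 2 * l2 * par[[nm]]
            }
          }
        }
        ## Adam update
        tstep <- tstep + 1
        b1c <- 1 - 0.9^tstep; b2c <- 1 - 0.999^tstep
        for (nm in names(par)) {
          g <- grads[[nm]]
          mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * g
          vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * g^2
          par[[nm]] <- par[[nm]] - learning_rate *
            (mstate[[nm]] / b1c) / (sqrt(vstate[[nm]] / b2c) + 1e-8)
        }
      }
      hist[ep, 1] <- ep_loss / n
      hist[ep, 2] <- ep_correct / n
      if (is.list(validation)) {
        fv <- .rnn_forward_batch(par, kind, layers, cells, validation$x,
                                 FALSE)
        pv <- pmin(pmax(fv$prob, 1e-12), 1 - 1e-12)
        hist[ep, 3] <- -mean(validation$y * log(pv) +
                               (1 - validation$y) * log(1 - pv))
        hist[ep, 4] <- mean((fv$prob > 0.5) == (validation$y > 0.5))
      }
    }
  })
  history <- data.frame(epoch = seq_len(epochs), loss = hist[, 1],
                        accuracy = hist[, 2], val_loss = hist[, 3],
                        val_accuracy = hist[, 4])
  class(history) <- c("tcn_history", "data.frame")
  structure(list(parameters = par, kind = kind, layers = layers,
                 cells = cells, vocab_size = vocab_size,
                 embed_dim = embed_dim, history = history, seed = seed),
            class = "rnn_model")
}

#' @export
predict.rnn_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  x[x > object$vocab_size] <- 0L  # unseen indices behave as OOV
  p <- .rnn_forward_batch(object$parameters, object$kind, object$layers,
                          object$cells, x, FALSE)$prob
  if (type == "class") ifelse(p > 0.5, 1, 0) else p
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(toupper(x$kind), "sequence classifier:", x$layers, "layer(s),",
      x$cells, "cells, embedding", x$embed_dim, "\n")
  h <- x$history
  cat("trained", nrow(h), "epochs; final loss",
      sprintf("%.4f", h$loss[nrow(h)]), "acc",
      sprintf("%.4f", h$accuracy[nrow(h)]), "\n")
  invisible(x)
}

#' Map token lists to padded index sequences
#'
#' Builds the integer input of the recurrent models: tokens are looked up in
#' `vocabulary` (1-based indices), unknown tokens and padding become 0, and
#' every document is truncated/padded to `max_tokens` positions — the same
#' 100-token budget as the embedding matrices.
#'
#' @param token_list Named list of token vectors.
#' @param vocabulary Character vector defining the index space.
#' @param max_tokens Sequence length (default 100).
#' @return Integer matrix `length(token_list) x max_tokens` with document
#'   ids as rownames.
#' @export
token_indices <- function(token_list, vocabulary, max_tokens = 100L) {
  out <- matrix(0L, length(token_list), max_tokens,
                dimnames = list(names(token_list), NULL))
  for (k in seq_along(token_list)) {
    tk <- token_list[[k]]
    m <- min(length(tk), max_tokens)
    if (m > 0) {
      ix <- match(tk[seq_len(m)], vocabulary)
      ix[is.na(ix)] <- 0L
      out[k, seq_len(m)] <- ix
    }
  }
  out
}
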