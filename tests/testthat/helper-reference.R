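# Independent reference implementations used as oracles in the tests.
# These deliberately share no code with the package internals.

# plain-R forward pass of the four-pathway convolutional classifier,
# evaluated in double precision with naive loops
tcn_forward_ref <- function(config, weights, xmat) {
  H <- config$max_tokens; W <- config$dims; F <- config$filters
  H2 <- H %/% config$pool; W2 <- W %/% config$pool; pool <- config$pool
  conv <- function(A, Wt, b, kh, kw, C) {
    pt <- (kh - 1) %/% 2; pl <- (kw - 1) %/% 2
    out <- array(0, c(H, W, F))
    for (f in 1:F) {
      acc <- matrix(b[1, f], H, W)
      for (dx in 0:(kw - 1)) for (cc in 1:C) for (dy in 0:(kh - 1)) {
        w <- Wt[(cc - 1) * kh + dy + 1, dx * F + f]
        sy <- dy - pt; sx <- dx - pl
        ys <- max(1, 1 - sy):min(H, H - sy)
        xs <- max(1, 1 - sx):min(W, W - sx)
        acc[ys, xs] <- acc[ys, xs] + w * A[ys + sy, xs + sx, cc]
      }
      out[, , f] <- acc
    }
    out
  }
  v <- numeric(0)
  for (p in 1:4) {
    kh <- config$kernel_matrix[p, 1]; kw <- config$kernel_matrix[p, 2]
    pw <- weights$pathways[[p]]
    Z1 <- conv(array(xmat, c(H, W, 1)), pw$W1, pw$b1, kh, kw, 1)
    Z2 <- conv(Z1, pw$W2, pw$b2, kh, kw, F)
    Z3 <- conv(Z2, pw$W3, pw$b3, kh, kw, F)
    R <- pmax(Z3, 0)
    for (f in 1:F) {
      pl2 <- matrix(0, H2, W2)
      for (x2 in 1:W2) for (y2 in 1:H2) {
        pl2[y2, x2] <- max(R[((y2 - 1) * pool + 1):(y2 * pool),
                             ((x2 - 1) * pool + 1):(x2 * pool), f])
      }
      v <- c(v, as.vector(pl2))
    }
  }
  h <- pmax(as.vector(t(weights$Wd) %*% v) + as.vector(weights$bd), 0)
  1 / (1 + exp(-(sum(weights$Wo * h) + weights$bo[1, 1])))
}

# all-pairs concordance AUC (ties counted one half)
auc_bruteforce <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# verified similarity scores reconstructed from the reported calibration
# count table: each threshold bin gets its exceedance-count difference of
# documents, placed at the bin midpoint
reconstruct_calibration_scores <- function(counts, n_true = 180,
                                           n_false = 70) {
  th <- counts$threshold
  edges <- c(0, th, 1)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  per_bin <- function(exceed, n) {
    ## documents per bin: below the lowest threshold, between thresholds,
    ## above the highest
    diff(c(n, exceed, 0)) * -1
  }
  tb <- per_bin(counts$true_count, n_true)
  fb <- per_bin(counts$false_count, n_false)
  data.frame(
    score = c(rep(mids, tb), rep(mids, fb)),
    label = c(rep("trustworthy", sum(tb)), rep("misinformation", sum(fb))),
    stringsAsFactors = FALSE)
}

# small pre-tokenized two-topic corpus for model tests: two disjoint
# vocabularies plus shared background words
make_separable_tokens <- function(n, seed = 1, purity = 1,
                                  len = c(6L, 12L)) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vocab_a <- paste0("alpha", letters[1:12])
  vocab_b <- paste0("beta", letters[1:12])
  shared <- paste0("zeta", letters[1:8])
  y <- rep(c(0, 1), length.out = n)
  toks <- lapply(seq_len(n), function(i) {
    L <- sample(len[1]:len[2], 1)
    own <- if (y[i] == 1) vocab_b else vocab_a
    ifelse(runif(L) < purity, sample(own, L, replace = TRUE),
           sample(shared, L, replace = TRUE))
  })
  names(toks) <- sprintf("doc%04d", seq_len(n))
  list(tokens = toks, y = y)
}
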