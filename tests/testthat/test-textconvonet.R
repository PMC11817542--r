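# small geometry used throughout these tests to keep runtimes low
tiny_cfg <- function(...) {
  tcn_config(max_tokens = 20, dims = 16, filters = 2,
             kernels = list(inter_main = c(5, 5), inter_sub = c(2, 2),
                            intra_main = c(4, 2), intra_sub = c(1, 3)),
             batch_size = 16, epochs = 3, seed = 42, ...)
}

rand_x <- function(cfg, n, seed = 1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  array(rnorm(cfg$max_tokens * cfg$dims * n),
        c(cfg$max_tokens, cfg$dims, n))
}

test_that("configurations validate their geometry", {
  cfg <- tcn_config()
  expect_equal(cfg$kernel_matrix[, 1], c(12, 2, 11, 1), ignore_attr = TRUE)
  expect_equal(cfg$kernel_matrix[, 2], c(12, 2, 2, 3), ignore_attr = TRUE)
  expect_error(tcn_config(max_tokens = 10,
                          kernels = list(inter_main = c(12, 12),
                                         inter_sub = c(2, 2),
                                         intra_main = c(11, 2),
                                         intra_sub = c(1, 3))),
               "inter_main")
  expect_error(tcn_config(dropout = 1), "dropout")
  expect_error(tcn_config(epochs = 0), "epochs")
})

test_that("the architecture summary lists four pathways and exact counts", {
  cfg <- tcn_config()  # default geometry
  arch <- tcn_architecture(cfg)
  convs <- arch[grepl("^conv", arch$layer), ]
  expect_equal(nrow(convs), 12)  # three convolutions per pathway
  expect_setequal(unique(convs$pathway),
                  c("inter_main", "inter_sub", "intra_main", "intra_sub"))
  expect_true(any(grepl("12x12", convs$layer)))
  expect_true(any(grepl("11x2", convs$layer)))
  expect_true(any(grepl("1x3", convs$layer)))
  expect_true(any(grepl("2x2", convs$layer)))
  ## closed-form parameter count: conv kernels + dense + output head
  f <- cfg$filters
  conv_params <- sum(vapply(1:4, function(p) {
    k <- prod(cfg$kernel_matrix[p, ])
    (k * f + f) + 2 * (k * f * f + f)
  }, 1))
  flat <- 4 * f * 50 * 50
  expect_equal(attr(arch, "total_params"),
               conv_params + (flat * 128 + 128) + (128 + 1))
  ## count depends only on the configuration
  expect_equal(attr(tcn_architecture(cfg), "total_params"),
               attr(arch, "total_params"))
})

test_that("model construction is deterministic in the seed", {
  m1 <- textconvonet(tiny_cfg())
  m2 <- textconvonet(tiny_cfg())
  expect_identical(m1$weights, m2$weights)
  ## weight shapes carry the configured parameter count
  n_par <- sum(vapply(rapply(m1$weights, length, how = "unlist"), sum, 1))
  expect_equal(n_par, attr(tcn_architecture(tiny_cfg()), "total_params"))
})

test_that("the compiled forward pass matches an independent R reference", {
  cfg <- tiny_cfg()
  m <- textconvonet(cfg)
  x <- rand_x(cfg, 4, seed = 3)
  p_cpp <- predict(m, x)
  p_ref <- vapply(1:4, function(k) tcn_forward_ref(cfg, m$weights, x[, , k]),
                  1)
  expect_equal(unname(p_cpp), p_ref, tolerance = 1e-5)
})

test_that("analytic gradients match fp64 finite differences of the reference", {
  cfg <- tcn_config(max_tokens = 8, dims = 6, filters = 2,
                    kernels = list(inter_main = c(3, 3), inter_sub = c(2, 2),
                                   intra_main = c(3, 2), intra_sub = c(1, 3)),
                    seed = 3)
  m <- textconvonet(cfg)
  x <- rand_x(cfg, 5, seed = 2)
  y <- c(0, 1, 0, 1, 1)
  lg <- misinfonet:::tcn_loss_grad_cpp(cfg, m$weights, x, y)
  loss_ref <- function(w) {
    ps <- vapply(1:5, function(k) tcn_forward_ref(cfg, w, x[, , k]), 1)
    mean(-(y * log(ps) + (1 - y) * log(1 - ps)))
  }
  eps <- 1e-6
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(11)
  for (p in 1:4) for (nm in c("W1", "W2", "W3", "b2")) {
    W <- m$weights$pathways[[p]][[nm]]
    G <- lg$grads$pathways[[p]][[nm]]
    for (i in sample(length(W), 2)) {
      wp <- m$weights; wm <- m$weights
      wp$pathways[[p]][[nm]][i] <- W[i] + eps
      wm$pathways[[p]][[nm]][i] <- W[i] - eps
      num <- (loss_ref(wp) - loss_ref(wm)) / (2 * eps)
      expect_equal(G[i], num, tolerance = 5e-3)
    }
  }
  for (nm in c("Wd", "Wo", "bo")) {
    W <- m$weights[[nm]]; G <- lg$grads[[nm]]
    i <- sample(length(W), 1)
    wp <- m$weights; wm <- m$weights
    wp[[nm]][i] <- W[i] + eps; wm[[nm]][i] <- W[i] - eps
    num <- (loss_ref(wp) - loss_ref(wm)) / (2 * eps)
    expect_equal(G[i], num, tolerance = 5e-3)
  }
})

test_that("prediction is a deterministic probability in (0,1)", {
  cfg <- tiny_cfg()
  m <- textconvonet(cfg)
  x <- rand_x(cfg, 6)
  p <- predict(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_length(p, 6)
  ## dropout is inactive at inference: repeated calls agree exactly
  expect_identical(p, predict(m, x))
  ## identical documents in one batch get identical probabilities
  x[, , 2] <- x[, , 1]
  p2 <- predict(m, x)
  expect_identical(p2[1], p2[2])
  ## degenerate all-zero (padding-only) input is tolerated
  x0 <- array(0, c(cfg$max_tokens, cfg$dims, 1))
  expect_true(predict(m, x0) > 0 && predict(m, x0) < 1)
  ## hard labels use the 0.5 cutoff
  expect_equal(predict(m, x, type = "class"), as.numeric(p2 > 0.5))
  ## shape mismatches are refused
  expect_error(predict(m, array(0, c(5, 5, 2))), "shape")
})

test_that("training runs the configured epochs, reproducibly", {
  cfg <- tiny_cfg()
  sep <- make_separable_tokens(60, seed = 2)
  pr <- hash_provider(cfg$dims, 1)
  x <- build_matrices(sep$tokens, pr, cfg$max_tokens)
  m1 <- train_textconvonet(textconvonet(cfg), x, sep$y, validation = 0.2)
  expect_equal(nrow(m1$history), cfg$epochs)
  expect_true(all(m1$history$loss >= 0))
  expect_true(all(m1$history$accuracy >= 0 & m1$history$accuracy <= 1))
  expect_true(all(!is.na(m1$history$val_loss)))
  ## bit-identical rerun under the same seed and data
  m2 <- train_textconvonet(textconvonet(cfg), x, sep$y, validation = 0.2)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  ## a single-class training set is refused
  expect_error(train_textconvonet(textconvonet(cfg), x, rep(1, 60)),
               "single class")
  ## overlapping train/validation ids are refused
  expect_error(train_textconvonet(textconvonet(cfg), x, sep$y,
                                  ids = c("a", "b"),
                                  validation_ids = c("b", "c")),
               "share")
})

test_that("training reduces the loss on a separable corpus", {
  cfg <- tcn_config(max_tokens = 20, dims = 16, filters = 2,
                    kernels = list(inter_main = c(5, 5),
                                   inter_sub = c(2, 2),
                                   intra_main = c(4, 2),
                                   intra_sub = c(1, 3)),
                    batch_size = 32, epochs = 5, seed = 7,
                    learning_rate = 1e-3)
  sep <- make_separable_tokens(400, seed = 9)
  x <- build_matrices(sep$tokens, hash_provider(cfg$dims, 2),
                      cfg$max_tokens)
  m <- train_textconvonet(textconvonet(cfg), x, sep$y, validation = NULL)
  h <- m$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
})
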