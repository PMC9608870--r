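test_that("shape trace reproduces the printed architecture arithmetic", {
  m <- build_cnn(c(60, 120), channels = c(64, 128), hidden = c(256, 64),
                 seed = 1)
  tr <- cnn_shape_trace(m)
  conv_pool <- tr[tr$type %in% c("conv", "pool"), "out_shape"]
  expect_equal(conv_pool,
               c("58x118x64", "56x116x64", "28x58x64",
                 "26x56x128", "24x54x128", "12x27x128"))
  expect_equal(tr$out_dim[tr$type == "flatten"], 41472)
})

test_that("undersized inputs raise a shape underflow error", {
  expect_error(build_cnn(c(12, 12), channels = c(2, 2), hidden = c(4, 2)),
               "too small")
})

test_that("weight initialization is a pure function of the seed", {
  a <- tiny_cnn(seed = 7)
  b <- tiny_cnn(seed = 7)
  expect_identical(a, b)
  c <- tiny_cnn(seed = 8)
  expect_false(identical(a$layers[[1]]$K, c$layers[[1]]$K))
})

test_that("all-zero weights give probability exactly 0.5", {
  m <- tiny_cnn()
  for (i in seq_along(m$layers)) {
    l <- m$layers[[i]]
    if (l$type == "conv") { m$layers[[i]]$K[] <- 0; m$layers[[i]]$bias[] <- 0 }
    if (l$type == "dense") { m$layers[[i]]$W[] <- 0; m$layers[[i]]$b[] <- 0 }
  }
  x <- matrix(rnorm(3 * 16 * 18), 3)
  expect_equal(predict(m, x), rep(0.5, 3))
})

test_that("probabilities are strictly inside (0,1) and eval mode is pure", {
  m <- tiny_cnn()
  x <- matrix(rnorm(4 * 16 * 18), 4)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("convolution forward matches a direct double-loop oracle", {
  H <- 5L; W <- 6L; C <- 2L; cout <- 3L
  geom <- cortexlrp:::conv_geometry(c(H, W, C))
  set.seed(10)
  K <- matrix(rnorm(geom$Q * cout), geom$Q, cout)
  bias <- rnorm(cout)
  layer <- list(type = "conv", geom = geom, K = K, bias = bias,
                in_shape = c(H, W, C), out_shape = c(geom$out_hw, cout))
  x <- rnorm(H * W * C)
  out <- cortexlrp:::conv_forward(matrix(x, 1), layer)$out
  xa <- array(x, dim = c(H, W, C))
  ka <- array(K, dim = c(3, 3, C, cout))
  H2 <- H - 2L; W2 <- W - 2L
  oracle <- array(0, dim = c(H2, W2, cout))
  for (co in 1:cout) for (r in 1:H2) for (cc in 1:W2) {
    acc <- bias[co]
    for (dr in 0:2) for (dc in 0:2) for (ch in 1:C) {
      acc <- acc + xa[r + dr, cc + dc, ch] * ka[dr + 1, dc + 1, ch, co]
    }
    oracle[r, cc, co] <- acc
  }
  expect_equal(as.vector(out), as.vector(oracle), tolerance = 1e-12)
})

test_that("backprop gradients match numeric differentiation", {
  m <- strip_biases(tiny_cnn(seed = 12))
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$type == "dropout") m$layers[[i]]$rate <- 0
  }
  set.seed(13)
  n <- 4
  x <- matrix(rnorm(n * 16 * 18), n)
  y <- c(1, 0, 1, 0)
  fwd <- cortexlrp:::forward_cnn(m, x, train = TRUE, keep = TRUE)
  grads <- cortexlrp:::backward_cnn(m, fwd$cache, (fwd$prob - y) / n)
  loss_at <- function(model) {
    f <- cortexlrp:::forward_cnn(model, x)
    cortexlrp:::bce_from_logits(f$logit, y)
  }
  eps <- 1e-5
  for (li in seq_along(m$layers)) {
    l <- m$layers[[li]]
    if (!l$type %in% c("conv", "dense")) next
    key <- if (l$type == "conv") "K" else "W"
    gkey <- if (l$type == "conv") "dK" else "dW"
    for (j in sample(length(l[[key]]), 3)) {
      mp <- m; mp$layers[[li]][[key]][j] <- mp$layers[[li]][[key]][j] + eps
      mm <- m; mm$layers[[li]][[key]][j] <- mm$layers[[li]][[key]][j] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[li]][[gkey]][j], num,
                   tolerance = 1e-4, label = paste("layer", li, "w", j))
    }
  }
})

test_that("binary cross-entropy at p = 0.5 is ln 2", {
  expect_equal(cortexlrp:::bce_from_logits(0, 1), log(2))
  expect_equal(cortexlrp:::bce_from_logits(0, 0), log(2))
  # stability at extreme logits
  expect_true(is.finite(cortexlrp:::bce_from_logits(500, 0)))
  expect_true(is.finite(cortexlrp:::bce_from_logits(-500, 1)))
})

test_that("training drives accuracy to 1 on linearly separable blobs", {
  d <- separable_images(n_per_class = 40, shift = 3)
  sp <- split_validation(seq_along(d$y), d$y, fraction = 1 / 11, seed = 2)
  fit <- train_cnn(tiny_cnn(seed = 3),
                   d$x[sp$train, ], d$y[sp$train],
                   d$x[sp$val, ], d$y[sp$val],
                   lr = 5e-3, batch_size = 16, max_epochs = 40, patience = 12,
                   seed = 4)
  # evaluation-mode accuracy on the training set (history$train_acc is
  # measured under dropout and lags behind)
  train_acc <- mean((predict(fit$model, d$x[sp$train, ]) >= 0.5) ==
                      d$y[sp$train])
  expect_gte(train_acc, 0.95)
  expect_gte(fit$best_val_acc, 0.9)
})

test_that("early stopping halts when validation accuracy is frozen", {
  d <- separable_images(n_per_class = 10)
  fit <- train_cnn(tiny_cnn(seed = 3), d$x[1:16, ], d$y[1:16],
                   d$x[17:20, ], d$y[17:20],
                   lr = 0, max_epochs = 50, patience = 1, seed = 5)
  # lr = 0: no epoch can improve on the first; stops at best + 1
  expect_lte(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
})

test_that("zero learning rate leaves weights untouched", {
  m0 <- tiny_cnn(seed = 6)
  d <- separable_images(n_per_class = 8)
  fit <- train_cnn(m0, d$x[1:12, ], d$y[1:12], d$x[13:16, ], d$y[13:16],
                   lr = 0, max_epochs = 3, patience = 10, seed = 7)
  expect_identical(cortexlrp:::get_params(fit$model),
                   cortexlrp:::get_params(m0))
  # evaluation-mode accuracy cannot move with frozen weights (training loss
  # still fluctuates through dropout masks)
  expect_equal(diff(range(fit$history$val_acc)), 0, tolerance = 1e-12)
})

test_that("learning-rate grid search picks the rate that can learn", {
  d <- separable_images(n_per_class = 25, shift = 3)
  builder <- function() tiny_cnn(seed = 8)
  one <- grid_search_lr(builder, d$x, d$y, grid = 5e-4, seed = 9,
                        max_epochs = 2, patience = 2)
  expect_equal(one$lr, 5e-4)
  gs1 <- grid_search_lr(builder, d$x, d$y, grid = c(5e-3, 1e-30), seed = 9,
                        max_epochs = 20, patience = 8, batch_size = 16)
  expect_equal(gs1$lr, 5e-3)
  gs2 <- grid_search_lr(builder, d$x, d$y, grid = c(5e-3, 1e-30), seed = 9,
                        max_epochs = 20, patience = 8, batch_size = 16)
  expect_identical(gs1$lr, gs2$lr)
  expect_identical(gs1$results, gs2$results)
})
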