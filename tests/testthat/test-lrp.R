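test_that("dense propagation reproduces hand-worked relevance flows", {
  # identity unit: weight 1, bias 0, a = 1
  r <- propagate_dense(matrix(2.5), matrix(1), 0, matrix(1), rule = "lrp0")
  expect_equal(as.vector(r), 2.5)

  # 2 -> 1, a = (1,1), w = (3,1), R_out = 4: z = (3,1), denom 4 -> R = (3,1)
  r2 <- propagate_dense(matrix(4), matrix(c(3, 1), 2, 1), 0,
                        matrix(c(1, 1), 1), rule = "lrp0")
  expect_equal(as.vector(r2), c(3, 1))

  # large gamma suppresses the negative-weight contribution entirely
  r3 <- propagate_dense(matrix(4), matrix(c(3, -1), 2, 1), 0,
                        matrix(c(1, 1), 1), rule = "gamma", gamma = 1e8)
  expect_equal(as.vector(r3), c(4, 0), tolerance = 1e-6)

  # epsilon shrinks relevance monotonically and vanishes as eps -> Inf
  W <- matrix(c(2, -1, 0.5, 1), 2, 2)
  A <- matrix(c(1, 2), 1)
  Rn <- matrix(c(1, 1), 1)
  small <- propagate_dense(Rn, W, c(0, 0), A, rule = "epsilon", eps = 0.01)
  big <- propagate_dense(Rn, W, c(0, 0), A, rule = "epsilon", eps = 100)
  huge <- propagate_dense(Rn, W, c(0, 0), A, rule = "epsilon", eps = 1e12)
  expect_lt(sum(abs(big)), sum(abs(small)))
  expect_lt(max(abs(huge)), 1e-9)
})

test_that("two-layer toy network matches full pencil-and-paper LRP", {
  # input a = (1,2); W1 = [[1,-1],[2,0]] (columns = hidden units), b = 0
  # pre-activations z = (5,-1); ReLU -> h = (5,0); w2 = (1,1) -> out 5
  A <- matrix(c(1, 2), 1)
  W1 <- matrix(c(1, 2, -1, 0), 2, 2)
  h <- pmax(A %*% W1, 0)
  expect_equal(as.vector(h), c(5, 0))
  W2 <- matrix(c(1, 1), 2, 1)
  out <- as.vector(h %*% W2)
  expect_equal(out, 5)

  # lrp0 through layer 2: denom = 5, R_hidden = h * w2 * (5/5) = (5,0)
  Rh <- propagate_dense(matrix(out), W2, 0, h, rule = "lrp0")
  expect_equal(as.vector(Rh), c(5, 0))

  # lrp0 through layer 1: s = (1, 0); c = W1 s = (1,2); R = a*c = (1,4)
  Ri <- propagate_dense(Rh, W1, c(0, 0), A, rule = "lrp0")
  expect_equal(as.vector(Ri), c(1, 4))
  expect_equal(sum(Ri), out)   # conservation

  # epsilon on layer 1 (eps = 0.01): s = (5/5.01, 0/-1.01)
  Re <- propagate_dense(Rh, W1, c(0, 0), A, rule = "epsilon", eps = 0.01)
  expect_equal(as.vector(Re), c(1 * (5 / 5.01), 2 * 2 * (5 / 5.01)),
               tolerance = 1e-12)
})

test_that("lrp0 conserves relevance through bias-free layers", {
  set.seed(41)
  for (k in 1:25) {
    d <- sample(3:10, 1); h <- sample(2:8, 1); n <- sample(1:3, 1)
    A <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * h), d, h)
    Rn <- matrix(rnorm(n * h), n, h)
    Rp <- suppressWarnings(propagate_dense(Rn, W, numeric(h), A, "lrp0"))
    expect_equal(rowSums(Rp), rowSums(Rn), tolerance = 1e-6)
  }
})

test_that("conv propagation equals dense propagation on the unrolled matrix", {
  m <- tiny_cnn(seed = 15)
  set.seed(42)
  for (li in which(vapply(m$layers, function(l) l$type == "conv", logical(1)))) {
    lay <- m$layers[[li]]
    n <- 2
    A <- matrix(rnorm(n * prod(lay$in_shape)), n)
    A <- pmax(A, 0)   # post-ReLU activations are non-negative
    Rn <- matrix(rnorm(n * prod(lay$out_shape)), n)
    Wd <- cortexlrp:::unroll_conv(lay)
    bias_d <- rep(lay$bias, each = lay$geom$P)
    for (rule in c("lrp0", "epsilon", "gamma")) {
      rc <- suppressWarnings(propagate_conv(Rn, lay, A, rule = rule))
      rd <- suppressWarnings(propagate_dense(Rn, Wd, bias_d, A, rule = rule))
      expect_equal(rc, rd, tolerance = 1e-7,
                   label = paste("layer", li, rule))
    }
  }
})

test_that("1x1 convolution with unit weight passes relevance through", {
  geom <- cortexlrp:::conv_geometry(c(3, 3, 1), 1L, 1L)
  lay <- list(type = "conv", geom = geom, K = matrix(1), bias = 0,
              in_shape = c(3, 3, 1), out_shape = c(3, 3, 1))
  A <- matrix(runif(9) + 0.5, 1)
  Rn <- matrix(rnorm(9), 1)
  expect_equal(propagate_conv(Rn, lay, A, "lrp0"), Rn, tolerance = 1e-12)
})

test_that("pooling relevance is winner-take-all with row-major ties", {
  geom <- cortexlrp:::pool_geometry(c(2, 2, 1))
  lay <- list(type = "pool", geom = geom, in_shape = c(2, 2, 1),
              out_shape = c(1, 1, 1))
  # column-major storage: (r1c1, r2c1, r1c2, r2c2) = (5, 1, 2, 3)
  X <- matrix(c(5, 1, 2, 3), 1)
  fw <- cortexlrp:::pool_forward(X, geom)
  r <- propagate_pool(matrix(7), lay, fw$sw)
  expect_equal(as.vector(r), c(7, 0, 0, 0))

  # tie: all equal -> first in row-major order, i.e. (r1, c1)
  Xt <- matrix(c(1, 1, 1, 1), 1)
  ft <- cortexlrp:::pool_forward(Xt, geom)
  rt <- propagate_pool(matrix(3), lay, ft$sw)
  expect_equal(as.vector(rt), c(3, 0, 0, 0))

  # conservation on a larger map
  geom2 <- cortexlrp:::pool_geometry(c(6, 8, 2))
  lay2 <- list(type = "pool", geom = geom2)
  set.seed(5)
  X2 <- matrix(rnorm(2 * 96), 2)
  f2 <- cortexlrp:::pool_forward(X2, geom2)
  R2 <- matrix(rnorm(2 * length(f2$out) / 2), 2)
  rp <- propagate_pool(R2, lay2, f2$sw)
  expect_equal(rowSums(rp), rowSums(R2), tolerance = 1e-12)
  expect_error(propagate_pool(R2, lay2, NULL), "switches")
})

test_that("composite explanation conserves the pre-sigmoid score under lrp0", {
  m <- strip_biases(tiny_cnn(seed = 16))
  comp <- lrp_composite(dense = "lrp0", block2 = "lrp0", block1 = "lrp0")
  set.seed(6)
  x <- matrix(rnorm(3 * 16 * 18), 3)
  rmap <- suppressWarnings(lrp_explain(m, x, composite = comp))
  f <- cortexlrp:::forward_cnn(m, x)
  init <- ifelse(f$prob >= 0.5, f$logit, -f$logit)
  expect_equal(rowSums(rmap$pixel), init, tolerance = 1e-6)
  expect_true(all(is.finite(rmap$pixel)))
})

test_that("back-projection equipartitions pixel relevance over vertices", {
  sp <- tiny_space(200)
  map <- build_projection_map(sp, 16)
  set.seed(8)
  R_px <- rnorm(prod(map$image_dim))
  vr <- pixel_to_vertex(R_px, map)
  expect_length(vr, sp$n_vertices)
  # vertex alone in its pixel gets the full pixel relevance
  solo <- which(map$counts[map$pixel] == 1)[1]
  expect_equal(vr[solo], R_px[map$pixel[solo]])
  # two vertices sharing a pixel split it evenly
  shared_px <- which(map$counts == 2)[1]
  if (!is.na(shared_px)) {
    vs <- which(map$pixel == shared_px)
    expect_equal(vr[vs], rep(R_px[shared_px] / 2, 2))
  }
  # conservation over non-empty pixels
  expect_equal(sum(vr), sum(R_px[map$counts > 0]), tolerance = 1e-9)
})

test_that("aggregation keeps only correctly classified trials", {
  px <- rbind(c(1, 2, 3, 4), c(-1, -2, -3, -4), c(1, 2, 3, 4))
  rmap <- structure(
    list(pixel = px, image_dim = c(2L, 2L),
         provenance = data.frame(trial = 1:3, subject = c("a", "a", "b"),
                                 prob = c(0.9, 0.8, 0.2),
                                 predicted = c(1, 1, 0),
                                 label = c(1, 0, 0),
                                 correct = c(TRUE, FALSE, TRUE))),
    class = "relevance_map")
  agg <- aggregate_relevance(rmap, scope = "pooled")
  expect_equal(as.vector(agg$pixel), c(1, 2, 3, 4))
  expect_equal(agg$n_aggregated, 2L)

  by_subj <- aggregate_relevance(rmap, scope = "subject")
  expect_equal(nrow(by_subj$pixel), 2L)

  # identical maps aggregate to themselves; r and -r cancel
  rmap$provenance$correct <- c(TRUE, TRUE, FALSE)
  agg2 <- aggregate_relevance(rmap, scope = "pooled")
  expect_equal(as.vector(agg2$pixel), rep(0, 4))

  rmap$provenance$correct <- c(FALSE, FALSE, FALSE)
  expect_error(aggregate_relevance(rmap), "no correctly classified")
})
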