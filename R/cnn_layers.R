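# Internal layer machinery for the compact VGG-style CNN.
#
# Feature maps are stored flat: a batch is an n x (H*W*C) matrix whose columns
# follow R's column-major array order dim = c(H, W, C) (rows fastest, then
# columns, then channels). Convolutions use valid padding and stride 1 and are
# computed by im2col gathering followed by one BLAS GEMM; the transpose
# (scatter) direction is a precomputed sparse matrix product. Max pooling is
# 2 x 2, stride 2, with floor on odd sizes.

conv_geometry <- function(in_shape, kh = 3L, kw = 3L) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  H2 <- H - kh + 1L; W2 <- W - kw + 1L
  if (H2 < 1L || W2 < 1L) {
    stop_("input ", H, "x", W, " too small for a valid ", kh, "x", kw,
          " convolution")
  }
  P <- H2 * W2
  Q <- kh * kw * C
  p_r <- rep(seq_len(H2), times = W2)
  p_c <- rep(seq_len(W2), each = H2)
  dr_q <- rep(seq_len(kh), times = kw * C)
  dc_q <- rep(rep(seq_len(kw), each = kh), times = C)
  ch_q <- rep(seq_len(C), each = kh * kw)
  idxmat <- outer(p_r, dr_q - 1L, `+`) +
    H * outer(p_c - 1L, dc_q - 1L, `+`) +
    matrix(H * W * (ch_q - 1L), P, Q, byrow = TRUE)
  idx <- as.integer(idxmat)
  S <- Matrix::sparseMatrix(i = seq_len(P * Q), j = idx, x = 1,
                            dims = c(P * Q, H * W * C))
  list(in_shape = in_shape, out_hw = c(H2, W2), P = P, Q = Q,
       idx = idx, S = S)
}

# Linear part of the convolution: X (n x HWC) -> n x (P*Cout).
conv_lin_fwd <- function(X, geom, K, keep_cols = FALSE) {
  n <- nrow(X)
  A <- X[, geom$idx, drop = FALSE]
  dim(A) <- c(n * geom$P, geom$Q)
  Z <- A %*% K
  dim(Z) <- c(n, geom$P * ncol(K))
  if (keep_cols) list(out = Z, A = A) else list(out = Z)
}

# Transpose of the convolution: V (n x P*Cout) -> n x HWC.
conv_lin_bwd <- function(V, geom, K) {
  n <- nrow(V)
  dim(V) <- c(n * geom$P, ncol(K))
  dA <- V %*% t(K)
  dim(dA) <- c(n, geom$P * geom$Q)
  as.matrix(dA %*% geom$S)
}

conv_forward <- function(X, layer, keep_cols = FALSE) {
  f <- conv_lin_fwd(X, layer$geom, layer$K, keep_cols)
  n <- nrow(X)
  cout <- ncol(layer$K)
  f$out <- f$out + rep(layer$bias, each = n * layer$geom$P)
  f
}

conv_backward <- function(dOut, A, layer) {
  n2 <- nrow(A)                     # n * P
  cout <- ncol(layer$K)
  dZ <- dOut
  dim(dZ) <- c(n2, cout)
  dK <- crossprod(A, dZ)
  db <- colSums(dZ)
  dA <- dZ %*% t(layer$K)
  dim(dA) <- c(nrow(dOut), layer$geom$P * layer$geom$Q)
  dX <- as.matrix(dA %*% layer$geom$S)
  list(dX = dX, dK = dK, db = db)
}

pool_geometry <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  if (H2 < 1L || W2 < 1L) stop_("input ", H, "x", W, " too small for 2x2 pooling")
  np <- H2 * W2 * C
  u_r <- rep(seq_len(H2), times = W2 * C)
  u_c <- rep(rep(seq_len(W2), each = H2), times = C)
  u_ch <- rep(seq_len(C), each = H2 * W2)
  # window offsets in row-major order (ties go to the first in row-major)
  offs <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  pidx <- integer(np * 4L)
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    pidx[(k - 1L) * np + seq_len(np)] <-
      (2L * (u_r - 1L) + dr) + H * (2L * (u_c - 1L) + dc - 1L) +
      H * W * (u_ch - 1L)
  }
  list(in_shape = in_shape, out_hw = c(H2, W2), np = np, pidx = pidx)
}

pool_forward <- function(X, geom) {
  n <- nrow(X)
  G <- X[, geom$pidx, drop = FALSE]
  dim(G) <- c(n * geom$np, 4L)
  sw <- max.col(G, ties.method = "first")
  vals <- G[cbind(seq_len(n * geom$np), sw)]
  out <- matrix(vals, n, geom$np)
  list(out = out, sw = sw)
}

# Routes dOut (n x np) back to the argmax inputs recorded in sw.
pool_backward <- function(dOut, geom, sw) {
  n <- nrow(dOut)
  np <- geom$np
  D <- prod(geom$in_shape)
  i <- seq_len(n * np)
  b <- ((i - 1L) %% n) + 1L
  u <- ((i - 1L) %/% n) + 1L
  col <- geom$pidx[(sw - 1L) * np + u]
  dX <- matrix(0, n, D)
  dX[cbind(b, col)] <- as.vector(dOut)
  dX
}

dense_forward <- function(X, layer) {
  X %*% layer$W + rep(layer$b, each = nrow(X))
}

dense_backward <- function(dOut, X, layer) {
  list(dX = dOut %*% t(layer$W),
       dW = crossprod(X, dOut),
       db = colSums(dOut))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  softplus_mz <- pmax(-z, 0) + log1p(exp(-abs(z)))
  mean(softplus_mz + (1 - y) * z)
}
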