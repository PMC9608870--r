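#' Build the VGG-style convolutional classifier
#'
#' Constructs the layer stack used throughout: two 3x3 valid convolutions
#' (ReLU) followed by one 2x2 max pooling, repeated twice, then flattening
#' and three fully connected layers, the first two with ReLU and 50% dropout
#' and the last a single sigmoid output unit (patient = 1). With the default
#' 60x120 input and channel plan `c(64, 128)` the spatial trace is
#' 58x118 -> 56x116 -> 28x58 -> 26x56 -> 24x54 -> 12x27, so the flattened
#' dimension is 128 * 12 * 27 = 41472. Weights use seeded Glorot-uniform
#' initialization; biases start at zero.
#'
#' @param input_shape `c(height, width)` of the single-channel input image.
#' @param channels channel counts of the first and second convolution blocks
#'   (default `c(64, 128)`).
#' @param hidden sizes of the two hidden fully connected layers
#'   (default `c(256, 64)`).
#' @param dropout dropout rate of the hidden dense layers (default 0.5).
#' @param seed integer seed for weight initialization; the same seed yields
#'   identical initial weights.
#' @return object of class `cnn_model`: list with `layers`, `input_shape`,
#'   `channels`, `hidden`, `seed`.
#' @examples
#' m <- build_cnn(c(12, 24), channels = c(2, 3), hidden = c(8, 4))
#' cnn_shape_trace(m)
#' @export
build_cnn <- function(input_shape = c(60, 120), channels = c(64, 128),
                      hidden = c(256, 64), dropout = 0.5, seed = 1L) {
  stopifnot(length(input_shape) == 2L, length(channels) == 2L,
            length(hidden) == 2L, dropout >= 0, dropout < 1)
  shape <- c(as.integer(input_shape), 1L)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }

  with_seed(seed, {
    plan <- list(c("block1", channels[1]), c("block1", channels[1]),
                 "pool",
                 c("block2", channels[2]), c("block2", channels[2]),
                 "pool")
    for (item in plan) {
      if (identical(item, "pool")) {
        geom <- pool_geometry(shape)
        add(list(type = "pool", block = NA_character_, geom = geom,
                 in_shape = shape,
                 out_shape = c(geom$out_hw, shape[3])))
        shape <- c(geom$out_hw, shape[3])
      } else {
        cout <- as.integer(item[2])
        geom <- conv_geometry(shape)
        K <- glorot(geom$Q, cout, fan_in = geom$Q, fan_out = 9L * cout)
        add(list(type = "conv", block = item[1], geom = geom, K = K,
                 bias = numeric(cout), in_shape = shape,
                 out_shape = c(geom$out_hw, cout)))
        shape <- c(geom$out_hw, cout)
        add(list(type = "relu", block = item[1], in_shape = shape,
                 out_shape = shape))
      }
    }

    flat <- prod(shape)
    add(list(type = "flatten", block = NA_character_, in_shape = shape,
             out_shape = flat))
    d_in <- flat
    for (h in hidden) {
      add(list(type = "dense", block = "dense",
               W = glorot(d_in, h, d_in, h), b = numeric(h),
               in_shape = d_in, out_shape = h))
      add(list(type = "relu", block = "dense", in_shape = h, out_shape = h))
      add(list(type = "dropout", block = "dense", rate = dropout,
               in_shape = h, out_shape = h))
      d_in <- h
    }
    add(list(type = "dense", block = "dense",
             W = glorot(d_in, 1L, d_in, 1L), b = numeric(1L),
             in_shape = d_in, out_shape = 1L))
  })

  structure(
    list(layers = layers, input_shape = as.integer(input_shape),
         channels = as.integer(channels), hidden = as.integer(hidden),
         dropout = dropout, seed = as.integer(seed)),
    class = "cnn_model"
  )
}

#' Per-layer shape trace of a CNN
#'
#' @param model a `cnn_model`.
#' @return data frame with one row per layer: `layer`, `type`, `block`,
#'   `out_shape` (text) and `out_dim` (total units).
#' @export
cnn_shape_trace <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  rows <- lapply(seq_along(model$layers), function(i) {
    l <- model$layers[[i]]
    out <- l$out_shape
    data.frame(layer = i, type = l$type,
               block = l$block %||% NA_character_,
               out_shape = paste(out, collapse = "x"),
               out_dim = prod(out), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Full forward pass. X: n x (H*W) matrix (single input channel, flat
# column-major). When `keep = TRUE` the per-layer inputs, im2col matrices,
# pool switches and dropout masks are cached for backprop / LRP.
forward_cnn <- function(model, X, train = FALSE, keep = FALSE) {
  n <- nrow(X)
  cache <- if (keep) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (keep) cache[[i]] <- list(input = X)
    X <- switch(
      l$type,
      conv = {
        f <- conv_forward(X, l, keep_cols = keep && train)
        if (keep && train) cache[[i]]$A <- f$A
        f$out
      },
      relu = pmax(X, 0),
      pool = {
        f <- pool_forward(X, l$geom)
        if (keep) cache[[i]]$sw <- f$sw
        f$out
      },
      flatten = X,
      dense = dense_forward(X, l),
      dropout = {
        if (train) {
          mask <- matrix((runif(n * l$out_shape) >= l$rate) / (1 - l$rate),
                         n, l$out_shape)
          if (keep) cache[[i]]$mask <- mask
          X * mask
        } else X
      },
      stop_("unknown layer type ", l$type)
    )
  }
  logit <- as.vector(X)
  list(logit = logit, prob = sigmoid(logit), cache = cache)
}

# Backward pass; returns list of gradients parallel to model$layers
# (NULL for parameterless layers) given d(loss)/d(logit).
backward_cnn <- function(model, cache, dlogit) {
  n <- length(dlogit)
  d <- matrix(dlogit, n, 1)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cc <- cache[[i]]
    d <- switch(
      l$type,
      dense = {
        g <- dense_backward(d, cc$input, l)
        grads[[i]] <- list(dW = g$dW, db = g$db)
        g$dX
      },
      conv = {
        g <- conv_backward(d, cc$A, l)
        grads[[i]] <- list(dK = g$dK, db = g$db)
        g$dX
      },
      relu = d * (cc$input > 0),
      pool = pool_backward(d, l$geom, cc$sw),
      flatten = d,
      dropout = if (is.null(cc$mask)) d else d * cc$mask
    )
  }
  grads
}

#' Predict method for CNN models
#'
#' Deterministic evaluation-mode forward pass (dropout disabled), computed in
#' mini-batches to bound memory.
#'
#' @param object a `cnn_model`.
#' @param newdata matrix n x pixels (flat images) or a `trial_images` object.
#' @param type `"prob"` for sigmoid probabilities, `"class"` for 0/1 labels
#'   at the 0.5 threshold (ties to the positive/patient class), `"logit"`
#'   for the pre-sigmoid score.
#' @param batch_size mini-batch size for the forward pass.
#' @param ... unused.
#' @return numeric vector of length n.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class", "logit"),
                              batch_size = 128L, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "trial_images")) newdata$images else as.matrix(newdata)
  if (ncol(X) != prod(object$input_shape)) {
    stop_("newdata has ", ncol(X), " pixels; model expects ",
          prod(object$input_shape))
  }
  n <- nrow(X)
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    rows <- s:min(s + batch_size - 1L, n)
    f <- forward_cnn(object, X[rows, , drop = FALSE])
    out[rows] <- if (type == "logit") f$logit else f$prob
  }
  if (type == "class") out <- as.numeric(out >= 0.5)
  out
}

#' @export
print.cnn_model <- function(x, ...) {
  tr <- cnn_shape_trace(x)
  n_par <- sum(vapply(x$layers, function(l) {
    length(l$K %||% numeric(0)) + length(l$bias %||% numeric(0)) +
      length(l$W %||% numeric(0)) + length(l$b %||% numeric(0))
  }, numeric(1)))
  cat("VGG-style CNN,", paste(x$input_shape, collapse = "x"),
      "input,", format(n_par, big.mark = ","), "parameters\n")
  print(tr, row.names = FALSE)
  invisible(x)
}
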