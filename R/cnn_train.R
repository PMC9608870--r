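# Adam-based training of the CNN with early stopping on validation accuracy.

# Extract / restore trainable parameters as a flat list keyed by layer index.
get_params <- function(model) {
  lapply(model$layers, function(l) {
    switch(l$type,
           conv = list(K = l$K, bias = l$bias),
           dense = list(W = l$W, b = l$b),
           NULL)
  })
}

set_params <- function(model, params) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p)) next
    if (!is.null(p$K)) {
      model$layers[[i]]$K <- p$K
      model$layers[[i]]$bias <- p$bias
    } else {
      model$layers[[i]]$W <- p$W
      model$layers[[i]]$b <- p$b
    }
  }
  model
}

#' Train the CNN with Adam, binary cross-entropy and early stopping
#'
#' Minimizes binary cross-entropy with the Adam optimizer
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). After every epoch the accuracy
#' on the validation set is evaluated; training stops when it has not
#' improved for `patience` consecutive epochs (or at `max_epochs`), and the
#' weights achieving the best validation accuracy are returned.
#'
#' @param model a `cnn_model`.
#' @param x,y training images (n x pixels) and 0/1 labels (patient = 1).
#' @param x_val,y_val validation images and labels, disjoint from training.
#' @param lr learning rate.
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs epoch cap (default 300).
#' @param patience early-stopping patience in epochs (default 20).
#' @param seed seed for shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation weights), `history` (data
#'   frame: epoch, train_loss, train_acc, val_acc), `best_epoch`,
#'   `best_val_acc`, `lr`.
#' @export
train_cnn <- function(model, x, y, x_val, y_val, lr = 1e-3,
                      batch_size = 64L, max_epochs = 300L, patience = 20L,
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  if (nrow(x) == 0L || nrow(x_val) == 0L) stop_("empty training or validation set")
  if (!all(y %in% c(0, 1)) || !all(y_val %in% c(0, 1))) {
    stop_("labels must be 0/1")
  }
  if (patience < 1L) stop_("patience must be >= 1")
  n <- nrow(x)

  # Adam state parallel to the parameter list
  params <- get_params(model)
  zero_like <- function(p) if (is.null(p)) NULL else lapply(p, function(t) t * 0)
  m_state <- lapply(params, zero_like)
  v_state <- lapply(params, zero_like)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  best_val <- -Inf
  best_params <- get_params(model)
  best_epoch <- 0L
  since_best <- 0L

  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      losses <- c(); accs <- c()
      for (s in seq(1L, n, by = batch_size)) {
        rows <- ord[s:min(s + batch_size - 1L, n)]
        xb <- x[rows, , drop = FALSE]
        yb <- y[rows]
        fwd <- forward_cnn(model, xb, train = TRUE, keep = TRUE)
        losses <- c(losses, bce_from_logits(fwd$logit, yb))
        accs <- c(accs, mean((fwd$prob >= 0.5) == yb))
        dlogit <- (fwd$prob - yb) / length(yb)
        grads <- backward_cnn(model, fwd$cache, dlogit)

        if (lr != 0) {
          t_step <- t_step + 1L
          bc1 <- 1 - b1^t_step
          bc2 <- 1 - b2^t_step
          for (i in seq_along(grads)) {
            g <- grads[[i]]
            if (is.null(g)) next
            l <- model$layers[[i]]
            if (l$type == "conv") {
              gl <- list(g$dK, g$db); keys <- c("K", "bias")
            } else {
              gl <- list(g$dW, g$db); keys <- c("W", "b")
            }
            for (k in 1:2) {
              m_state[[i]][[k]] <- b1 * m_state[[i]][[k]] + (1 - b1) * gl[[k]]
              v_state[[i]][[k]] <- b2 * v_state[[i]][[k]] + (1 - b2) * gl[[k]]^2
              upd <- lr * (m_state[[i]][[k]] / bc1) /
                (sqrt(v_state[[i]][[k]] / bc2) + adam_eps)
              model$layers[[i]][[keys[k]]] <- model$layers[[i]][[keys[k]]] - upd
            }
          }
        }
      }

      val_prob <- predict(model, x_val)
      val_acc <- mean((val_prob >= 0.5) == y_val)
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), mean(accs),
                                            val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %.3f",
                        epoch, mean(losses), mean(accs), val_acc))
      }
      if (val_acc > best_val) {
        best_val <- val_acc
        best_params <- get_params(model)
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
    }
  })

  list(model = set_params(model, best_params), history = history,
       best_epoch = best_epoch, best_val_acc = best_val, lr = lr)
}

#' Grid search over the learning rate
#'
#' Trains one model per candidate learning rate on the same seeded
#' training/validation split and returns the rate with the highest
#' validation accuracy; ties go to the smaller rate.
#'
#' @param model_builder zero-argument function returning a fresh (identically
#'   initialized) `cnn_model`.
#' @param x,y training images and labels (the split into train/validation is
#'   done internally).
#' @param grid numeric vector of candidate learning rates.
#' @param val_fraction fraction held out for validation (default 1/11).
#' @param seed seed for the split and for each training run.
#' @param ... further arguments passed to [train_cnn()]
#'   (`batch_size`, `max_epochs`, `patience`).
#' @return list with `lr` (selected rate), `results` (data frame of rate and
#'   validation accuracy) and `fits` (the per-rate training results).
#' @export
grid_search_lr <- function(model_builder, x, y, grid,
                           val_fraction = 1 / 11, seed = 1L, ...) {
  if (!length(grid)) stop_("learning-rate grid must be non-empty")
  grid <- sort(unique(grid))
  sp <- split_validation(seq_len(nrow(x)), y, fraction = val_fraction,
                         seed = seed)
  fits <- lapply(grid, function(lr) {
    train_cnn(model_builder(), x[sp$train, , drop = FALSE], y[sp$train],
              x[sp$val, , drop = FALSE], y[sp$val],
              lr = lr, seed = seed, ...)
  })
  accs <- vapply(fits, `[[`, numeric(1), "best_val_acc")
  pick <- which(accs == max(accs))[1]   # grid sorted ascending: ties -> smaller
  list(lr = grid[pick],
       results = data.frame(lr = grid, val_acc = accs),
       fits = fits)
}
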