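# Composite layer-wise relevance propagation (LRP) through the CNN.
#
# All three rules share one algebraic skeleton. For a linear layer
# z_k = sum_j a_j w_jk + b_k, relevance flows backward as
#   R_j = sum_k (z_jk^mod / z_k^mod) R_k,   z_jk = a_j w_jk,
# where the modification depends on the rule:
#   lrp0:     z^mod = z                      (denominator = z_k + b_k)
#   epsilon:  denominator gains eps * sign(z_k)
#   gamma:    z^mod = z + gamma * z^+, applied elementwise; since
#             (a w)^+ = a^+ w^+ + a^- w^-, the modified forward/backward
#             pass splits into three plain linear passes.
# Bias terms enter the denominator but receive no redistributed relevance,
# so for bias-free layers every rule conserves total relevance exactly.

lrp_rule_params <- function(rule = c("lrp0", "epsilon", "gamma"),
                            eps = 0.01, gamma = 0.25) {
  rule <- match.arg(rule)
  if (rule == "epsilon" && eps <= 0) stop_("eps must be positive")
  if (rule == "gamma" && gamma < 0) stop_("gamma must be non-negative")
  list(rule = rule, eps = eps, gamma = gamma)
}

# Stabilise a denominator: zero entries under lrp0/gamma get +/- 1e-9.
guard_denominator <- function(z, warn = TRUE) {
  zero <- z == 0
  if (any(zero)) {
    if (warn) warn_("zero denominator in LRP; stabilising with eps = 1e-9")
    z[zero] <- 1e-9
  }
  z
}

#' Propagate relevance through a fully connected layer
#'
#' Applies the LRP-0, LRP-epsilon or LRP-gamma rule to a dense layer with
#' the stored forward activations (dropout disabled). Bias contributes to
#' the denominator only.
#'
#' @param R_next relevance at the layer output, n x h matrix (or vector).
#' @param weights d x h weight matrix.
#' @param bias length-h bias vector.
#' @param activations layer input activations, n x d matrix (or vector).
#' @param rule `"lrp0"`, `"epsilon"` or `"gamma"`.
#' @param eps epsilon stabilizer (default 0.01).
#' @param gamma positive-weight amplification (default 0.25).
#' @return relevance at the layer input, n x d matrix.
#' @export
propagate_dense <- function(R_next, weights, bias, activations,
                            rule = "lrp0", eps = 0.01, gamma = 0.25) {
  prm <- lrp_rule_params(rule, eps, gamma)
  A <- if (is.matrix(activations)) activations else matrix(activations, 1)
  R <- if (is.matrix(R_next)) R_next else matrix(R_next, nrow(A))
  n <- nrow(A)
  z <- A %*% weights + rep(bias, each = n)
  if (prm$rule == "lrp0") {
    denom <- guard_denominator(z)
    s <- R / denom
    return(A * (s %*% t(weights)))
  }
  if (prm$rule == "epsilon") {
    denom <- z + prm$eps * sign1(z)
    s <- R / denom
    return(A * (s %*% t(weights)))
  }
  # gamma rule
  Ap <- pmax(A, 0); An <- pmax(-A, 0)
  Wp <- pmax(weights, 0); Wn <- pmax(-weights, 0)
  denom <- z + prm$gamma *
    (Ap %*% Wp + An %*% Wn + rep(pmax(bias, 0), each = n))
  denom <- guard_denominator(denom, warn = FALSE)
  s <- R / denom
  A * (s %*% t(weights)) +
    prm$gamma * (Ap * (s %*% t(Wp)) + An * (s %*% t(Wn)))
}

#' Propagate relevance through a convolutional layer
#'
#' Identical formulas to [propagate_dense()], with the influence terms
#' z_jk taken from the unrolled valid-padding convolution. Computed without
#' materializing the unrolled matrix, via the same im2col/scatter machinery
#' as the forward pass.
#'
#' @param R_next relevance at the conv output, n x (P*Cout) matrix.
#' @param layer a conv layer of a `cnn_model` (carries kernel, bias and
#'   geometry).
#' @param activations layer input, n x (H*W*Cin) matrix.
#' @param rule,eps,gamma as in [propagate_dense()].
#' @return relevance at the layer input, n x (H*W*Cin) matrix.
#' @export
propagate_conv <- function(R_next, layer, activations,
                           rule = "lrp0", eps = 0.01, gamma = 0.25) {
  prm <- lrp_rule_params(rule, eps, gamma)
  if (layer$type != "conv") stop_("layer is not a convolution")
  A <- if (is.matrix(activations)) activations else matrix(activations, 1)
  R <- if (is.matrix(R_next)) R_next else matrix(R_next, nrow(A))
  if (ncol(A) != prod(layer$in_shape) ||
      ncol(R) != prod(layer$out_shape)) {
    stop_("activation/relevance geometry does not match the layer")
  }
  n <- nrow(A)
  geom <- layer$geom
  z <- conv_lin_fwd(A, geom, layer$K)$out +
    rep(layer$bias, each = n * geom$P)
  if (prm$rule == "lrp0") {
    denom <- guard_denominator(z)
    s <- R / denom
    return(A * conv_lin_bwd(s, geom, layer$K))
  }
  if (prm$rule == "epsilon") {
    denom <- z + prm$eps * sign1(z)
    s <- R / denom
    return(A * conv_lin_bwd(s, geom, layer$K))
  }
  Ap <- pmax(A, 0); An <- pmax(-A, 0)
  Kp <- pmax(layer$K, 0); Kn <- pmax(-layer$K, 0)
  denom <- z + prm$gamma *
    (conv_lin_fwd(Ap, geom, Kp)$out + conv_lin_fwd(An, geom, Kn)$out +
       rep(pmax(layer$bias, 0), each = n * geom$P))
  denom <- guard_denominator(denom, warn = FALSE)
  s <- R / denom
  A * conv_lin_bwd(s, geom, layer$K) +
    prm$gamma * (Ap * conv_lin_bwd(s, geom, Kp) +
                   An * conv_lin_bwd(s, geom, Kn))
}

#' Propagate relevance through a max-pooling layer
#'
#' Winner-take-all: each pooled unit's relevance is assigned entirely to the
#' argmax input of its 2x2 window, as recorded during the forward pass
#' (ties to the first element in row-major order). Total relevance is
#' conserved exactly.
#'
#' @param R_next relevance at the pool output, n x np matrix.
#' @param layer a pool layer of a `cnn_model`.
#' @param switches argmax switches from the cached forward pass.
#' @return relevance at the pool input.
#' @export
propagate_pool <- function(R_next, layer, switches) {
  if (layer$type != "pool") stop_("layer is not a pooling layer")
  if (is.null(switches)) stop_("pooling switches missing; run a cached forward pass")
  R <- if (is.matrix(R_next)) R_next else matrix(R_next, 1)
  pool_backward(R, layer$geom, switches)
}

#' Composite rule assignment
#'
#' Which LRP rule applies to which part of the network: LRP-0 on the fully
#' connected layers, LRP-epsilon on the upper (second) convolution block and
#' LRP-gamma on the lower (first) convolution block.
#'
#' @param dense,block2,block1 rule names per group.
#' @param eps,gamma rule parameters.
#' @return list used by [lrp_explain()].
#' @export
lrp_composite <- function(dense = "lrp0", block2 = "epsilon",
                          block1 = "gamma", eps = 0.01, gamma = 0.25) {
  list(dense = dense, block2 = block2, block1 = block1,
       eps = eps, gamma = gamma)
}

#' Explain classifier decisions by composite LRP
#'
#' Runs a cached evaluation-mode forward pass for each image, initializes
#' the output relevance to the pre-sigmoid score of the predicted class
#' (+logit for predicted patient, -logit for predicted control) and
#' propagates it back to the input pixels with the composite rule
#' assignment. ReLU, dropout and flatten layers pass relevance through
#' unchanged; pooling uses winner-take-all.
#'
#' @param model a trained `cnn_model`.
#' @param images matrix n x pixels or a `trial_images` object.
#' @param composite rule assignment from [lrp_composite()].
#' @param label optional true 0/1 labels, recorded in the provenance so
#'   heatmaps can be filtered to correctly classified trials.
#' @param subject optional per-trial subject ids for the provenance.
#' @param batch_size mini-batch size for the cached forward passes.
#' @return object of class `relevance_map`: list with `pixel` (n x pixels
#'   relevance matrix), `image_dim`, `provenance` (data frame: trial,
#'   subject, prob, predicted, label, correct) and `composite`.
#' @export
lrp_explain <- function(model, images, composite = lrp_composite(),
                        label = NULL, subject = NULL, batch_size = 64L) {
  if (inherits(images, "trial_images")) {
    subject <- subject %||% images$subject
    label <- label %||% as.numeric(images$group == "patient")
    dims <- images$image_dim
    X <- images$images
  } else {
    X <- as.matrix(images)
    dims <- model$input_shape
  }
  n <- nrow(X)
  R_pix <- matrix(0, n, ncol(X))
  prob <- numeric(n)

  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    fwd <- forward_cnn(model, X[rows, , drop = FALSE], train = FALSE,
                       keep = TRUE)
    prob[rows] <- fwd$prob
    pred <- as.numeric(fwd$prob >= 0.5)
    R <- matrix(ifelse(pred == 1, fwd$logit, -fwd$logit), ncol = 1)
    for (i in rev(seq_along(model$layers))) {
      l <- model$layers[[i]]
      cc <- fwd$cache[[i]]
      R <- switch(
        l$type,
        dense = propagate_dense(R, l$W, l$b, cc$input,
                                rule = composite$dense,
                                eps = composite$eps, gamma = composite$gamma),
        conv = propagate_conv(R, l, cc$input,
                              rule = switch(l$block,
                                            block1 = composite$block1,
                                            block2 = composite$block2),
                              eps = composite$eps, gamma = composite$gamma),
        pool = propagate_pool(R, l, cc$sw),
        relu = R,
        dropout = R,
        flatten = R
      )
    }
    R_pix[rows, ] <- R
  }

  pred <- as.numeric(prob >= 0.5)
  provenance <- data.frame(
    trial = seq_len(n),
    subject = if (is.null(subject)) NA_character_ else as.character(subject),
    prob = prob, predicted = pred,
    label = if (is.null(label)) NA_real_ else label,
    correct = if (is.null(label)) NA else pred == label,
    stringsAsFactors = FALSE
  )
  structure(
    list(pixel = R_pix, image_dim = dims, provenance = provenance,
         composite = composite),
    class = "relevance_map"
  )
}

#' Aggregate relevance heatmaps over correctly classified trials
#'
#' Filters to correctly classified trials and averages pixel relevance,
#' either pooled over all trials or per subject.
#'
#' @param rmap a `relevance_map` with labels in its provenance.
#' @param scope `"pooled"` (one mean map) or `"subject"` (one mean map per
#'   subject).
#' @param correct_only keep only correctly classified trials (default TRUE).
#' @return for `"pooled"`, a `relevance_map` with a single-row `pixel`
#'   matrix; for `"subject"`, a `relevance_map` whose `pixel` rows are
#'   subject means (subjects in `provenance$subject`).
#' @export
aggregate_relevance <- function(rmap, scope = c("pooled", "subject"),
                                correct_only = TRUE) {
  scope <- match.arg(scope)
  stopifnot(inherits(rmap, "relevance_map"))
  keep <- if (correct_only) {
    if (all(is.na(rmap$provenance$correct))) {
      stop_("provenance has no labels; cannot filter to correct trials")
    }
    which(rmap$provenance$correct)
  } else {
    seq_len(nrow(rmap$pixel))
  }
  if (!length(keep)) stop_("no correctly classified trials to aggregate")
  px <- rmap$pixel[keep, , drop = FALSE]
  if (scope == "pooled") {
    out_px <- matrix(colMeans(px), 1)
    prov <- data.frame(trial = NA, subject = "pooled",
                       prob = NA, predicted = NA, label = NA, correct = TRUE)
  } else {
    subj <- rmap$provenance$subject[keep]
    out_px <- rowsum(px, subj) / as.vector(table(subj)[sort(unique(subj))])
    prov <- data.frame(trial = NA, subject = rownames(out_px),
                       prob = NA, predicted = NA, label = NA, correct = TRUE)
  }
  structure(
    list(pixel = out_px, image_dim = rmap$image_dim, provenance = prov,
         composite = rmap$composite, n_aggregated = length(keep)),
    class = "relevance_map"
  )
}

#' Back-project pixel relevance to cortical vertices
#'
#' Each vertex receives the relevance of its pixel divided by the number of
#' vertices sharing that pixel (equipartition), so summed vertex relevance
#' equals summed relevance over non-empty pixels. Empty pixels contribute to
#' no vertex.
#'
#' @param R_pixels relevance in pixel space: vector of length `prod(dim)`,
#'   a single-row matrix, or a `relevance_map` (its first row is used).
#' @param map a `projection_map` built from the same source space
#'   ([build_projection_map()]).
#' @return numeric vector of vertex relevance, indexed by vertex id.
#' @export
pixel_to_vertex <- function(R_pixels, map) {
  stopifnot(inherits(map, "projection_map"))
  if (inherits(R_pixels, "relevance_map")) {
    if (!all(R_pixels$image_dim == map$image_dim)) {
      stop_("relevance map and projection map have different image sizes")
    }
    R_pixels <- R_pixels$pixel[1, ]
  }
  R_pixels <- as.vector(R_pixels)
  if (length(R_pixels) != prod(map$image_dim %||% c(map$grid_size, map$grid_size))) {
    stop_("pixel relevance length does not match the projection map")
  }
  R_pixels[map$pixel] / map$counts[map$pixel]
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("Relevance map:", nrow(x$pixel), "map(s) of",
      x$image_dim[1], "x", x$image_dim[2], "pixels\n")
  if (!is.null(x$n_aggregated)) {
    cat("Aggregated over", x$n_aggregated, "correctly classified trials\n")
  }
  invisible(x)
}

#' @export
plot.relevance_map <- function(x, which = 1L, ...) {
  m <- matrix(x$pixel[which, ], x$image_dim[1], x$image_dim[2])
  image(t(m[rev(seq_len(nrow(m))), ]), col = hcl.colors(64, "RdBu", rev = TRUE),
        axes = FALSE, main = "LRP relevance", ...)
  invisible(x)
}

# Dense matrix of the unrolled convolution (oracle for tests):
# rows = input units, cols = output units.
unroll_conv <- function(layer) {
  geom <- layer$geom
  cout <- ncol(layer$K)
  P <- geom$P; Q <- geom$Q
  i <- rep(geom$idx, times = cout)
  j <- rep(seq_len(P), Q) + rep((seq_len(cout) - 1L) * P, each = P * Q)
  x <- as.vector(vapply(seq_len(cout),
                        function(co) rep(layer$K[, co], each = P),
                        numeric(P * Q)))
  as.matrix(Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(prod(layer$in_shape), P * cout)))
}
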