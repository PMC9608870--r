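# Shared fixtures: everything is generated in code at test time.

# A small source space with the default six region caps.
tiny_space <- function(n = 400, seed = 11) {
  generate_source_space(n, region_spec = default_region_spec(), seed = seed)
}

# A short-epoch simulation config for fast trial generation.
tiny_config <- function(..., seed = 21) {
  defaults <- list(
    n_subjects_control = 3, n_subjects_patient = 3,
    trials_per_subject = 4,
    epoch_ms = c(0, 400),
    subject_sd = 0.1, noise_sd = 0.5,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Hand-built trial set with full control over eog and data.
manual_trial_set <- function(data, eog, times, subject = NULL, group = NULL) {
  n <- dim(data)[1]
  structure(
    list(data = data,
         subject = subject %||% paste0("S", seq_len(n)),
         group = group %||% rep("control", n),
         eog = eog, times = times,
         retained = rep(TRUE, n)),
    class = "trial_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal CNN that fits the layer stack: input must be >= 16 per side.
tiny_cnn <- function(input = c(16, 18), channels = c(2, 3),
                     hidden = c(6, 4), seed = 5) {
  build_cnn(input, channels = channels, hidden = hidden, seed = seed)
}

# Zero out all biases of a model (for conservation checks).
strip_biases <- function(model) {
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "conv") model$layers[[i]]$bias[] <- 0
    if (model$layers[[i]]$type == "dense") model$layers[[i]]$b[] <- 0
  }
  model
}

# Linearly separable toy image set: class 1 carries a bright patch.
separable_images <- function(n_per_class = 50, dims = c(16, 18),
                             shift = 2, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n <- 2 * n_per_class
    x <- matrix(rnorm(n * prod(dims)), n, prod(dims))
    y <- rep(c(0, 1), each = n_per_class)
    patch <- outer(4:9, 4:9, function(r, c) r + dims[1] * (c - 1))
    x[y == 1, as.vector(patch)] <- x[y == 1, as.vector(patch)] + shift
    list(x = x, y = y)
  })
}

# Independent bisection oracle for the Mollweide auxiliary angle.
# The poles are closed-form (theta = +/- pi/2); bisection there would chase
# floating-point noise of the flat objective.
bisect_theta <- function(phi, tol = 1e-12) {
  vapply(phi, function(p) {
    if (abs(abs(p) - pi / 2) < 1e-15) return(sign(p) * pi / 2)
    f <- function(th) 2 * th + sin(2 * th) - pi * sin(p)
    lo <- -pi / 2; hi <- pi / 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Brute-force pairwise concordance AUC (Mann-Whitney with ties = 1/2).
auc_bruteforce <- function(prob, label) {
  pos <- prob[label == 1]; neg <- prob[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
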