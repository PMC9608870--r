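# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# global RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a parent seed and a stage/fold index.
# Kept well below .Machine$integer.max for parent seeds < 2^20.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 131L + as.numeric(index) * 7919) %% 2147483647)
}

# sign() with sign(0) = 1, the convention used by the epsilon stabiliser.
sign1 <- function(x) ifelse(x >= 0, 1, -1)

# Great-circle distance (radians) between (phi1, lam1) and (phi2, lam2) on the
# unit sphere; inputs in radians. Vectorised over the first pair.
great_circle <- function(phi1, lam1, phi2, lam2) {
  cosd <- sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(lam1 - lam2)
  acos(pmin(1, pmax(-1, cosd)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)
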