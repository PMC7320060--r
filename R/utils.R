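# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and a stream label,
# keeping the result a valid 32-bit R integer. Used so that each module of a
# pipeline run (walks, trial order, responses, permutations) has its own
# reproducible substream.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip_prob <- function(p, lo = 0.01, hi = 0.99) pmin(pmax(p, lo), hi)

# Wrap angles (degrees) into [0, 360).
wrap_deg <- function(a) ((a %% 360) + 360) %% 360

# Signed angular difference a - b in (-180, 180].
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Normal draws truncated to [lo, hi] by resampling (vectors are tiny here).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

assert_that <- function(ok, msg, class = "walkmem_invariant_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_scalar_prob <- function(p) is.numeric(p) && length(p) == 1 && !is.na(p) && p >= 0 && p <= 1
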