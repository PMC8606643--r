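# Internal numerical and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the user's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed; stays inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Central-difference Hessian; dimension here is at most 2 (random effects
# per study), so the O(d^2) stencil is cheap.
num_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  hh <- h * pmax(1, abs(x))
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- numeric(d); ei[i] <- hh[i]
      ej <- numeric(d); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  (H + t(H)) / 2
}

# Central-difference Jacobian of a vector-valued function (model prediction
# with respect to the study random effects).
num_jacobian <- function(f, x, h = 1e-5) {
  d <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), d)
  hh <- h * pmax(1, abs(x))
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hh[i]
    J[, i] <- (f(x + ei) - f(x - ei)) / (2 * hh[i])
  }
  J
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}
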