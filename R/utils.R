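# Internal helpers shared across modules.

# Condition-scoped error with a machine-readable class, in the style of
# rlang::abort() but without the dependency.
tg_stop <- function(code, message, call. = FALSE) {
  cond <- structure(
    class = c(code, "toogood_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Deterministic factor of a PSD covariance matrix via eigendecomposition.
# chol() rejects semidefinite matrices; eigen handles them and is
# deterministic, which the seeded sampling contract requires.
psd_factor <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Run expr with a temporarily seeded Mersenne-Twister stream, restoring the
# caller's RNG state afterwards (withr handles the save/restore).
with_seed_mt <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

# Derive per-grid-point seeds from a master seed using L'Ecuyer-CMRG
# substreams so sweep points are statistically independent yet fully
# reproducible from one integer.
substream_seeds <- function(master_seed, k) {
  withr::with_seed(master_seed, {
    s <- .Random.seed
    out <- integer(k)
    for (i in seq_len(k)) {
      s <- parallel::nextRNGStream(s)
      # fold the six stream integers into one positive 31-bit seed
      # (double arithmetic stays exact: 69069 * 2^31 < 2^53)
      acc <- Reduce(function(a, b) (a * 69069 + abs(b)) %% 2147483647,
                    as.double(s[-1L]), accumulate = FALSE)
      out[i] <- as.integer(acc)
    }
    out
  }, .rng_kind = "L'Ecuyer-CMRG")
}
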