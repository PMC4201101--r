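# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive `n` independent sub-seeds from one master seed; keeps per-modality
# draws independent while a single integer reproduces everything.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

soft_threshold <- function(x, t) {
  sign(x) * pmax(abs(x) - t, 0)
}

# Block soft-threshold: shrink the Euclidean norm of `v` by `t`.
group_shrink <- function(v, t) {
  nv <- sqrt(sum(v^2))
  if (nv <= t) v * 0 else v * (1 - t / nv)
}

# FNV-1a string hash (hex); used for config provenance stamps so result rows
# can be traced back to the exact configuration that produced them.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in doubles without precision loss
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
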