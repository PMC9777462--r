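`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## deterministic sub-seed derivation; kept inside 32-bit integer range
derive_seed <- function(base_seed, tier_index = 0L, chain_index = 0L) {
  as.integer((as.double(base_seed) + 7919 * tier_index +
                104729 * chain_index) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
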