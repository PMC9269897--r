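softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Zipf-like weights over within-component frequency ranks 1..n.
zipf_weights <- function(n, exponent = 1) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Evaluate `expr` under a fixed RNG seed when one is given, leaving the
# caller's RNG state untouched; with seed = NULL use the ambient stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= 1
}

stop_snowsem <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "snowsem_error")
}
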