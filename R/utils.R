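`%||%` <- function(a, b) if (is.null(a)) b else a

# max over rows of a numeric matrix without matrixStats
row_max <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# derive a secondary RNG seed from the user seed; stays a valid 32-bit integer
offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999983 * k) %% 2147483647)
}
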