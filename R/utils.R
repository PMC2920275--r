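# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the code runs on the ambient stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive `n` child seeds from a master seed (kept below
# 2^31 - 1 so they remain valid R integer seeds).
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(2147483646L, n))
}

# All C(K, k) locus combinations as a C x k matrix of column indices,
# rows in lexicographic order.
combo_matrix <- function(K, k) {
  if (k > K) {
    abort(sprintf("model size k = %d exceeds the number of loci K = %d", k, K))
  }
  t(combn(K, k))
}

# Lexicographic comparison of two integer/character vectors of equal length:
# negative if a < b, 0 if equal, positive if a > b.
lex_cmp <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0) return(0L)
  i <- d[[1]]
  if (a[[i]] < b[[i]]) -1L else 1L
}

# Index of the lexicographically smallest element of a list of vectors.
lex_which_min <- function(sets) {
  best <- 1L
  for (i in seq_along(sets)[-1]) {
    if (lex_cmp(sets[[i]], sets[[best]]) < 0) best <- i
  }
  best
}

# Sort rows of a combination matrix lexicographically.
lex_sort_rows <- function(m) {
  ord <- do.call(order, split(m, col(m)))
  m[ord, , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
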