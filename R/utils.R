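# Internal helpers shared across modules.

# Key for an unordered CN-genotype pair, e.g. cn_pair_key(2, 1) -> "1/2".
cn_pair_key <- function(c1, c2) {
  paste(pmin(c1, c2), pmax(c1, c2), sep = "/")
}

# Inverse of cn_pair_key(); returns a 2-column integer matrix (cn1 <= cn2).
parse_cn_pair <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("cn1", "cn2")
  m
}

# Deterministic per-classifier seed derivation: a documented LCG-style mix
# keeping everything inside 32-bit integer range. All intermediate products
# stay below 2^53 so double arithmetic is exact.
derive_seed <- function(seed, k) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + as.double(k) * 69621 + 1) %% m
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# argmax with deterministic tie-break: among maximal entries pick the one
# whose name is lexicographically smallest by parsed CN pair.
argmax_cn_pair <- function(probs, tol = 1e-12) {
  stopifnot(length(probs) > 0)
  top <- max(probs)
  cand <- names(probs)[probs >= top - tol]
  if (length(cand) == 1L) {
    return(cand)
  }
  pairs <- parse_cn_pair(cand)
  cand[order(pairs[, 1L], pairs[, 2L])][1L]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
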