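# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops over all ordered pairs / grid points) so
# they cannot share a defect with the package internals they check.

# Brute-force posterior over unordered CN pairs: loop over every ordered
# haplotype pair, test compatibility elementwise, accumulate f(h1)*f(h2).
brute_posterior <- function(H, cn, freq, g) {
  m <- nrow(H)
  scores <- list()
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      ok <- TRUE
      for (j in seq_along(g)) {
        if (!is.na(g[j]) && H[a, j] + H[b, j] != g[j]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      key <- paste(min(cn[a], cn[b]), max(cn[a], cn[b]), sep = "/")
      scores[[key]] <- (scores[[key]] %||% 0) + freq[a] * freq[b]
    }
  }
  if (length(scores) == 0) {
    return(NULL)
  }
  v <- unlist(scores)
  v / sum(v)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Observed-data log-likelihood of a frequency vector for a labeled panel,
# by direct summation over ordered compatible extended-haplotype pairs.
brute_loglik <- function(H, cn, freq, geno, labels) {
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    tot <- 0
    for (a in seq_len(nrow(H))) {
      for (b in seq_len(nrow(H))) {
        ok <- TRUE
        for (j in seq_len(ncol(geno))) {
          if (!is.na(geno[i, j]) && H[a, j] + H[b, j] != geno[i, j]) {
            ok <- FALSE
            break
          }
        }
        if (!ok) next
        if (labels$known_phase_split[i]) {
          pair_ok <- (cn[a] == labels$cn1[i] && cn[b] == labels$cn2[i]) ||
            (cn[a] == labels$cn2[i] && cn[b] == labels$cn1[i])
        } else {
          pair_ok <- cn[a] + cn[b] == labels$total_cn[i]
        }
        if (pair_ok) tot <- tot + freq[a] * freq[b]
      }
    }
    if (tot <= 0) {
      return(-Inf)
    }
    ll <- ll + log(tot)
  }
  ll
}

# All compositions of `total` into `k` parts (for simplex grids).
compositions <- function(total, k) {
  if (k == 1) {
    return(matrix(total, 1, 1))
  }
  out <- list()
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Random extended-haplotype set for property tests.
random_hapset <- function(n_snps, n_haps, cn_range = 0:3) {
  repeat {
    H <- matrix(sample(0:1, n_haps * n_snps, replace = TRUE), n_haps)
    key <- apply(cbind(H, cn <- sample(cn_range, n_haps, replace = TRUE)), 1, paste, collapse = "")
    if (!anyDuplicated(key)) break
  }
  freq <- stats::rgamma(n_haps, 1) + 1e-3
  freq <- freq / sum(freq)
  structure(
    list(
      snp_ids = paste0("s", seq_len(n_snps)), H = H, cn = cn, freq = freq,
      log_lik = NA_real_, ll_trace = numeric(0), n_iter = NA_integer_,
      converged = NA
    ),
    class = "hap_set"
  )
}

# A tiny panel where one SNP determines the CN allele exactly (r^2 = 1 tag
# at column `tag_col`) and the remaining SNPs are noise.
perfect_tag_panel <- function(n = 80, p = 6, tag_col = 3, seed = 1) {
  cnbag:::with_seed(seed, {
    cn_hap <- function() sample(c(0L, 1L), 1, prob = c(0.3, 0.7))
    h <- replicate(2 * n, {
      cn <- cn_hap()
      alleles <- sample(0:1, p, replace = TRUE)
      alleles[tag_col] <- cn # tag: allele == CN allele
      list(alleles = alleles, cn = cn)
    }, simplify = FALSE)
    codes <- t(vapply(seq_len(n), function(i) {
      h[[2 * i - 1]]$alleles + h[[2 * i]]$alleles
    }, integer(p)))
    rownames(codes) <- sprintf("P%03d", seq_len(n))
    snps <- tibble::tibble(
      snp_id = paste0("tag_panel_", seq_len(p)), chrom = "19",
      pos = 1000L * seq_len(p), allele_a = "A", allele_b = "G"
    )
    list(
      genotypes = geno_matrix(codes, snps),
      labels = cn_labels(
        rownames(codes),
        vapply(seq_len(n), function(i) h[[2 * i - 1]]$cn, integer(1)),
        vapply(seq_len(n), function(i) h[[2 * i]]$cn, integer(1)),
        cn_max = 1
      )
    )
  })
}

# Small LILRA6-like simulated panel used by several suites.
small_sim_panel <- function(seed = 1, ld = 0.95, n_samples = 120, n_snps = 12,
                            missing_rate = 0) {
  cfg <- sim_config(
    n_haplotype_pool = 400L, n_samples = n_samples, n_snps = n_snps,
    ld_strength = ld, missing_rate = missing_rate, rng_seed = seed
  )
  pool <- simulate_pool(cfg)
  c(simulate_panel(pool), list(pool = pool, cfg = cfg))
}
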