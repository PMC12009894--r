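# EM estimation of extended-haplotype frequencies from unphased genotypes.
#
# An "extended haplotype" is a phased SNP allele vector over the classifier's
# SNP subset augmented with the CN allele of the gene, treated as one extra
# multiallelic locus. Under Hardy-Weinberg equilibrium the likelihood of an
# individual's data is
#   P(g_i, cn_i) = sum over ordered compatible pairs (h1, h2) of f(h1) f(h2)
# where compatibility means the allele vectors sum to the genotype at every
# non-missing SNP and the CN alleles reproduce the label (as an unordered
# pair when the per-haplotype split is known, as a total otherwise). Missing
# genotypes are marginalized, never imputed.

# ---- compatibility machinery ------------------------------------------------

# Ordered compatible haplotype pairs among the rows of H.
# g: genotype vector (0/1/2/NA) over the columns of H.
# label: NULL (unconstrained), or a list with known (logical), cn1, cn2, total.
# Returns a 2-column integer matrix of (i1, i2) row indices.
compat_pairs <- function(H, cn, g, label = NULL, key_index = NULL) {
  m <- nrow(H)
  if (m == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  if (!anyNA(g) && length(g) > 0L) {
    # fast path: h2 is fully determined by (g, h1) at every site, so look it
    # up by allele key instead of scanning all m^2 ordered pairs
    if (is.null(key_index)) {
      key_index <- split(seq_len(m), apply(H, 1L, paste, collapse = ""))
    }
    req <- matrix(rep(as.integer(g), each = m), m) - H
    valid <- which(rowSums(req < 0L | req > 1L) == 0L)
    if (length(valid) == 0L) {
      return(matrix(integer(0), ncol = 2L))
    }
    req_keys <- apply(req[valid, , drop = FALSE], 1L, paste, collapse = "")
    partners <- key_index[req_keys]
    n_p <- lengths(partners)
    # unname(partners) may hold NULLs for absent keys; lengths() handles them
    pairs <- cbind(
      rep.int(valid, n_p),
      unlist(partners, use.names = FALSE)
    )
  } else {
    C <- matrix(TRUE, m, m)
    for (j in seq_along(g)) {
      if (!is.na(g[j])) {
        C <- C & (outer(H[, j], H[, j], "+") == g[j])
      }
    }
    pairs <- which(C, arr.ind = TRUE, useNames = FALSE)
  }
  if (!is.null(label) && nrow(pairs) > 0L) {
    cn1 <- cn[pairs[, 1L]]
    cn2 <- cn[pairs[, 2L]]
    keep <- if (isTRUE(label$known)) {
      (cn1 == label$cn1 & cn2 == label$cn2) |
        (cn1 == label$cn2 & cn2 == label$cn1)
    } else {
      cn1 + cn2 == label$total
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

# Collapse samples into unique (genotype pattern, label) patterns.
# geno: N x S integer matrix; labels: tibble as from cn_labels() aligned to
# rows of geno, or NULL. Returns list(patterns, weight, sample_of, pattern_of).
build_patterns <- function(geno, labels = NULL) {
  n <- nrow(geno)
  gkey <- apply(geno, 1L, function(r) paste(ifelse(is.na(r), "m", r), collapse = ""))
  if (ncol(geno) == 0L) gkey <- rep("", n)
  if (!is.null(labels)) {
    lkey <- ifelse(labels$known_phase_split,
      paste0("p", labels$cn1, ".", labels$cn2),
      paste0("t", labels$total_cn)
    )
    key <- paste(gkey, lkey)
  } else {
    key <- gkey
  }
  u <- !duplicated(key)
  pattern_of <- match(key, key[u])
  reps <- which(u)
  patterns <- lapply(reps, function(i) {
    lab <- NULL
    if (!is.null(labels)) {
      lab <- list(
        known = labels$known_phase_split[i],
        cn1 = labels$cn1[i], cn2 = labels$cn2[i],
        total = labels$total_cn[i]
      )
    }
    list(g = geno[i, ], label = lab, sample = rownames(geno)[i] %||% as.character(i))
  })
  list(
    patterns = patterns,
    weight = as.numeric(tabulate(pattern_of, nbins = length(reps))),
    pattern_of = pattern_of
  )
}

# ---- EM core ----------------------------------------------------------------

# Run EM given a fixed candidate haplotype universe.
# H: m x S alleles; cn: m CN alleles; freq0: initial frequencies (normalized
# internally); geno/labels as in build_patterns.
# Returns list(H, cn, freq, log_lik, ll_trace, n_iter, converged).
em_core <- function(H, cn, freq0, geno, labels, tol = 1e-6, max_iter = 200L) {
  pat <- build_patterns(geno, labels)
  np <- length(pat$patterns)
  key_index <- split(seq_len(nrow(H)), apply(H, 1L, paste, collapse = ""))
  pair_list <- vector("list", np)
  for (p in seq_len(np)) {
    pp <- compat_pairs(H, cn, pat$patterns[[p]]$g, pat$patterns[[p]]$label,
      key_index = key_index
    )
    if (nrow(pp) == 0L) {
      stop(
        "no extended-haplotype configuration is compatible with sample ",
        pat$patterns[[p]]$sample, " (inconsistent genotype/CN label)"
      )
    }
    pair_list[[p]] <- pp
  }
  pat_idx <- rep.int(seq_len(np), vapply(pair_list, nrow, integer(1)))
  pairs <- do.call(rbind, pair_list)
  i1 <- pairs[, 1L]
  i2 <- pairs[, 2L]
  w <- pat$weight
  n_total <- sum(w)
  m <- nrow(H)
  freq <- freq0 / sum(freq0)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- freq[i1] * freq[i2]
    denom <- as.vector(rowsum(p, pat_idx, reorder = TRUE))
    if (any(denom <= 0)) {
      bad <- which(denom <= 0)[1]
      stop(
        "likelihood vanished for sample ", pat$patterns[[bad]]$sample,
        " (all compatible haplotypes pruned to zero frequency)"
      )
    }
    ll <- sum(w * log(denom))
    ll_trace <- c(ll_trace, ll)
    post <- w[pat_idx] * p / denom[pat_idx]
    freq_new <- numeric(m)
    acc1 <- rowsum(post, i1, reorder = TRUE)
    freq_new[as.integer(rownames(acc1))] <- acc1
    acc2 <- rowsum(post, i2, reorder = TRUE)
    freq_new[as.integer(rownames(acc2))] <-
      freq_new[as.integer(rownames(acc2))] + acc2
    freq <- freq_new / (2 * n_total)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  list(
    H = H, cn = cn, freq = freq, log_lik = ll_trace[length(ll_trace)],
    ll_trace = ll_trace, n_iter = iter, converged = converged
  )
}

# Prune haplotypes below a frequency threshold and renormalize.
prune_hapset <- function(fit, prune_freq) {
  keep <- fit$freq >= prune_freq
  if (!any(keep)) keep <- fit$freq == max(fit$freq)
  fit$H <- fit$H[keep, , drop = FALSE]
  fit$cn <- fit$cn[keep]
  fit$freq <- fit$freq[keep] / sum(fit$freq[keep])
  fit
}

new_hap_set <- function(fit, snp_ids) {
  structure(
    list(
      snp_ids = snp_ids, H = fit$H, cn = fit$cn, freq = fit$freq,
      log_lik = fit$log_lik, ll_trace = fit$ll_trace, n_iter = fit$n_iter,
      converged = fit$converged
    ),
    class = "hap_set"
  )
}

#' @export
print.hap_set <- function(x, ...) {
  cat(
    "<hap_set> ", length(x$freq), " extended haplotypes over ",
    length(x$snp_ids), " SNPs; log-lik ", signif(x$log_lik, 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy hap_set
#' @export
tidy.hap_set <- function(x, ...) {
  tibble::tibble(
    alleles = apply(x$H, 1L, paste, collapse = ""),
    cn_allele = x$cn,
    freq = x$freq
  )
}

# ---- user-facing operations -------------------------------------------------

#' Enumerate haplotype configurations compatible with one genotype
#'
#' Lists every ordered pair of extended haplotypes (SNP allele vector plus CN
#' allele) over the universe `{0,1}^S x cn_range` whose allele vectors sum to
#' the genotype at each non-missing SNP and whose CN alleles reproduce the
#' label: as an unordered pair when the per-haplotype split is known, as a
#' diploid total otherwise, or unconstrained when `cn` is `NULL`. Missing
#' genotypes leave the corresponding site free. Mainly a diagnostic /
#' testing aid; the fitting internals use an equivalent vectorized routine.
#'
#' @param snp_genotype genotype vector (0/1/2/`NA`).
#' @param cn `NULL`, or a list with `cn1`/`cn2` (known split) or `total`.
#' @param cn_range integer vector of allowed CN alleles.
#' @return tibble with columns `hap1`, `cn1`, `hap2`, `cn2`; `hap*` are
#'   allele strings such as `"010"`. Zero rows when nothing is compatible.
#' @export
enumerate_configurations <- function(snp_genotype, cn = NULL, cn_range = 0:4) {
  s <- length(snp_genotype)
  if (s > 16) stop("configuration enumeration limited to <= 16 SNPs")
  site_opts <- lapply(snp_genotype, function(gj) {
    if (is.na(gj)) {
      cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
    } else if (gj == 0L) {
      cbind(0L, 0L)
    } else if (gj == 1L) {
      cbind(c(0L, 1L), c(1L, 0L))
    } else {
      cbind(1L, 1L)
    }
  })
  allele_pairs <- Reduce(function(acc, opt) {
    na <- nrow(acc)
    no <- nrow(opt)
    cbind(
      acc[rep(seq_len(na), times = no), 1:(ncol(acc) / 2), drop = FALSE],
      opt[rep(seq_len(no), each = na), 1L],
      acc[rep(seq_len(na), times = no), -(1:(ncol(acc) / 2)), drop = FALSE],
      opt[rep(seq_len(no), each = na), 2L]
    )
  }, site_opts[-1], init = site_opts[[1]])
  k <- ncol(allele_pairs) / 2L
  h1 <- allele_pairs[, seq_len(k), drop = FALSE]
  h2 <- allele_pairs[, k + seq_len(k), drop = FALSE]
  if (is.null(cn)) {
    cn_opts <- expand.grid(cn1 = cn_range, cn2 = cn_range)
  } else if (!is.null(cn$cn1) && !is.na(cn$cn1 %||% NA) && !is.null(cn$cn2) && !is.na(cn$cn2 %||% NA)) {
    cn_opts <- unique(data.frame(cn1 = c(cn$cn1, cn$cn2), cn2 = c(cn$cn2, cn$cn1)))
  } else {
    t <- cn$total
    c1 <- cn_range[t - cn_range >= min(cn_range) & t - cn_range <= max(cn_range) &
      (t - cn_range) %in% cn_range]
    cn_opts <- data.frame(cn1 = c1, cn2 = t - c1)
  }
  na <- nrow(h1)
  nc <- nrow(cn_opts)
  if (na == 0L || nc == 0L) {
    return(tibble::tibble(
      hap1 = character(0), cn1 = integer(0),
      hap2 = character(0), cn2 = integer(0)
    ))
  }
  tibble::tibble(
    hap1 = rep(apply(h1, 1L, paste, collapse = ""), times = nc),
    cn1 = rep(as.integer(cn_opts$cn1), each = na),
    hap2 = rep(apply(h2, 1L, paste, collapse = ""), times = nc),
    cn2 = rep(as.integer(cn_opts$cn2), each = na)
  )
}

#' Fit extended-haplotype frequencies by EM
#'
#' Maximizes the observed-data likelihood of unphased SNP genotypes and CN
#' labels over extended-haplotype frequencies. Initialization is uniform over
#' the union of haplotypes appearing in at least one compatible configuration
#' of at least one individual (the likelihood puts no mass outside that
#' union, so nothing is lost). The log-likelihood is non-decreasing across
#' iterations (`$ll_trace`); convergence when the increase falls below `tol`.
#' At convergence, haplotypes with frequency below `prune_freq` are removed
#' and the remainder renormalized.
#'
#' @param genotypes a [geno_matrix()] or plain 0/1/2/`NA` matrix restricted
#'   to the SNP subset being modeled.
#' @param labels label tibble from [cn_labels()] / [read_cn_labels()], one
#'   row per sample, in sample order of `genotypes`.
#' @param cn_range integer vector of allowed per-haplotype CN alleles.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap.
#' @param prune_freq post-convergence pruning threshold; default
#'   `1 / (4 * N)`.
#' @return a `hap_set` object (`tidy()` gives the haplotype table).
#' @export
em_fit <- function(genotypes, labels, cn_range = 0:4, tol = 1e-6,
                   max_iter = 200L, prune_freq = NULL) {
  geno <- if (inherits(genotypes, "geno_matrix")) geno_codes(genotypes) else as.matrix(genotypes)
  n <- nrow(geno)
  stopifnot(n >= 1, ncol(geno) >= 1)
  if (nrow(labels) != n) stop("labels must have one row per sample")
  prune_freq <- prune_freq %||% (1 / (4 * n))
  universe <- hap_universe(geno, labels, cn_range)
  fit <- em_core(universe$H, universe$cn, rep(1, nrow(universe$H)),
    geno, labels,
    tol = tol, max_iter = max_iter
  )
  fit <- prune_hapset(fit, prune_freq)
  snp_ids <- colnames(geno) %||% paste0("snp", seq_len(ncol(geno)))
  new_hap_set(fit, snp_ids)
}

# Union of extended haplotypes compatible with >= 1 individual.
hap_universe <- function(geno, labels, cn_range) {
  pat <- build_patterns(geno, labels)
  seen <- new.env(parent = emptyenv())
  Hs <- list()
  cns <- list()
  for (p in pat$patterns) {
    g <- p$g
    n_free <- sum(is.na(g) | g == 1L)
    cn_opts <- if (is.null(p$label)) {
      cn_range
    } else if (p$label$known) {
      intersect(unique(c(p$label$cn1, p$label$cn2)), cn_range)
    } else {
      cn_range[(p$label$total - cn_range) %in% cn_range]
    }
    if (length(cn_opts) == 0L) {
      stop(
        "no extended-haplotype configuration is compatible with sample ",
        p$sample, " (CN label outside the configured CN-allele range)"
      )
    }
    if (2^n_free * length(cn_opts) > 65536) {
      stop(
        "compatible-haplotype universe too large for sample ", p$sample,
        " (", n_free, " free sites); restrict the SNP subset"
      )
    }
    site_opts <- lapply(g, function(gj) {
      if (is.na(gj) || gj == 1L) c(0L, 1L) else if (gj == 0L) 0L else 1L
    })
    hmat <- as.matrix(expand.grid(site_opts, KEEP.OUT.ATTRS = FALSE))
    for (c_allele in cn_opts) {
      keys <- paste0(apply(hmat, 1L, paste, collapse = ""), ":", c_allele)
      new <- !vapply(keys, exists, logical(1), envir = seen)
      for (k in keys[new]) assign(k, TRUE, envir = seen)
      if (any(new)) {
        Hs[[length(Hs) + 1L]] <- hmat[new, , drop = FALSE]
        cns[[length(cns) + 1L]] <- rep(c_allele, sum(new))
      }
    }
  }
  H <- do.call(rbind, Hs)
  dimnames(H) <- NULL
  list(H = H, cn = as.integer(unlist(cns)))
}

#' Posterior distribution over CN genotypes for one SNP genotype
#'
#' Computes `P(cn pair | genotype)` under the fitted extended-haplotype
#' frequencies and Hardy-Weinberg pairing: the score of an unordered CN pair
#' is the sum of `f(h1) f(h2)` over ordered compatible haplotype pairs
#' carrying those CN alleles, normalized over all pairs. Missing genotypes
#' are marginalized; an all-missing genotype yields the frequency-implied
#' prior over CN pairs. When no compatible haplotype pair exists the
#' distribution is undefined (classifier abstention): a zero-length vector
#' with attribute `undefined = TRUE`.
#'
#' @param hs a `hap_set` from [em_fit()].
#' @param snp_genotype genotype vector (0/1/2/`NA`) over `hs$snp_ids`.
#' @return named numeric vector of probabilities; names are unordered CN
#'   pairs such as `"1/2"`.
#' @export
posterior_cn <- function(hs, snp_genotype) {
  stopifnot(length(snp_genotype) == ncol(hs$H))
  pairs <- compat_pairs(hs$H, hs$cn, snp_genotype)
  if (nrow(pairs) == 0L) {
    return(structure(numeric(0), undefined = TRUE))
  }
  score <- hs$freq[pairs[, 1L]] * hs$freq[pairs[, 2L]]
  key <- cn_pair_key(hs$cn[pairs[, 1L]], hs$cn[pairs[, 2L]])
  agg <- rowsum(score, key, reorder = TRUE)
  probs <- as.vector(agg)
  names(probs) <- rownames(agg)
  tot <- sum(probs)
  if (tot <= 0) {
    return(structure(numeric(0), undefined = TRUE))
  }
  probs <- probs / tot
  # order by parsed CN pair for stable output
  pp <- parse_cn_pair(names(probs))
  probs[order(pp[, 1L], pp[, 2L])]
}

# Posterior for every row of a genotype matrix, deduplicating patterns.
# Returns a list of named numeric vectors (or undefined markers).
posterior_cn_matrix <- function(hs, geno) {
  pat <- build_patterns(geno, NULL)
  per_pattern <- lapply(pat$patterns, function(p) posterior_cn(hs, p$g))
  per_pattern[pat$pattern_of]
}
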