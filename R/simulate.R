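# Synthetic reference panels with a latent CN locus embedded in a SNP
# haplotype background with controllable linkage disequilibrium, so the whole
# pipeline is testable without external data.

#' Simulation configuration
#'
#' Defines a founder haplotype pool: each CN allele gets a "core" SNP
#' haplotype, and each founder copies its core allele at every SNP with
#' probability `ld_strength`, otherwise draws from the SNP's background
#' allele frequency. `ld_strength = 1` makes every SNP a deterministic
#' function of the CN allele; `ld_strength = 0` makes SNPs independent of
#' the CN locus. Positions listed in `tag_snp_positions` are perfect tags:
#' their allele is the indicator of one designated CN allele (assigned
#' round-robin over the CN alleles present), so r-squared with that CN
#' allele is 1 in the founder pool.
#'
#' Defaults describe a panel of the kind used throughout the package's own
#' validation: 400 diploid samples, 30 SNPs in a +/-100 kb region around a
#' chr19-like gene center, and a CN-allele frequency shape typical of a
#' strongly skewed CN-variable gene (one common allele plus rare deletion /
#' duplication alleles).
#'
#' @param n_haplotype_pool founder haplotypes in the pool.
#' @param n_samples diploid samples per simulated panel.
#' @param n_snps SNPs placed uniformly across the region.
#' @param region_span_bp total span of the SNP region (centered on
#'   `gene_center_bp`).
#' @param chrom chromosome label.
#' @param gene_center_bp 1-based center coordinate of the gene.
#' @param cn_allele_freqs named numeric vector, CN allele -> frequency
#'   (must sum to 1).
#' @param ld_strength core-copy probability in `[0, 1]`.
#' @param tag_snp_positions optional bp positions of perfect tag SNPs.
#' @param missing_rate i.i.d. genotype missingness in `[0, 1)`.
#' @param rng_seed integer seed; every simulation output is deterministic
#'   given this seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_haplotype_pool = 2000L, n_samples = 400L, n_snps = 30L,
                       region_span_bp = 200000L, chrom = "19",
                       gene_center_bp = 19800000L,
                       cn_allele_freqs = c("0" = 0.019, "1" = 0.926, "2" = 0.051, "3" = 0.004),
                       ld_strength = 0.9, tag_snp_positions = NULL,
                       missing_rate = 0, rng_seed = 1L) {
  stopifnot(
    n_haplotype_pool >= 2, n_samples >= 1, n_snps >= 1,
    ld_strength >= 0, ld_strength <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  if (abs(sum(cn_allele_freqs) - 1) > 1e-8) stop("cn_allele_freqs must sum to 1")
  if (is.null(names(cn_allele_freqs))) stop("cn_allele_freqs must be named by CN allele")
  structure(
    list(
      n_haplotype_pool = as.integer(n_haplotype_pool),
      n_samples = as.integer(n_samples),
      n_snps = as.integer(n_snps),
      region_span_bp = as.integer(region_span_bp),
      chrom = as.character(chrom),
      gene_center_bp = as.integer(gene_center_bp),
      cn_allele_freqs = cn_allele_freqs,
      ld_strength = ld_strength,
      tag_snp_positions = tag_snp_positions,
      missing_rate = missing_rate,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a founder haplotype pool
#'
#' @param cfg a [sim_config()].
#' @return an object of class `cn_pool`: list with `haplotypes` (pool x SNPs
#'   allele matrix), `cn_allele`, `freq` (uniform founder frequencies),
#'   `snps` (metadata tibble), `cores`, `tag_targets` (CN allele tagged by
#'   each tag SNP, named by snp_id) and `config`.
#' @export
simulate_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$rng_seed, 101L), {
    half <- cfg$region_span_bp %/% 2L
    lo <- cfg$gene_center_bp - half
    hi <- cfg$gene_center_bp + half
    n_tag <- length(cfg$tag_snp_positions)
    n_bg <- cfg$n_snps - n_tag
    if (n_bg < 0) stop("more tag positions than n_snps")
    pos <- sort(c(
      as.integer(cfg$tag_snp_positions),
      sample(setdiff(seq.int(lo, hi), cfg$tag_snp_positions), n_bg)
    ))
    is_tag <- pos %in% cfg$tag_snp_positions
    # non-palindromic pairs only, so simulated panels survive strand-aware
    # model/target matching unscathed
    pair_choices <- list(
      c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
    )
    allele_pairs <- do.call(rbind, sample(pair_choices, length(pos), replace = TRUE))
    snps <- tibble::tibble(
      snp_id = sprintf("rs%06d", seq_along(pos)),
      chrom = cfg$chrom, pos = pos,
      allele_a = allele_pairs[, 1L], allele_b = allele_pairs[, 2L]
    )
    cn_alleles <- as.integer(names(cfg$cn_allele_freqs))
    bg_freq <- stats::runif(cfg$n_snps, 0.1, 0.9)
    # one core SNP haplotype per CN allele; resample until pairwise distinct
    repeat {
      cores <- matrix(
        stats::rbinom(length(cn_alleles) * cfg$n_snps, 1L, rep(bg_freq, each = length(cn_alleles))),
        nrow = length(cn_alleles)
      )
      if (nrow(unique(cores)) == nrow(cores)) break
    }
    rownames(cores) <- names(cfg$cn_allele_freqs)
    # perfect tags: allele = indicator of a designated CN allele, round-robin
    tag_targets <- integer(0)
    if (any(is_tag)) {
      targets <- rep_len(cn_alleles, sum(is_tag))
      cores[, is_tag] <- 0L
      for (t in seq_along(targets)) {
        jj <- which(is_tag)[t]
        cores[match(targets[t], cn_alleles), jj] <- 1L
      }
      tag_targets <- stats::setNames(targets, snps$snp_id[is_tag])
    }
    founder_cn <- sample(cn_alleles, cfg$n_haplotype_pool,
      replace = TRUE, prob = cfg$cn_allele_freqs
    )
    core_rows <- cores[match(founder_cn, cn_alleles), , drop = FALSE]
    copy_core <- matrix(
      stats::runif(cfg$n_haplotype_pool * cfg$n_snps) < cfg$ld_strength,
      nrow = cfg$n_haplotype_pool
    )
    copy_core[, is_tag] <- TRUE
    background <- matrix(
      stats::rbinom(cfg$n_haplotype_pool * cfg$n_snps, 1L, rep(bg_freq, each = cfg$n_haplotype_pool)),
      nrow = cfg$n_haplotype_pool
    )
    haplotypes <- ifelse(copy_core, core_rows, background)
    storage.mode(haplotypes) <- "integer"
    structure(
      list(
        haplotypes = haplotypes,
        cn_allele = founder_cn,
        freq = rep(1 / cfg$n_haplotype_pool, cfg$n_haplotype_pool),
        snps = snps,
        cores = cores,
        tag_targets = tag_targets,
        config = cfg
      ),
      class = "cn_pool"
    )
  })
}

#' @export
print.cn_pool <- function(x, ...) {
  cat(
    "<cn_pool> ", nrow(x$haplotypes), " founder haplotypes x ",
    ncol(x$haplotypes), " SNPs; CN alleles {",
    paste(sort(unique(x$cn_allele)), collapse = ","), "}\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a diploid panel from a founder pool
#'
#' Each sample is two independent founder draws (Hardy-Weinberg pairing);
#' genotypes are allele sums and the CN label is the unordered pair of the
#' two founders' CN alleles (`known_phase_split = TRUE`). Genotype calls are
#' then masked i.i.d. at `missing_rate`.
#'
#' @param pool a `cn_pool` from [simulate_pool()].
#' @param n_samples,missing_rate,seed overrides of the pool's configuration.
#' @return list with `genotypes` (a [geno_matrix()]) and `labels`
#'   (a [cn_labels()] tibble).
#' @export
simulate_panel <- function(pool, n_samples = NULL, missing_rate = NULL, seed = NULL) {
  stopifnot(inherits(pool, "cn_pool"))
  cfg <- pool$config
  n_samples <- n_samples %||% cfg$n_samples
  missing_rate <- missing_rate %||% cfg$missing_rate
  seed <- seed %||% cfg$rng_seed
  with_seed(derive_seed(seed, 202L), {
    m <- nrow(pool$haplotypes)
    h1 <- sample.int(m, n_samples, replace = TRUE, prob = pool$freq)
    h2 <- sample.int(m, n_samples, replace = TRUE, prob = pool$freq)
    codes <- pool$haplotypes[h1, , drop = FALSE] + pool$haplotypes[h2, , drop = FALSE]
    if (missing_rate > 0) {
      mask <- matrix(
        stats::runif(length(codes)) < missing_rate,
        nrow = nrow(codes)
      )
      codes[mask] <- NA_integer_
    }
    samples <- sprintf("sim%04d", seq_len(n_samples))
    rownames(codes) <- samples
    list(
      genotypes = geno_matrix(codes, pool$snps, samples = samples),
      labels = cn_labels(samples, pool$cn_allele[h1], pool$cn_allele[h2])
    )
  })
}

#' SNP-to-CN-locus linkage disequilibrium in the founder pool
#'
#' Squared Pearson correlation between the SNP allele indicator and the
#' indicator of a CN allele, maximized over CN alleles, computed over the
#' frequency-weighted founder pool. 1 for a perfect tag, ~0 for a SNP
#' independent of the CN locus.
#'
#' @param pool a `cn_pool`.
#' @param snp_index SNP column index.
#' @return r-squared in `[0, 1]`.
#' @export
snp_cn_r2 <- function(pool, snp_index) {
  x <- pool$haplotypes[, snp_index]
  w <- pool$freq / sum(pool$freq)
  mx <- sum(w * x)
  vx <- sum(w * (x - mx)^2)
  if (vx <= 0) {
    return(0)
  }
  r2 <- vapply(sort(unique(pool$cn_allele)), function(c_allele) {
    y <- as.numeric(pool$cn_allele == c_allele)
    my <- sum(w * y)
    vy <- sum(w * (y - my)^2)
    if (vy <= 0) {
      return(0)
    }
    cxy <- sum(w * (x - mx) * (y - my))
    cxy^2 / (vx * vy)
  }, numeric(1))
  max(r2)
}
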