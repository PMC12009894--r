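#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the p-value
#' is the sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration. Full
#' enumeration, no mid-p adjustment and no asymptotic approximation — the
#' behavior at extreme significance cutoffs (the QC default removes SNPs at
#' p < 1e-5) is exact even for small panels.
#'
#' @param n_aa,n_ab,n_bb genotype counts (allele_a homozygote, heterozygote,
#'   allele_b homozygote).
#' @return p-value in `[0, 1]`; monomorphic input returns 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotyped individual required")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) {
    return(1.0)
  }
  rare <- min(n_a, n_b)
  # heterozygote count shares the parity of the rare allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_ab = h | n_a, n_b) up to a constant:
  #   n! / (n_aa! n_ab! n_bb!) * 2^n_ab  with n_aa = (n_a - h)/2 etc.
  hom_rare <- (rare - het) / 2
  hom_common <- (max(n_a, n_b) - het) / 2
  logp <- het * log(2) - lfactorial(hom_rare) - lfactorial(het) - lfactorial(hom_common)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- n_ab
  p_obs <- prob[match(obs, het)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  min(1.0, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP quality control
#'
#' Applies the standard array-QC filters: a SNP is removed when its minor
#' allele frequency is <= `maf_min`, its call rate is <= `cr_min`, or its
#' exact Hardy-Weinberg p-value is < `hwe_min`. Thresholds are applied with
#' these exact inequalities (retention requires MAF > `maf_min`, call rate >
#' `cr_min`, HWE p >= `hwe_min`). MAF and HWE are computed on non-missing
#' calls only; a SNP with zero calls fails on call rate.
#'
#' @param g a [geno_matrix()].
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param cr_min call-rate threshold (default 0.95).
#' @param hwe_min Hardy-Weinberg p-value threshold (default 1e-5).
#' @return a list with `genotypes` (the filtered [geno_matrix()]) and
#'   `report`, a tibble with one row per input SNP: `snp_id`, `maf`,
#'   `call_rate`, `hwe_p`, `pass`, `reasons` (comma-separated failure
#'   reasons, `""` when passing).
#' @export
snp_qc <- function(g, maf_min = 0.05, cr_min = 0.95, hwe_min = 1e-5) {
  codes <- geno_codes(g)
  if (ncol(codes) == 0) stop("empty genotype matrix")
  n <- nrow(codes)
  n_called <- colSums(!is.na(codes))
  call_rate <- n_called / n
  n_bb <- colSums(codes == 2L, na.rm = TRUE)
  n_ab <- colSums(codes == 1L, na.rm = TRUE)
  n_aa <- n_called - n_bb - n_ab
  p_b <- ifelse(n_called > 0, (2 * n_bb + n_ab) / (2 * n_called), NA_real_)
  maf <- pmin(p_b, 1 - p_b)
  hwe_p <- vapply(seq_len(ncol(codes)), function(j) {
    if (n_called[j] == 0) {
      return(NA_real_)
    }
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j])
  }, numeric(1))
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_cr <- call_rate <= cr_min
  fail_hwe <- is.na(hwe_p) | hwe_p < hwe_min
  pass <- !(fail_maf | fail_cr | fail_hwe)
  reasons <- purrr::pmap_chr(
    list(fail_maf, fail_cr, fail_hwe),
    function(m, c, h) paste(c("maf", "call_rate", "hwe")[c(m, c, h)], collapse = ",")
  )
  report <- tibble::tibble(
    snp_id = snp_meta(g)$snp_id,
    maf = unname(maf), call_rate = unname(call_rate), hwe_p = unname(hwe_p),
    pass = unname(pass), reasons = unname(reasons)
  )
  if (!any(pass)) warning("all SNPs removed by QC")
  list(genotypes = g[, which(pass)], report = report)
}

#' Select SNPs in a flanking window around a gene center
#'
#' Retains SNPs on `chrom` whose 1-based position lies in the closed interval
#' `[center - 1000 * window_kb, center + 1000 * window_kb]`; input order is
#' preserved. Optionally excludes a gene-body interval (closed, same
#' chromosome) for workflows that only trust markers outside the
#' copy-variable segment itself.
#'
#' @param g a [geno_matrix()].
#' @param chrom chromosome of the gene.
#' @param center 1-based bp coordinate of the gene center.
#' @param window_kb half-width of the window in kb (> 0).
#' @param gene_body optional `c(start, end)` interval to exclude.
#' @return a [geno_matrix()] restricted to the selected SNPs (possibly with
#'   zero columns, with a warning).
#' @export
select_flanking <- function(g, chrom, center, window_kb, gene_body = NULL) {
  stopifnot(window_kb > 0)
  meta <- snp_meta(g)
  lo <- center - 1000 * window_kb
  hi <- center + 1000 * window_kb
  keep <- meta$chrom == as.character(chrom) & meta$pos >= lo & meta$pos <= hi
  if (!is.null(gene_body)) {
    stopifnot(length(gene_body) == 2)
    keep <- keep & !(meta$pos >= gene_body[1] & meta$pos <= gene_body[2])
  }
  if (!any(keep)) warning("no SNPs in the ", window_kb, " kb flanking window")
  g[, which(keep)]
}
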