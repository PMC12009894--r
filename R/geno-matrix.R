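#' Genotype matrix container
#'
#' An individuals-by-SNPs matrix of unphased biallelic genotype codes together
#' with SNP metadata. Codes count copies of `allele_b` (0, 1 or 2); missing
#' genotypes are `NA`. This convention is applied consistently everywhere,
#' including when reading PLINK files (`allele_a` = bim column 5, `allele_b` =
#' bim column 6), so model/target allele reconciliation is unambiguous.
#'
#' @param codes integer matrix, one row per sample, one column per SNP, values
#'   in `c(0L, 1L, 2L, NA)`.
#' @param snps a data frame of SNP metadata with columns `snp_id`, `chrom`,
#'   `pos` (1-based bp), `allele_a`, `allele_b`.
#' @param samples character vector of sample ids (defaults to rownames).
#'
#' @return An object of class `geno_matrix`: the code matrix with the SNP
#'   metadata tibble attached (`snp_meta()`) and sample ids as rownames.
#' @export
geno_matrix <- function(codes, snps, samples = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  snps <- tibble::as_tibble(snps)
  required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  samples <- as.character(samples)
  if (nrow(codes) != length(samples)) {
    stop("codes has ", nrow(codes), " rows but ", length(samples), " sample ids")
  }
  if (ncol(codes) != nrow(snps)) {
    stop("codes has ", ncol(codes), " columns but ", nrow(snps), " SNP records")
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicated snp_id: ", paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(snps$pos < 1L, na.rm = TRUE)) stop("SNP positions must be >= 1")
  if (any(snps$allele_a == snps$allele_b)) stop("allele_a must differ from allele_b")
  ok_allele <- c("A", "C", "G", "T")
  if (!all(snps$allele_a %in% ok_allele) || !all(snps$allele_b %in% ok_allele)) {
    stop("alleles must be one of A, C, G, T")
  }
  dimnames(codes) <- list(samples, snps$snp_id)
  structure(codes, snps = snps, class = c("geno_matrix", "matrix", "array"))
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
snp_meta <- function(g) {
  attr(g, "snps")
}

#' @rdname geno_matrix
#' @export
sample_ids <- function(g) {
  rownames(g)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "<geno_matrix> ", nrow(x), " samples x ", ncol(x), " SNPs; ",
    "missing rate ", signif(mean(is.na(x)), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Subset a genotype matrix
#'
#' Keeps SNP metadata in sync with the retained columns. Always returns a
#' `geno_matrix` (drop is ignored).
#'
#' @param x a `geno_matrix`.
#' @param i,j row (sample) and column (SNP) indices.
#' @param ... ignored.
#' @param drop ignored; kept for signature compatibility.
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  codes <- unclass(x)
  attr(codes, "snps") <- NULL
  if (missing(i)) i <- seq_len(nrow(codes))
  if (missing(j)) j <- seq_len(ncol(codes))
  sub <- codes[i, j, drop = FALSE]
  geno_matrix(sub, attr(x, "snps")[j, , drop = FALSE], samples = rownames(sub))
}

# Plain integer matrix view (no metadata), used by numeric internals.
geno_codes <- function(g) {
  codes <- unclass(g)
  attr(codes, "snps") <- NULL
  class(codes) <- NULL
  dim(codes) <- dim(g)
  dimnames(codes) <- dimnames(g)
  codes
}
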