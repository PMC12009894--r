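#' Read genotypes from TSV or PLINK bed/bim/fam
#'
#' Two on-disk dialects are supported.
#'
#' **TSV dialect**: a tab-separated file with a header row; first column
#' `sample`, remaining columns one per SNP (named by `snp_id`), values 0/1/2
#' counting copies of `allele_b`, with the literal token `NA` for missing.
#' SNP metadata comes from a companion TSV (`snp_info`) with columns
#' `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`. Without `snp_info`,
#' placeholder metadata is synthesized (chrom `"0"`, positions 1..P, alleles
#' A/C) — sufficient for fitting, not for window selection or model/target
#' allele matching.
#'
#' **PLINK**: `path` is the file prefix of a variant-major `.bed` with its
#' `.bim`/`.fam`. The 2-bit codes are decoded as 00 = `allele_a` homozygote
#' (code 0), 10 = heterozygote (1), 11 = `allele_b` homozygote (2),
#' 01 = missing, where `allele_a`/`allele_b` are bim columns 5 and 6.
#'
#' @param path file path (TSV) or PLINK prefix.
#' @param format `"tsv"` or `"plink-bed"`.
#' @param snp_info optional path to the SNP metadata TSV (TSV format only).
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-bed"), snp_info = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    read_genotypes_tsv(path, snp_info)
  } else {
    read_plink(path)
  }
}

read_genotypes_tsv <- function(path, snp_info = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr)) {
    stop("duplicated snp_id in ", path, ": ", paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  if (!identical(names(tab)[1], "sample")) {
    stop("malformed genotype TSV ", path, ": first header column must be 'sample' (line 1)")
  }
  snp_ids <- names(tab)[-1]
  if (length(snp_ids) == 0) stop("malformed genotype TSV ", path, ": no SNP columns (line 1)")
  if (anyDuplicated(snp_ids)) {
    stop("duplicated snp_id in ", path, ": ", paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  codes <- as.matrix(tab[, -1, drop = FALSE])
  bad <- matrix(!(codes %in% c("0", "1", "2", "NA", NA)), nrow = nrow(codes))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(
      "malformed genotype TSV ", path, ": invalid token '", codes[bad][1],
      "' at line ", idx[1] + 1L, " (sample ", tab$sample[idx[1]], ")"
    )
  }
  codes[codes == "NA"] <- NA
  storage.mode(codes) <- "integer"
  if (!is.null(snp_info)) {
    meta <- readr::read_tsv(snp_info, col_types = readr::cols(
      snp_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), allele_a = readr::col_character(),
      allele_b = readr::col_character()
    ), progress = FALSE)
    meta <- meta[match(snp_ids, meta$snp_id), , drop = FALSE]
    if (anyNA(meta$snp_id)) {
      stop("snp_info ", snp_info, " lacks metadata for: ", paste(snp_ids[is.na(meta$snp_id)], collapse = ", "))
    }
  } else {
    meta <- tibble::tibble(
      snp_id = snp_ids, chrom = "0", pos = seq_along(snp_ids),
      allele_a = "A", allele_b = "C"
    )
  }
  geno_matrix(codes, meta, samples = tab$sample)
}

#' Write genotypes as TSV
#'
#' Writes the genotype TSV dialect of [read_genotypes()] plus, optionally,
#' the companion SNP metadata TSV.
#'
#' @param g a [geno_matrix()].
#' @param path output genotype TSV path.
#' @param snp_info optional path for the SNP metadata TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, snp_info = NULL) {
  codes <- geno_codes(g)
  tab <- tibble::as_tibble(as.data.frame(codes))
  tab <- dplyr::bind_cols(tibble::tibble(sample = sample_ids(g)), tab)
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  if (!is.null(snp_info)) readr::write_tsv(snp_meta(g), snp_info, progress = FALSE)
  invisible(path)
}

# ---- PLINK variant-major bed codec -----------------------------------------

plink_byte_table <- function() {
  # 256 x 4 matrix: genotype codes of the 4 samples packed in one byte.
  # 2-bit fields, least significant pair first: 00 -> 0, 10 -> 1, 11 -> 2,
  # 01 -> NA.
  decode2 <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  bytes <- 0:255
  t(vapply(bytes, function(b) {
    shifts <- c(0L, 2L, 4L, 6L)
    decode2[as.character(bitwAnd(bitwShiftR(b, shifts), 3L))]
  }, integer(4)))
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("PLINK file not found: ", f)
  bim_tab <- utils::read.table(bim,
    col.names = c("chrom", "snp_id", "cm", "pos", "allele_a", "allele_b"),
    colClasses = c("character", "character", "numeric", "integer", "character", "character")
  )
  fam_tab <- utils::read.table(fam, colClasses = "character")
  n <- nrow(fam_tab)
  p <- nrow(bim_tab)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed PLINK bed ", bed, ": bad magic number (byte 1)")
  }
  if (raw[3] != as.raw(0x01)) stop("PLINK bed ", bed, " is not variant-major (byte 3)")
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_snp * p) {
    stop(
      "malformed PLINK bed ", bed, ": expected ", bytes_per_snp * p,
      " data bytes for ", n, " samples x ", p, " SNPs, found ", length(raw) - 3L
    )
  }
  tab <- plink_byte_table()
  body <- as.integer(raw[-(1:3)]) + 1L
  # bytes_per_snp*4 slots per SNP; take the first n.
  codes <- matrix(t(tab[body, , drop = FALSE]), nrow = bytes_per_snp * 4L, ncol = p)
  codes <- codes[seq_len(n), , drop = FALSE]
  geno_matrix(codes, bim_tab[, c("snp_id", "chrom", "pos", "allele_a", "allele_b")],
    samples = fam_tab[[2]]
  )
}

#' Write genotypes as a PLINK bed/bim/fam triple
#'
#' Variant-major encoding, inverse of the PLINK reader. Centimorgan column is
#' written as 0; family/paternal/maternal/sex/phenotype fam columns are
#' filled with placeholder values.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  codes <- geno_codes(g)
  n <- nrow(codes)
  p <- ncol(codes)
  meta <- snp_meta(g)
  encode2 <- function(code) {
    # inverse of the 2-bit decode map
    out <- integer(length(code))
    out[is.na(code)] <- 1L
    out[!is.na(code) & code == 1L] <- 2L
    out[!is.na(code) & code == 2L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(p)) {
    slots <- integer(bytes_per_snp * 4L) # padding slots encode as 00
    slots[seq_len(n)] <- encode2(codes[, j])
    quads <- matrix(slots, nrow = 4L)
    byte_vals <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte_vals), con)
  }
  utils::write.table(
    data.frame(meta$chrom, meta$snp_id, 0, meta$pos, meta$allele_a, meta$allele_b),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  ids <- sample_ids(g)
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read copy-number genotype labels
#'
#' Expects a TSV with header columns `sample`, `cn1` and optionally `cn2`.
#' A row with both `cn1` and `cn2` gives the unordered pair of per-haplotype
#' CN alleles (normalized so `cn1 <= cn2`). A row with only `cn1` (or `cn2`
#' equal to `NA`) is interpreted as a total diploid CN with unknown split:
#' `known_phase_split` is `FALSE` and `cn1`/`cn2` are `NA` in the result.
#'
#' @param path label TSV path.
#' @param cn_min,cn_max allowed range of a per-haplotype CN allele.
#' @return a tibble with columns `sample`, `cn1`, `cn2`, `total_cn`,
#'   `known_phase_split`.
#' @export
read_cn_labels <- function(path, cn_min = 0L, cn_max = 4L) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  if (!"sample" %in% names(tab) || !"cn1" %in% names(tab)) {
    stop("label TSV ", path, " must have columns sample, cn1[, cn2]")
  }
  cn1 <- suppressWarnings(as.integer(tab$cn1))
  cn2 <- if ("cn2" %in% names(tab)) suppressWarnings(as.integer(tab$cn2)) else rep(NA_integer_, nrow(tab))
  cn_labels(tab$sample, cn1, cn2, cn_min = cn_min, cn_max = cn_max)
}

#' Construct a CN label table
#'
#' Programmatic equivalent of [read_cn_labels()]: validates and normalizes
#' CN-genotype labels into the tibble used throughout the package.
#'
#' @param sample sample ids.
#' @param cn1,cn2 per-haplotype CN alleles; `cn2 = NA` marks a total-CN row
#'   where `cn1` holds the diploid total.
#' @inheritParams read_cn_labels
#' @export
cn_labels <- function(sample, cn1, cn2 = NA_integer_, cn_min = 0L, cn_max = 4L) {
  n <- length(sample)
  cn1 <- as.integer(rep_len(cn1, n))
  cn2 <- as.integer(rep_len(cn2, n))
  if (anyDuplicated(sample)) stop("duplicated sample id in labels")
  known <- !is.na(cn2)
  if (anyNA(cn1)) stop("cn1 missing or non-integer for sample ", sample[is.na(cn1)][1])
  lo <- pmin(cn1, cn2)
  hi <- pmax(cn1, cn2)
  total <- ifelse(known, cn1 + cn2, cn1)
  bad_pair <- known & (lo < cn_min | hi > cn_max)
  bad_total <- !known & (total < 2L * cn_min | total > 2L * cn_max)
  if (any(bad_pair | bad_total)) {
    stop(
      "CN label out of range [", cn_min, ", ", cn_max, "] for sample ",
      sample[bad_pair | bad_total][1]
    )
  }
  tibble::tibble(
    sample = as.character(sample),
    cn1 = ifelse(known, lo, NA_integer_),
    cn2 = ifelse(known, hi, NA_integer_),
    total_cn = as.integer(total),
    known_phase_split = known
  )
}
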