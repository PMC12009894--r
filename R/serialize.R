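# Versioned JSON (de)serialization of fitted models.
#
# Haplotype frequencies, log-likelihoods and OOB accuracies are stored as
# %.17g decimal strings so the round trip reproduces the doubles bit for bit
# (plain JSON number emission truncates to ~15 significant digits, which is
# enough to perturb posterior ties).

CNBAG_FORMAT_VERSION <- "1.0"

num_str <- function(x) sprintf("%.17g", x)

#' Serialize a fitted model to JSON
#'
#' The file is self-contained: region metadata, SNP universe, build
#' parameters and every classifier's SNP subset, extended-haplotype table
#' (frequencies as full-precision decimal strings) and out-of-bag summary.
#' [read_cnbag()] restores a model whose predictions are bit-identical to
#' the original's.
#'
#' @param model a `cnbag` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnbag <- function(model, path) {
  stopifnot(inherits(model, "cnbag"), length(model$classifiers) >= 1)
  payload <- list(
    format_version = CNBAG_FORMAT_VERSION,
    gene = model$gene,
    chrom = model$chrom,
    center = model$center,
    window_kb = model$window_kb,
    cn_min = model$config$cn_min,
    cn_max = model$config$cn_max,
    config = model$config[c(
      "K", "mtry", "max_snps", "seed", "em_tol", "em_max_iter", "patience"
    )],
    samples = model$samples,
    snps = model$snps,
    classifiers = lapply(model$classifiers, function(clf) {
      list(
        seed = clf$seed,
        bootstrap_seed = clf$split$seed,
        snp_indices = clf$snp_idx,
        oob_correct = clf$oob_correct,
        n_oob = clf$n_oob,
        oob_accuracy = num_str(clf$oob_accuracy),
        oob_samples = model$samples[clf$split$out_of_bag],
        log_lik = num_str(clf$hap_set$log_lik),
        history = clf$history,
        haplotypes = list(
          alleles = apply(clf$hap_set$H, 1L, paste, collapse = ""),
          cn = clf$hap_set$cn,
          freq = vapply(clf$hap_set$freq, num_str, character(1))
        )
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a model from JSON
#'
#' @param path a file written by [write_cnbag()].
#' @return a `cnbag` model. Bootstrap splits are restored as out-of-bag
#'   sample memberships (in-bag multiplicities are not persisted).
#' @export
read_cnbag <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$format_version)) stop("not a cnbag model file: ", path)
  if (!identical(js$format_version, CNBAG_FORMAT_VERSION)) {
    stop(
      "model format version mismatch: file is '", js$format_version,
      "', this package reads '", CNBAG_FORMAT_VERSION, "'"
    )
  }
  snps <- dplyr::bind_rows(lapply(js$snps, tibble::as_tibble))
  snps$pos <- as.integer(snps$pos)
  samples <- as.character(unlist(js$samples))
  classifiers <- lapply(js$classifiers, function(clf) {
    alleles <- as.character(unlist(clf$haplotypes$alleles))
    H <- do.call(rbind, lapply(strsplit(alleles, ""), as.integer))
    if (is.null(H)) H <- matrix(integer(0), 0, 0)
    snp_idx <- as.integer(unlist(clf$snp_indices))
    hs <- structure(
      list(
        snp_ids = snps$snp_id[snp_idx],
        H = H,
        cn = as.integer(unlist(clf$haplotypes$cn)),
        freq = as.numeric(unlist(clf$haplotypes$freq)),
        log_lik = as.numeric(clf$log_lik),
        ll_trace = numeric(0),
        n_iter = NA_integer_,
        converged = NA
      ),
      class = "hap_set"
    )
    oob_idx <- match(as.character(unlist(clf$oob_samples)), samples)
    structure(
      list(
        snp_idx = snp_idx,
        snp_ids = hs$snp_ids,
        hap_set = hs,
        oob_accuracy = as.numeric(clf$oob_accuracy),
        oob_correct = as.integer(clf$oob_correct),
        n_oob = as.integer(clf$n_oob),
        history = dplyr::bind_rows(lapply(clf$history, tibble::as_tibble)),
        split = structure(
          list(
            in_bag = NULL, out_of_bag = oob_idx,
            seed = as.integer(clf$bootstrap_seed), n = length(samples)
          ),
          class = "bootstrap_split"
        ),
        seed = as.integer(clf$seed)
      ),
      class = "cn_classifier"
    )
  })
  cfg <- js$config
  structure(
    list(
      gene = js$gene, chrom = js$chrom, center = js$center,
      window_kb = js$window_kb,
      snps = snps, samples = samples, classifiers = classifiers,
      config = list(
        K = as.integer(cfg$K), mtry = as.integer(cfg$mtry),
        max_snps = as.integer(cfg$max_snps), cn_min = as.integer(js$cn_min),
        cn_max = as.integer(js$cn_max), seed = as.integer(cfg$seed),
        em_tol = as.numeric(cfg$em_tol),
        em_max_iter = as.integer(cfg$em_max_iter),
        patience = as.integer(cfg$patience)
      )
    ),
    class = "cnbag"
  )
}
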