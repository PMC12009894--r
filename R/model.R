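# The K-classifier ensemble: build, match model SNPs to a target dataset,
# aggregate posteriors, and call CN genotypes with a call threshold.

#' Build an attribute-bagging CN imputation model
#'
#' Trains `K` classifiers, each on its own bootstrap sample of the reference
#' panel with a greedily grown SNP subset (see [train_classifier()]).
#' Per-classifier seeds are derived deterministically from `seed`, so the
#' same inputs and seed always give the identical model. The panel is
#' expected to be QC'd and window-selected already (see [snp_qc()],
#' [select_flanking()]); the region metadata is recorded in the model for
#' provenance and target matching.
#'
#' @param genotypes reference-panel [geno_matrix()].
#' @param labels label tibble ([cn_labels()]) covering every panel sample.
#' @param gene gene name recorded in the model.
#' @param chrom,center,window_kb region metadata (recorded, not applied).
#' @param K number of classifiers.
#' @param mtry candidate SNPs drawn per growth round; default
#'   `ceiling(sqrt(P))`.
#' @param max_snps per-classifier SNP subset cap; default `min(P, 25)`.
#' @param cn_min,cn_max per-haplotype CN allele bounds.
#' @param seed master RNG seed.
#' @param em_tol,em_max_iter EM convergence controls.
#' @param patience failed growth redraws allowed before a classifier stops.
#' @return an object of class `cnbag`.
#' @export
cnbag <- function(genotypes, labels, gene = "gene", chrom = NULL, center = NULL,
                  window_kb = NULL, K = 25L, mtry = NULL, max_snps = NULL,
                  cn_min = 0L, cn_max = 4L, seed = 1L, em_tol = 1e-6,
                  em_max_iter = 200L, patience = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"), K >= 1, cn_min <= cn_max)
  p <- ncol(genotypes)
  if (p == 0L) stop("no SNPs available to build a model")
  n <- nrow(genotypes)
  labels <- align_labels(labels, sample_ids(genotypes))
  mtry <- mtry %||% ceiling(sqrt(p))
  max_snps <- max_snps %||% min(p, 25L)
  cn_range <- seq.int(cn_min, cn_max)
  classifiers <- vector("list", K)
  for (k in seq_len(K)) {
    seed_k <- derive_seed(seed, k)
    split <- bootstrap_split(n, seed_k)
    attempt <- 0L
    while (length(split$out_of_bag) == 0L) {
      attempt <- attempt + 1L
      if (attempt > 10L) stop("could not draw a bootstrap sample with a non-empty out-of-bag set")
      split <- bootstrap_split(n, derive_seed(seed_k, 1000L + attempt))
    }
    classifiers[[k]] <- train_classifier(
      genotypes, labels, split,
      candidate_pool = seq_len(p), mtry = mtry, max_snps = max_snps,
      seed = derive_seed(seed_k, 2L), cn_range = cn_range,
      em_tol = em_tol, em_max_iter = em_max_iter, patience = patience
    )
  }
  structure(
    list(
      gene = gene, chrom = chrom, center = center, window_kb = window_kb,
      snps = snp_meta(genotypes),
      samples = sample_ids(genotypes),
      classifiers = classifiers,
      config = list(
        K = as.integer(K), mtry = as.integer(mtry),
        max_snps = as.integer(max_snps), cn_min = as.integer(cn_min),
        cn_max = as.integer(cn_max), seed = as.integer(seed),
        em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
        patience = as.integer(patience)
      )
    ),
    class = "cnbag"
  )
}

align_labels <- function(labels, samples) {
  idx <- match(samples, labels$sample)
  if (anyNA(idx)) {
    stop("no CN label for sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
  }
  labels[idx, , drop = FALSE]
}

#' @export
print.cnbag <- function(x, ...) {
  cat(
    "<cnbag> gene ", x$gene, ": ", length(x$classifiers), " classifiers over ",
    nrow(x$snps), " SNPs; mean OOB accuracy ",
    signif(mean(vapply(x$classifiers, `[[`, numeric(1), "oob_accuracy")), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy cnbag
#' @export
tidy.cnbag <- function(x, ...) {
  tibble::tibble(
    classifier = seq_along(x$classifiers),
    seed = vapply(x$classifiers, `[[`, integer(1), "seed"),
    n_snps = vapply(x$classifiers, function(c) length(c$snp_idx), integer(1)),
    n_haplotypes = vapply(x$classifiers, function(c) length(c$hap_set$freq), integer(1)),
    oob_accuracy = vapply(x$classifiers, `[[`, numeric(1), "oob_accuracy"),
    n_oob = vapply(x$classifiers, `[[`, integer(1), "n_oob")
  )
}

#' @method glance cnbag
#' @export
glance.cnbag <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    gene = x$gene,
    n_classifiers = nrow(td),
    n_snps_universe = nrow(x$snps),
    mean_snps_per_classifier = mean(td$n_snps),
    mean_oob_accuracy = mean(td$oob_accuracy),
    cn_min = x$config$cn_min,
    cn_max = x$config$cn_max
  )
}

# ---- model/target SNP matching ---------------------------------------------

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Match model SNPs to a target dataset
#'
#' Aligns a target genotype matrix onto the model's SNP universe. SNPs are
#' matched by `snp_id` first, then by `chrom` + `pos`. Allele reconciliation:
#' identical alleles are kept as-is; swapped alleles recode genotypes as
#' `2 - g`; complementary alleles are strand-flipped and re-compared (codes
#' unchanged, or recoded when flipped and swapped). Palindromic (A/T, C/G)
#' SNPs cannot be oriented and are dropped by default; model SNPs absent
#' from the target become all-missing columns.
#'
#' @param model a `cnbag` model.
#' @param target target [geno_matrix()].
#' @param keep_palindromic treat A/T and C/G SNPs as same-strand instead of
#'   dropping them.
#' @return list with `genotypes` (aligned [geno_matrix()] over the model SNP
#'   universe, carrying the model's SNP metadata) and `report`, a tibble with
#'   one row per model SNP: `snp_id`, `status`, `target_snp_id`. Statuses:
#'   `matched`, `matched_swapped`, `matched_strand_flipped`,
#'   `ambiguous_dropped`, `missing_in_target`.
#' @export
match_snps <- function(model, target, keep_palindromic = FALSE) {
  msnps <- model$snps
  tsnps <- snp_meta(target)
  tcodes <- geno_codes(target)
  n <- nrow(tcodes)
  p <- nrow(msnps)
  out <- matrix(NA_integer_, n, p, dimnames = list(sample_ids(target), msnps$snp_id))
  status <- character(p)
  target_id <- rep(NA_character_, p)
  t_idx <- match(msnps$snp_id, tsnps$snp_id)
  pos_key_t <- paste(tsnps$chrom, tsnps$pos)
  pos_idx <- match(paste(msnps$chrom, msnps$pos), pos_key_t)
  t_idx <- ifelse(is.na(t_idx), pos_idx, t_idx)
  for (j in seq_len(p)) {
    tj <- t_idx[j]
    if (is.na(tj)) {
      status[j] <- "missing_in_target"
      next
    }
    target_id[j] <- tsnps$snp_id[tj]
    ma <- msnps$allele_a[j]
    mb <- msnps$allele_b[j]
    ta <- tsnps$allele_a[tj]
    tb <- tsnps$allele_b[tj]
    palindromic <- ta == DNA_COMPLEMENT[tb] || ma == DNA_COMPLEMENT[mb]
    if (palindromic && !keep_palindromic) {
      status[j] <- "ambiguous_dropped"
      next
    }
    g <- tcodes[, tj]
    if (ta == ma && tb == mb) {
      out[, j] <- g
      status[j] <- "matched"
    } else if (ta == mb && tb == ma) {
      out[, j] <- 2L - g
      status[j] <- "matched_swapped"
    } else if (DNA_COMPLEMENT[ta] == ma && DNA_COMPLEMENT[tb] == mb) {
      out[, j] <- g
      status[j] <- "matched_strand_flipped"
    } else if (DNA_COMPLEMENT[ta] == mb && DNA_COMPLEMENT[tb] == ma) {
      out[, j] <- 2L - g
      status[j] <- "matched_strand_flipped"
    } else {
      status[j] <- "ambiguous_dropped"
      next
    }
  }
  list(
    genotypes = geno_matrix(out, msnps, samples = sample_ids(target)),
    report = tibble::tibble(
      snp_id = msnps$snp_id, status = status, target_snp_id = target_id
    )
  )
}

#' Average posterior distributions across classifiers
#'
#' Arithmetic mean over non-abstaining classifiers (a CN pair absent from a
#' distribution contributes probability 0), renormalized. With zero
#' non-abstaining classifiers the result is undefined (a no-call upstream).
#'
#' @param posteriors list of named probability vectors as returned by
#'   [posterior_cn()]; `NULL` entries and undefined distributions are
#'   abstentions.
#' @return named probability vector, or a zero-length vector with attribute
#'   `undefined = TRUE` plus attribute `n_abstained` in both cases.
#' @export
aggregate_posteriors <- function(posteriors) {
  voting <- Filter(function(p) !is.null(p) && length(p) > 0, posteriors)
  n_abst <- length(posteriors) - length(voting)
  if (length(voting) == 0L) {
    return(structure(numeric(0), undefined = TRUE, n_abstained = n_abst))
  }
  keys <- sort(unique(unlist(lapply(voting, names))))
  acc <- numeric(length(keys))
  names(acc) <- keys
  for (p in voting) acc[names(p)] <- acc[names(p)] + p
  acc <- acc / length(voting)
  acc <- acc / sum(acc)
  pp <- parse_cn_pair(names(acc))
  structure(acc[order(pp[, 1L], pp[, 2L])], n_abstained = n_abst)
}

#' Impute CN genotypes for a target dataset
#'
#' Matches the target SNPs onto the model universe ([match_snps()]), computes
#' each classifier's posterior CN-genotype distribution per sample, averages
#' them ([aggregate_posteriors()]), and reports the highest-probability
#' unordered CN pair. A sample is *called* when the aggregated probability of
#' its best pair reaches the call threshold `ct`; exact probability ties are
#' broken toward the lexicographically smallest CN pair. A classifier with no
#' matched SNP abstains for every sample; a sample for which all classifiers
#' abstain is a no-call with probability 0.
#'
#' @param object a `cnbag` model.
#' @param newdata target [geno_matrix()]; defaults to asking for the training
#'   panel is not supported — pass it explicitly.
#' @param ct call threshold on the aggregated best-pair probability.
#' @param keep_palindromic passed to [match_snps()].
#' @param posteriors attach the full aggregated distribution as a list column
#'   `posterior`.
#' @param ... unused.
#' @return tibble with columns `sample`, `cn1`, `cn2`, `total_cn`, `prob`,
#'   `called`, `n_abstained` (attributes: `match_report`).
#' @export
predict.cnbag <- function(object, newdata, ct = 0.5, keep_palindromic = FALSE,
                          posteriors = FALSE, ...) {
  matched <- match_snps(object, newdata, keep_palindromic = keep_palindromic)
  aligned <- geno_codes(matched$genotypes)
  usable <- matched$report$status %in%
    c("matched", "matched_swapped", "matched_strand_flipped")
  n <- nrow(aligned)
  per_clf <- lapply(object$classifiers, function(clf) {
    if (!any(usable[clf$snp_idx])) {
      return(NULL) # classifier abstains for all samples
    }
    posterior_cn_matrix(clf$hap_set, aligned[, clf$snp_idx, drop = FALSE])
  })
  if (all(vapply(per_clf, is.null, logical(1)))) {
    stop("no classifier has any matched SNP in the target dataset")
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    posts <- lapply(per_clf, function(pc) if (is.null(pc)) NULL else pc[[i]])
    agg <- aggregate_posteriors(posts)
    if (length(agg) == 0L) {
      res[[i]] <- list(
        cn1 = NA_integer_, cn2 = NA_integer_, total_cn = NA_integer_,
        prob = 0, called = FALSE,
        n_abstained = attr(agg, "n_abstained"), posterior = list(NULL)
      )
    } else {
      key <- argmax_cn_pair(agg)
      pair <- parse_cn_pair(key)
      res[[i]] <- list(
        cn1 = unname(pair[1L, 1L]), cn2 = unname(pair[1L, 2L]),
        total_cn = unname(sum(pair[1L, ])),
        prob = unname(agg[key]),
        called = unname(agg[key]) >= ct,
        n_abstained = attr(agg, "n_abstained"),
        posterior = list(agg)
      )
    }
  }
  out <- dplyr::bind_rows(lapply(res, tibble::as_tibble))
  out <- dplyr::bind_cols(tibble::tibble(sample = sample_ids(newdata)), out)
  if (!posteriors) out$posterior <- NULL
  attr(out, "match_report") <- matched$report
  out
}

#' @rdname predict.cnbag
#' @param x a prediction tibble from `predict.cnbag`.
#' @export
snp_match_report <- function(x) {
  attr(x, "match_report")
}
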