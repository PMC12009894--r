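# One attribute-bagged classifier: a bootstrap sample of the reference panel,
# a greedily grown SNP subset, and the EM-fitted extended-haplotype set.

#' Draw a bootstrap split
#'
#' `n` uniform draws with replacement; the out-of-bag set is every index not
#' drawn. With `n` samples the expected out-of-bag fraction is
#' `(1 - 1/n)^n`, about 37% for panel-scale `n`. Deterministic given `seed`.
#'
#' @param n number of samples (>= 2).
#' @param seed integer RNG seed.
#' @return an object of class `bootstrap_split`: list with `in_bag` (length
#'   `n`, with repeats), `out_of_bag`, `seed`, `n`.
#' @export
bootstrap_split <- function(n, seed) {
  stopifnot(n >= 2)
  in_bag <- with_seed(seed, sample.int(n, n, replace = TRUE))
  structure(
    list(
      in_bag = in_bag,
      out_of_bag = setdiff(seq_len(n), in_bag),
      seed = as.integer(seed),
      n = as.integer(n)
    ),
    class = "bootstrap_split"
  )
}

#' @export
print.bootstrap_split <- function(x, ...) {
  cat(
    "<bootstrap_split> n = ", x$n, ", out-of-bag = ", length(x$out_of_bag),
    " (", signif(length(x$out_of_bag) / x$n, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

# Count of correctly predicted samples among `idx` rows of geno, given the
# fitted hap set over columns snp_idx. Abstentions and no-calls count wrong.
# Labels with unknown phase split are compared on diploid totals.
count_correct <- function(hs, geno, labels, idx, snp_idx) {
  if (length(idx) == 0L) {
    return(0L)
  }
  posts <- posterior_cn_matrix(hs, geno[idx, snp_idx, drop = FALSE])
  correct <- 0L
  for (i in seq_along(idx)) {
    pr <- posts[[i]]
    if (length(pr) == 0L) next
    key <- argmax_cn_pair(pr)
    row <- idx[i]
    if (labels$known_phase_split[row]) {
      ok <- key == cn_pair_key(labels$cn1[row], labels$cn2[row])
    } else {
      ok <- sum(parse_cn_pair(key)) == labels$total_cn[row]
    }
    if (ok) correct <- correct + 1L
  }
  correct
}

#' Out-of-bag accuracy of a classifier
#'
#' Fraction of out-of-bag individuals whose maximum-posterior CN pair equals
#' the true unordered pair (total-CN labels compared on totals). Undefined
#' posteriors (abstentions) count as incorrect.
#'
#' @param classifier a `cn_classifier` from [train_classifier()].
#' @param genotypes the training [geno_matrix()].
#' @param labels label tibble aligned to `genotypes` rows.
#' @return accuracy in `[0, 1]`.
#' @export
oob_accuracy <- function(classifier, genotypes, labels) {
  geno <- geno_codes(genotypes)
  oob <- classifier$split$out_of_bag
  if (length(oob) == 0L) stop("empty out-of-bag set")
  count_correct(classifier$hap_set, geno, labels, oob, classifier$snp_idx) / length(oob)
}

# Fit a single-SNP hap set on the in-bag data (uniform initialization over
# {0,1} x cn_range, then prune).
fit_first_snp <- function(geno, labels, in_bag, j, cn_range, tol, max_iter) {
  cn_opts <- cn_range
  H <- matrix(rep(c(0L, 1L), times = length(cn_opts)), ncol = 1L)
  cn <- rep(as.integer(cn_opts), each = 2L)
  fit <- em_core(H, cn, rep(1, nrow(H)),
    geno[in_bag, j, drop = FALSE], labels[in_bag, , drop = FALSE],
    tol = tol, max_iter = max_iter
  )
  prune_hapset(fit, 1 / (4 * length(in_bag)))
}

# Expand the current hap set with SNP j and refit on in-bag data.
# Initial frequencies split each haplotype by the in-bag allele-b frequency.
refit_with_snp <- function(state, geno, labels, in_bag, snp_idx_new, j,
                           tol, max_iter) {
  gj <- geno[in_bag, j]
  p_b <- mean(gj, na.rm = TRUE) / 2
  if (!is.finite(p_b)) p_b <- 0.5
  p_b <- min(max(p_b, 1e-3), 1 - 1e-3)
  H2 <- rbind(cbind(state$H, 0L), cbind(state$H, 1L))
  cn2 <- c(state$cn, state$cn)
  freq0 <- c(state$freq * (1 - p_b), state$freq * p_b)
  fit <- em_core(H2, cn2, freq0,
    geno[in_bag, snp_idx_new, drop = FALSE], labels[in_bag, , drop = FALSE],
    tol = tol, max_iter = max_iter
  )
  prune_hapset(fit, 1 / (4 * length(in_bag)))
}

#' Train one attribute-bagged classifier
#'
#' Grows the classifier's SNP subset greedily by out-of-bag accuracy: the
#' subset starts from the best single SNP among an initial random draw of
#' `mtry` candidates, then repeatedly draws `mtry` unused candidates, refits
#' the in-bag extended-haplotype EM for each tentative addition, and accepts
#' the best addition only when it strictly improves the out-of-bag correct
#' count. One additional redraw ("patience") is allowed after a failed round
#' before growth stops; growth also stops when the pool is exhausted or
#' `max_snps` is reached. Ties between candidates are broken by higher
#' in-bag log-likelihood, then lower SNP index. Everything is deterministic
#' given `seed`.
#'
#' Tentative refits expand the current pruned haplotype set by the new SNP
#' (frequencies split by the in-bag allele frequency) before running EM, and
#' prune at `1 / (4 N_in_bag)` after convergence, which keeps the haplotype
#' state space bounded as the subset grows.
#'
#' @param genotypes training [geno_matrix()].
#' @param labels label tibble aligned to `genotypes` rows.
#' @param split a [bootstrap_split()].
#' @param candidate_pool SNP column indices eligible for selection.
#' @param mtry candidates drawn per round; default `ceiling(sqrt(P))` over
#'   the pool size.
#' @param max_snps cap on the subset size.
#' @param seed RNG seed for candidate draws.
#' @param cn_range allowed CN alleles.
#' @param em_tol,em_max_iter EM convergence controls.
#' @param patience failed redraws allowed before stopping (default 1).
#' @return an object of class `cn_classifier`: list with `snp_idx`,
#'   `snp_ids`, `hap_set`, `oob_accuracy`, `oob_correct`, `n_oob`,
#'   `history` (tibble of accepted additions), `split`, `seed`.
#' @export
train_classifier <- function(genotypes, labels, split,
                             candidate_pool = seq_len(ncol(genotypes)),
                             mtry = NULL, max_snps = 25L, seed = 1L,
                             cn_range = 0:4, em_tol = 1e-6,
                             em_max_iter = 200L, patience = 1L) {
  geno <- geno_codes(genotypes)
  stopifnot(length(candidate_pool) >= 1)
  if (length(split$out_of_bag) == 0L) stop("empty out-of-bag set")
  mtry <- mtry %||% ceiling(sqrt(length(candidate_pool)))
  in_bag <- split$in_bag
  oob <- split$out_of_bag
  n_oob <- length(oob)

  with_seed(seed, {
    draw <- sample(candidate_pool, min(mtry, length(candidate_pool)))
    best <- NULL
    for (j in sort(draw)) {
      fit <- fit_first_snp(geno, labels, in_bag, j, cn_range, em_tol, em_max_iter)
      cnt <- count_correct(fit, geno, labels, oob, j)
      if (is.null(best) || cnt > best$cnt ||
        (cnt == best$cnt && fit$log_lik > best$fit$log_lik)) {
        best <- list(j = j, fit = fit, cnt = cnt)
      }
    }
    snp_idx <- best$j
    state <- best$fit
    best_cnt <- best$cnt
    history <- list(list(
      step = 1L, snp_id = colnames(geno)[best$j] %||% as.character(best$j),
      oob_accuracy = best_cnt / n_oob
    ))
    fails <- 0L
    while (length(snp_idx) < max_snps) {
      avail <- setdiff(candidate_pool, snp_idx)
      if (length(avail) == 0L) break
      draw <- sample(avail, min(mtry, length(avail)))
      cand <- NULL
      for (j in sort(draw)) {
        fit <- refit_with_snp(
          state, geno, labels, in_bag, c(snp_idx, j), j,
          em_tol, em_max_iter
        )
        cnt <- count_correct(fit, geno, labels, oob, c(snp_idx, j))
        if (is.null(cand) || cnt > cand$cnt ||
          (cnt == cand$cnt && fit$log_lik > cand$fit$log_lik)) {
          cand <- list(j = j, fit = fit, cnt = cnt)
        }
      }
      if (!is.null(cand) && cand$cnt > best_cnt) {
        snp_idx <- c(snp_idx, cand$j)
        state <- cand$fit
        best_cnt <- cand$cnt
        fails <- 0L
        history[[length(history) + 1L]] <- list(
          step = length(snp_idx),
          snp_id = colnames(geno)[cand$j] %||% as.character(cand$j),
          oob_accuracy = best_cnt / n_oob
        )
      } else {
        fails <- fails + 1L
        if (fails > patience) break
      }
    }
  })

  hs <- new_hap_set(state, colnames(geno)[snp_idx] %||% as.character(snp_idx))
  structure(
    list(
      snp_idx = snp_idx,
      snp_ids = hs$snp_ids,
      hap_set = hs,
      oob_accuracy = best_cnt / n_oob,
      oob_correct = best_cnt,
      n_oob = n_oob,
      history = dplyr::bind_rows(lapply(history, tibble::as_tibble)),
      split = split,
      seed = as.integer(seed)
    ),
    class = "cn_classifier"
  )
}

#' @export
print.cn_classifier <- function(x, ...) {
  cat(
    "<cn_classifier> ", length(x$snp_idx), " SNPs, ",
    length(x$hap_set$freq), " haplotypes, OOB accuracy ",
    signif(x$oob_accuracy, 4), " (n = ", x$n_oob, ")\n",
    sep = ""
  )
  invisible(x)
}
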