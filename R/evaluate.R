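# Evaluation harnesses: confusion tables, one-vs-rest class metrics,
# internal validation (out-of-bag and k-fold), flanking-window sweep and
# call-threshold sweep.

#' Confusion table over CN classes
#'
#' Square matrix indexed by the union of the truth and prediction classes
#' (rows = truth, columns = predicted). `NA` predictions (no-calls) are
#' excluded, so the table total equals the number of called samples.
#'
#' @param truth,predicted class vectors (totals or pair keys).
#' @return an integer matrix of class `cn_confusion`.
#' @export
cn_confusion <- function(truth, predicted) {
  keep <- !is.na(predicted) & !is.na(truth)
  classes <- sort(unique(c(truth[keep], predicted[keep])))
  m <- matrix(0L, length(classes), length(classes), dimnames = list(
    truth = as.character(classes), predicted = as.character(classes)
  ))
  for (i in which(keep)) {
    m[as.character(truth[i]), as.character(predicted[i])] <-
      m[as.character(truth[i]), as.character(predicted[i])] + 1L
  }
  structure(m, class = c("cn_confusion", "matrix", "array"))
}

#' One-vs-rest class metrics
#'
#' Sensitivity, specificity, positive and negative predictive value per CN
#' class, computed one-vs-rest from a confusion table. Undefined ratios
#' (zero denominator, e.g. a class absent from the truth) are reported as
#' `NA`, never as 0.
#'
#' @param confusion a [cn_confusion()] matrix (truth rows, predicted
#'   columns).
#' @return tibble with columns `class`, `n_true`, `sen`, `spe`, `ppv`,
#'   `npv`.
#' @export
class_metrics <- function(confusion) {
  m <- unclass(confusion)
  if (length(m) == 0L || sum(m) == 0L) stop("empty confusion table")
  total <- sum(m)
  classes <- rownames(m)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  rows <- lapply(seq_along(classes), function(i) {
    tp <- m[i, i]
    fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = classes[i], n_true = as.integer(tp + fn),
      sen = ratio(tp, tp + fn), spe = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn)
    )
  })
  dplyr::bind_rows(rows)
}

#' Internal validation of a CN imputation model
#'
#' Out-of-bag mode (the default, matching how the ensemble is built): a
#' model is trained on the full panel and each sample is scored by
#' aggregating only the classifiers whose out-of-bag set contains it — an
#' unbiased internal estimate that needs no data splitting. K-fold mode:
#' folds stratified by CN genotype (falling back to unstratified with a
#' warning when a class has fewer samples than one per fold), a model
#' trained on the held-in folds, held-out samples predicted with `ct = 0`.
#'
#' Accuracy is the fraction of panel samples whose predicted unordered CN
#' pair equals the truth (samples that could not be scored count as
#' incorrect); total-CN accuracy and a total-CN confusion table are
#' reported alongside.
#'
#' @param genotypes panel [geno_matrix()] (already QC'd / window-selected).
#' @param labels label tibble covering all panel samples.
#' @param mode `"oob"` or `"kfold"`.
#' @param folds folds for k-fold mode.
#' @param model optional pre-built `cnbag` trained on exactly this panel
#'   (out-of-bag mode only); otherwise one is built from `...`.
#' @param ... passed to [cnbag()] (`K`, `seed`, `max_snps`, ...).
#' @return an object of class `cn_validation`: list with `accuracy`,
#'   `accuracy_total`, `confusion` (totals), `per_sample` tibble, `mode`,
#'   `n`, and the model (OOB mode).
#' @export
internal_validation <- function(genotypes, labels, mode = c("oob", "kfold"),
                                folds = 5L, model = NULL, ...) {
  mode <- match.arg(mode)
  labels <- align_labels(labels, sample_ids(genotypes))
  if (mode == "oob") {
    model <- model %||% cnbag(genotypes, labels, ...)
    per_sample <- oob_validation_scores(model, genotypes, labels)
  } else {
    per_sample <- kfold_validation_scores(genotypes, labels, folds, ...)
    model <- NULL
  }
  truth_pair <- ifelse(labels$known_phase_split,
    cn_pair_key(labels$cn1, labels$cn2), NA_character_
  )
  correct <- ifelse(labels$known_phase_split,
    !is.na(per_sample$pred_pair) & per_sample$pred_pair == truth_pair,
    !is.na(per_sample$pred_total) & per_sample$pred_total == labels$total_cn
  )
  correct_total <- !is.na(per_sample$pred_total) &
    per_sample$pred_total == labels$total_cn
  per_sample$truth_pair <- truth_pair
  per_sample$truth_total <- labels$total_cn
  per_sample$correct <- correct
  per_sample$correct_total <- correct_total
  # a sample no classifier can score (never out-of-bag) carries no
  # information about the model; it is excluded from accuracy and counted
  scored <- !is.na(per_sample$n_classifiers) & per_sample$n_classifiers > 0
  structure(
    list(
      mode = mode,
      n = nrow(per_sample),
      n_unscored = sum(!scored),
      accuracy = mean(correct[scored]),
      accuracy_total = mean(correct_total[scored]),
      confusion = cn_confusion(labels$total_cn, per_sample$pred_total),
      per_sample = per_sample,
      model = model
    ),
    class = "cn_validation"
  )
}

oob_validation_scores <- function(model, genotypes, labels) {
  geno <- geno_codes(genotypes)
  n <- nrow(geno)
  k <- length(model$classifiers)
  # posterior of every classifier for every sample (patterns deduplicated)
  clf_posts <- lapply(model$classifiers, function(clf) {
    posterior_cn_matrix(clf$hap_set, geno[, clf$snp_idx, drop = FALSE])
  })
  oob_sets <- lapply(model$classifiers, function(clf) clf$split$out_of_bag)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    voting <- which(vapply(oob_sets, function(s) i %in% s, logical(1)))
    if (length(voting) == 0L) {
      res[[i]] <- list(
        pred_pair = NA_character_, pred_total = NA_integer_,
        prob = NA_real_, n_classifiers = 0L
      )
      next
    }
    agg <- aggregate_posteriors(lapply(voting, function(kk) clf_posts[[kk]][[i]]))
    if (length(agg) == 0L) {
      res[[i]] <- list(
        pred_pair = NA_character_, pred_total = NA_integer_,
        prob = NA_real_, n_classifiers = length(voting)
      )
    } else {
      key <- argmax_cn_pair(agg)
      res[[i]] <- list(
        pred_pair = key, pred_total = sum(parse_cn_pair(key)),
        prob = unname(agg[key]), n_classifiers = length(voting)
      )
    }
  }
  out <- dplyr::bind_rows(lapply(res, tibble::as_tibble))
  dplyr::bind_cols(tibble::tibble(sample = sample_ids(genotypes)), out)
}

kfold_validation_scores <- function(genotypes, labels, folds, ...) {
  dots <- list(...)
  seed <- dots$seed %||% 1L
  n <- nrow(genotypes)
  strata <- ifelse(labels$known_phase_split,
    cn_pair_key(labels$cn1, labels$cn2), paste0("t", labels$total_cn)
  )
  fold_of <- integer(n)
  if (min(table(strata)) < 2L) {
    warning("a CN class has fewer than 2 samples; using unstratified folds")
    fold_of <- with_seed(
      derive_seed(seed, 303L),
      sample(rep_len(seq_len(folds), n))
    )
  } else {
    with_seed(derive_seed(seed, 303L), {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    })
  }
  res <- tibble::tibble(
    sample = sample_ids(genotypes),
    pred_pair = NA_character_, pred_total = NA_integer_,
    prob = NA_real_, n_classifiers = NA_integer_, fold = fold_of
  )
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (length(test_idx) == 0L) next
    model_f <- do.call(cnbag, c(
      list(genotypes = genotypes[train_idx, ], labels = labels[train_idx, , drop = FALSE]),
      dots
    ))
    pred <- predict(model_f, genotypes[test_idx, ], ct = 0)
    res$pred_pair[test_idx] <- ifelse(is.na(pred$cn1), NA_character_,
      cn_pair_key(pred$cn1, pred$cn2)
    )
    res$pred_total[test_idx] <- pred$total_cn
    res$prob[test_idx] <- pred$prob
    res$n_classifiers[test_idx] <- length(model_f$classifiers)
  }
  res
}

#' @export
print.cn_validation <- function(x, ...) {
  cat(
    "<cn_validation> ", x$mode, " mode, n = ", x$n,
    ": CN-pair accuracy ", signif(x$accuracy, 4),
    ", total-CN accuracy ", signif(x$accuracy_total, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method glance cn_validation
#' @export
glance.cn_validation <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n = x$n,
    accuracy = x$accuracy, accuracy_total = x$accuracy_total
  )
}

#' Flanking-window sweep
#'
#' For each half-window width, selects the SNPs in the window around the
#' gene center, applies QC, builds a model and runs out-of-bag internal
#' validation. Quantifies the accuracy/SNP-count trade-off of widening the
#' flanking region; windows are nested, so SNP counts are non-decreasing.
#'
#' @param genotypes full-region panel [geno_matrix()].
#' @param labels label tibble.
#' @param chrom,center gene location.
#' @param windows half-window widths in kb.
#' @param qc apply [snp_qc()] inside each window.
#' @param ... passed to [cnbag()].
#' @return tibble of class `cn_window_sweep`: `window_kb`, `n_snps`,
#'   `accuracy`, `accuracy_total`, `n_scored` (`NA` accuracy when a window
#'   holds no SNPs).
#' @export
window_sweep <- function(genotypes, labels, chrom, center,
                         windows = seq(10, 100, by = 10), qc = TRUE, ...) {
  rows <- lapply(sort(windows), function(w) {
    g_w <- suppressWarnings(select_flanking(genotypes, chrom, center, w))
    if (qc && ncol(g_w) > 0) {
      g_w <- suppressWarnings(snp_qc(g_w))$genotypes
    }
    if (ncol(g_w) == 0L) {
      return(tibble::tibble(
        window_kb = w, n_snps = 0L, accuracy = NA_real_,
        accuracy_total = NA_real_, n_scored = 0L
      ))
    }
    val <- internal_validation(g_w, labels, mode = "oob", ...)
    tibble::tibble(
      window_kb = w, n_snps = ncol(g_w), accuracy = val$accuracy,
      accuracy_total = val$accuracy_total,
      n_scored = sum(val$per_sample$n_classifiers > 0)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cn_window_sweep", class(out))
  out
}

#' Call-threshold sweep
#'
#' Re-thresholds a set of predictions over a grid of call thresholds and
#' reports, per threshold, the call rate (called / total) and the accuracy
#' among called samples. Call rate is monotone non-increasing in the
#' threshold; this is asserted. Accuracy is `NA` when nothing is called.
#'
#' @param predictions tibble from [predict.cnbag()] (needs `sample`, `cn1`,
#'   `cn2`, `total_cn`, `prob`).
#' @param truth label tibble.
#' @param grid thresholds to evaluate.
#' @return tibble of class `cn_ct_sweep`: `ct`, `n_called`, `call_rate`,
#'   `accuracy`.
#' @export
ct_sweep <- function(predictions, truth, grid = seq(0, 0.95, by = 0.05)) {
  truth <- align_labels(truth, predictions$sample)
  has_pred <- !is.na(predictions$cn1)
  correct <- ifelse(truth$known_phase_split,
    has_pred & cn_pair_key(predictions$cn1, predictions$cn2) ==
      cn_pair_key(truth$cn1, truth$cn2),
    has_pred & predictions$total_cn == truth$total_cn
  )
  n <- nrow(predictions)
  rows <- lapply(sort(grid), function(ct) {
    called <- has_pred & predictions$prob >= ct
    tibble::tibble(
      ct = ct, n_called = sum(called), call_rate = sum(called) / n,
      accuracy = if (any(called)) mean(correct[called]) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(diff(out$call_rate) <= 0 + 1e-12))
  class(out) <- c("cn_ct_sweep", class(out))
  out
}
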