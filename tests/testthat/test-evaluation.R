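test_that("class metrics match hand computation and mark undefined ratios", {
  # perfect diagonal: every metric 1 for every class
  perfect <- cn_confusion(c(0, 1, 1, 2, 2), c(0, 1, 1, 2, 2))
  cm <- class_metrics(perfect)
  expect_true(all(cm$sen == 1 & cm$spe == 1 & cm$ppv == 1 & cm$npv == 1))
  expect_equal(sum(unclass(perfect)), 5L)

  # 2-class table [[8,2],[1,9]]: class-0 SEN .8, SPE .9, PPV 8/9, NPV 9/11
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), "a", rep("b", 9))
  cm2 <- class_metrics(cn_confusion(truth, pred))
  a <- cm2[cm2$class == "a", ]
  expect_equal(a$sen, 0.8)
  expect_equal(a$spe, 0.9)
  expect_equal(a$ppv, 8 / 9)
  expect_equal(a$npv, 9 / 11)

  # class never present in the truth: SEN is 0/0 -> NA, not 0
  cm3 <- class_metrics(cn_confusion(c("x", "x"), c("x", "y")))
  expect_true(is.na(cm3$sen[cm3$class == "y"]))
  expect_false(any(cm3$sen == 0, na.rm = TRUE))
})

test_that("internal validation reaches accuracy 1 on a perfect-tag panel in both modes", {
  panel <- perfect_tag_panel(n = 90, p = 5, tag_col = 2, seed = 3)
  val <- internal_validation(panel$genotypes, panel$labels,
    mode = "oob",
    K = 12, seed = 2, cn_max = 1, mtry = 5
  )
  expect_equal(val$accuracy, 1.0)
  expect_equal(val$accuracy_total, 1.0)
  expect_equal(sum(unclass(val$confusion)), sum(val$per_sample$n_classifiers > 0))

  valk <- internal_validation(panel$genotypes, panel$labels,
    mode = "kfold",
    folds = 3, K = 6, seed = 2, cn_max = 1, mtry = 5
  )
  expect_equal(valk$accuracy, 1.0)
})

test_that("oob validation is deterministic given the model seed", {
  panel <- small_sim_panel(seed = 9, n_samples = 60, n_snps = 8)
  v1 <- internal_validation(panel$genotypes, panel$labels, K = 4, seed = 11)
  v2 <- internal_validation(panel$genotypes, panel$labels, K = 4, seed = 11)
  expect_identical(v1$accuracy, v2$accuracy)
  expect_identical(v1$per_sample$prob, v2$per_sample$prob)
})

test_that("shuffled labels drop validation accuracy to the chance band", {
  panel <- perfect_tag_panel(n = 90, p = 5, tag_col = 2, seed = 4)
  shuffled <- panel$labels
  perm <- cnbag:::with_seed(8, sample(nrow(shuffled)))
  shuffled[, c("cn1", "cn2", "total_cn")] <- shuffled[perm, c("cn1", "cn2", "total_cn")]
  val <- internal_validation(panel$genotypes, shuffled, K = 8, seed = 3, cn_max = 1)
  class_freq <- table(cnbag:::cn_pair_key(shuffled$cn1, shuffled$cn2)) / nrow(shuffled)
  modal <- max(class_freq)
  # accuracy should sit near the modal-class baseline, far below the
  # tagged-panel ceiling of 1
  expect_lt(val$accuracy, 0.95)
  expect_gt(val$accuracy, sum(class_freq^2) - 0.15)
})

test_that("window sweep nests SNP counts and agrees with single-window validation", {
  panel <- small_sim_panel(seed = 12, n_samples = 70, n_snps = 10)
  center <- panel$cfg$gene_center_bp
  sw <- window_sweep(panel$genotypes, panel$labels,
    chrom = "19", center = center,
    windows = c(30, 60, 100), qc = FALSE, K = 3, seed = 5
  )
  expect_equal(sw$window_kb, c(30, 60, 100))
  expect_true(all(diff(sw$n_snps) >= 0))

  g100 <- select_flanking(panel$genotypes, "19", center, 100)
  direct <- internal_validation(g100, panel$labels, K = 3, seed = 5)
  expect_equal(sw$accuracy[sw$window_kb == 100], direct$accuracy)

  # a window with no SNPs yields an NA-accuracy row, not an error
  sw0 <- suppressWarnings(window_sweep(panel$genotypes, panel$labels,
    chrom = "7", center = center, windows = 10, qc = FALSE, K = 2, seed = 5
  ))
  expect_equal(sw0$n_snps, 0L)
  expect_true(is.na(sw0$accuracy))
})

test_that("ct sweep matches brute-force filter-and-count at every threshold", {
  cnbag:::with_seed(14, {
    n <- 200
    truth <- cn_labels(
      sprintf("T%03d", 1:n),
      sample(0:1, n, TRUE), sample(0:2, n, TRUE)
    )
    pred_pair <- cbind(sample(0:1, n, TRUE), sample(0:2, n, TRUE))
    predictions <- tibble::tibble(
      sample = truth$sample,
      cn1 = pmin(pred_pair[, 1], pred_pair[, 2]),
      cn2 = pmax(pred_pair[, 1], pred_pair[, 2]),
      total_cn = cn1 + cn2,
      prob = round(runif(n), 2)
    )
  })
  grid <- seq(0, 0.95, by = 0.05)
  sw <- ct_sweep(predictions, truth, grid = grid)
  expect_equal(sw$call_rate[1], 1.0)
  expect_true(all(diff(sw$call_rate) <= 0))
  for (ct in c(0.15, 0.5, 0.9)) {
    row <- which.min(abs(sw$ct - ct))
    called <- predictions$prob >= sw$ct[row]
    expect_equal(sw$n_called[row], sum(called))
    ok <- predictions$cn1 == truth$cn1 & predictions$cn2 == truth$cn2
    expect_equal(sw$accuracy[row], mean(ok[called]))
  }

  # an all-confident predictor keeps a flat call rate of 1
  conf <- predictions
  conf$prob <- 1
  swc <- ct_sweep(conf, truth, grid = grid)
  expect_true(all(swc$call_rate == 1))

  # boundary: probability 0.49 is a no-call at CT 0.5
  one <- tibble::tibble(
    sample = "T001", cn1 = 0L, cn2 = 1L, total_cn = 1L, prob = 0.49
  )
  sw1 <- ct_sweep(one, truth[1, ], grid = c(0, 0.5))
  expect_equal(sw1$n_called[sw1$ct == 0.5], 0L)
})
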