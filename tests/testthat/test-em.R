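test_that("configuration enumeration covers the spec'd edge cases", {
  # hom b/b genotype, CN unconstrained over {0,1}: one allele phase x 4 CN pairs
  e1 <- enumerate_configurations(2L, cn = NULL, cn_range = 0:1)
  expect_equal(nrow(e1), 4L)
  expect_true(all(e1$hap1 == "1" & e1$hap2 == "1"))

  # het genotype with known CN pair (1,0): 2 allele orders x 2 CN orders
  e2 <- enumerate_configurations(1L, cn = list(cn1 = 1L, cn2 = 0L), cn_range = 0:4)
  expect_equal(nrow(e2), 4L)
  expect_setequal(paste(e2$hap1, e2$hap2), c("0 1", "1 0"))
  expect_setequal(paste(e2$cn1, e2$cn2), c("1 0", "0 1"))

  # missing genotype, total CN 2 over {0,1,2}: 4 allele pairs x 3 decompositions
  e3 <- enumerate_configurations(NA_integer_, cn = list(total = 2L), cn_range = 0:2)
  expect_equal(nrow(e3), 12L)
  expect_setequal(unique(paste(e3$cn1, e3$cn2)), c("0 2", "1 1", "2 0"))
  expect_setequal(unique(paste(e3$hap1, e3$hap2)), c("0 0", "0 1", "1 0", "1 1"))
})

test_that("EM reproduces exact counting frequencies when phase is unambiguous", {
  # 3 individuals [0] with CN pair (1,1), one [1] with pair (1,0):
  # haplotype ([0],CN1) appears 7/8, ([1],CN0) 1/8, no latent structure.
  geno <- matrix(c(0L, 0L, 0L, 1L), ncol = 1)
  rownames(geno) <- paste0("I", 1:4)
  labels <- cn_labels(rownames(geno), c(1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L))
  hs <- em_fit(geno, labels, cn_range = 0:1)
  tab <- tidy(hs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$freq[tab$alleles == "0" & tab$cn_allele == 1], 7 / 8,
    tolerance = 1e-4
  )
  expect_equal(tab$freq[tab$alleles == "1" & tab$cn_allele == 0], 1 / 8,
    tolerance = 1e-4
  )

  # fully homozygous panel: frequencies equal direct haplotype counts / 2N
  geno2 <- matrix(c(0L, 2L, 2L, 0L, 0L, 0L, 2L, 2L), ncol = 2)
  rownames(geno2) <- paste0("H", 1:4)
  labels2 <- cn_labels(rownames(geno2), c(1L, 0L, 2L, 1L), c(1L, 0L, 2L, 1L))
  hs2 <- em_fit(geno2, labels2, cn_range = 0:2)
  tab2 <- tidy(hs2)
  expect_equal(sort(tab2$freq), sort(c(2, 2, 2, 2) / 8))
  # truly no latent structure: a single M-step is stationary
  expect_lt(abs(hs2$ll_trace[length(hs2$ll_trace)] - hs2$ll_trace[2]), 1e-9)
})

test_that("EM log-likelihood is non-decreasing on random fixtures", {
  for (seed in 1:5) {
    panel <- small_sim_panel(seed = seed, ld = 0.6, n_samples = 40, n_snps = 3, missing_rate = 0.05)
    hs <- em_fit(panel$genotypes, panel$labels)
    expect_true(all(diff(hs$ll_trace) > -1e-9))
    expect_equal(sum(tidy(hs)$freq), 1, tolerance = 1e-9)
  }
})

test_that("EM errors on an impossible genotype/label combination", {
  geno <- matrix(c(0L, 2L), ncol = 1)
  rownames(geno) <- c("okA", "corrupt")
  labels <- cn_labels(c("okA", "corrupt"), c(1L, 1L), c(1L, 1L))
  # both samples fine; now corrupt the label range so nothing is compatible
  expect_error(
    em_fit(geno, cn_labels(c("okA", "corrupt"), c(3L, 3L), c(3L, 3L)),
      cn_range = 0:2
    ),
    "okA"
  )
})

test_that("posterior matches the worked conditional-probability example", {
  # haplotypes ([0],CN1):0.6, ([1],CN1):0.3, ([1],CN0):0.1; genotype het:
  # (1,1) score 2*0.6*0.3 = 0.36, (0,1) score 2*0.6*0.1 = 0.12 -> 0.75/0.25
  hs <- structure(
    list(
      snp_ids = "s1", H = matrix(c(0L, 1L, 1L), ncol = 1),
      cn = c(1L, 1L, 0L), freq = c(0.6, 0.3, 0.1)
    ),
    class = "hap_set"
  )
  post <- posterior_cn(hs, 1L)
  expect_equal(unname(post["1/1"]), 0.75)
  expect_equal(unname(post["0/1"]), 0.25)

  # single haplotype: its CN pair with probability 1
  hs1 <- structure(
    list(snp_ids = "s1", H = matrix(1L), cn = 2L, freq = 1),
    class = "hap_set"
  )
  expect_equal(unname(posterior_cn(hs1, 2L)["2/2"]), 1)
  # incompatible genotype: undefined distribution (abstention)
  p0 <- posterior_cn(hs1, 0L)
  expect_length(p0, 0)
  expect_true(attr(p0, "undefined"))
})

test_that("all-missing genotype yields the frequency-implied CN-pair prior", {
  set.seed(11)
  hs <- random_hapset(3, 5, cn_range = 0:2)
  post <- posterior_cn(hs, rep(NA_integer_, 3))
  # direct computation from CN-allele marginal frequencies
  marg <- tapply(hs$freq, hs$cn, sum)
  expected <- numeric(0)
  cns <- as.integer(names(marg))
  for (a in seq_along(cns)) {
    for (b in seq_along(cns)) {
      key <- cnbag:::cn_pair_key(cns[a], cns[b])
      prev <- if (key %in% names(expected)) expected[[key]] else 0
      expected[key] <- prev + marg[[a]] * marg[[b]]
    }
  }
  expect_equal(post[names(expected)], expected[names(post)], tolerance = 1e-12)
})

test_that("posterior equals brute-force pair enumeration on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    hs <- random_hapset(sample(1:4, 1), sample(2:6, 1))
    g <- sample(c(0:2, NA), ncol(hs$H), replace = TRUE)
    mine <- posterior_cn(hs, g)
    oracle <- brute_posterior(hs$H, hs$cn, hs$freq, g)
    if (is.null(oracle)) {
      expect_length(mine, 0)
    } else {
      expect_equal(mine[sort(names(oracle))], oracle[sort(names(oracle))],
        tolerance = 1e-10
      )
    }
  }
})

test_that("posterior is invariant to haplotype order and constant SNPs", {
  set.seed(5)
  hs <- random_hapset(3, 6, cn_range = 0:2)
  g <- c(1L, NA, 2L)
  base <- posterior_cn(hs, g)
  perm <- sample(length(hs$freq))
  hs_p <- hs
  hs_p$H <- hs$H[perm, , drop = FALSE]
  hs_p$cn <- hs$cn[perm]
  hs_p$freq <- hs$freq[perm]
  expect_equal(posterior_cn(hs_p, g), base, tolerance = 1e-12)

  # appending a SNP constant across all haplotypes changes nothing
  hs_c <- hs
  hs_c$H <- cbind(hs$H, 1L)
  hs_c$snp_ids <- c(hs$snp_ids, "const")
  expect_equal(posterior_cn(hs_c, c(g, 2L)), base, tolerance = 1e-12)
})

test_that("EM attains the brute-force simplex-grid likelihood maximum", {
  # small panel built from 4 founder haplotypes so the compatible-haplotype
  # union stays low-dimensional enough for a coarse grid search
  cfg <- sim_config(
    n_haplotype_pool = 4L, n_samples = 30L, n_snps = 3L,
    cn_allele_freqs = c("0" = 0.3, "1" = 0.7), ld_strength = 0.9,
    rng_seed = 21L
  )
  panel <- simulate_panel(simulate_pool(cfg))
  geno <- unclass(panel$genotypes)[, ]
  hs <- em_fit(geno, panel$labels, cn_range = 0:1, prune_freq = 0)
  d <- length(hs$freq)
  expect_lte(d, 12)
  steps <- 6L
  grid <- compositions(steps, d) / steps
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    if (any(grid[r, ] == 0)) next
    ll <- brute_loglik(hs$H, hs$cn, grid[r, ], geno, panel$labels)
    if (ll > best) best <- ll
  }
  expect_gte(hs$log_lik, best - 1e-4)
  # and the EM solution's likelihood recomputed independently agrees
  expect_equal(
    brute_loglik(hs$H, hs$cn, hs$freq, geno, panel$labels),
    hs$log_lik,
    tolerance = 1e-8
  )
})
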