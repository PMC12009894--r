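# cnbag

Copy-number (CN) genotype imputation from flanking SNPs with attribute
bagging.

Genes such as **LILRB3, LILRA6 and LILRA3** in the leukocyte receptor
complex (chr19q13.4) carry common copy-number variation — up to four gene
copies per haplotype — which SNP genotyping arrays cannot type directly.
`cnbag` imputes the diploid CN genotype (an unordered pair of per-haplotype
CN alleles) from ordinary biallelic SNPs flanking the gene, using a
reference panel in which CN genotypes are known (e.g. called from
whole-genome sequencing read depth).

The model is an ensemble of K classifiers built by **attribute bagging**:
each classifier is trained on a bootstrap sample of the panel, greedily
grows a SNP subset $S_k$ by out-of-bag (OOB) accuracy, and fits frequencies
of **extended haplotypes** — phased SNP allele vectors over $S_k$ augmented
with the CN allele — by EM from the unphased data. Under Hardy–Weinberg
pairing, the posterior probability of CN genotype $\{c_1,c_2\}$ given a
genotype vector $g$ is

$$P(\{c_1,c_2\}\mid g)\ \propto \sum_{(h_1,h_2)\sim g,\ \{c(h_1),c(h_2)\}=\{c_1,c_2\}} f(h_1)\,f(h_2),$$

classifier posteriors are averaged, and the best pair is reported when its
aggregated probability reaches the call threshold (CT, default 0.5).
See `vignette("cn-imputation")` for the full model, numerical choices and
limitations.

## Worked example

```r
library(cnbag)

# a synthetic reference panel: 400 samples, 30 SNPs around a chr19-like
# gene center, skewed CN-allele frequencies, strong SNP-CN linkage
cfg   <- sim_config(ld_strength = 0.95, rng_seed = 1)
pool  <- simulate_pool(cfg)
panel <- simulate_panel(pool)

# QC (drops low-MAF / low-call-rate / HWE-failing SNPs), then train a
# 25-classifier model
qc    <- snp_qc(panel$genotypes)
model <- cnbag(qc$genotypes, panel$labels,
               gene = "LILRA6", chrom = "19",
               center = cfg$gene_center_bp, window_kb = 100,
               K = 25, seed = 1)
glance(model)
#> # A tibble: 1 x 7
#>   gene   n_classifiers n_snps_universe mean_snps_per_classifier mean_oob_accuracy cn_min cn_max
#>   <chr>          <int>           <int>                    <dbl>             <dbl>  <int>  <int>
#> 1 LILRA6            25              18                     3.96             0.992      0      4

# out-of-bag internal validation: each sample scored only by classifiers
# that held it out
val <- internal_validation(qc$genotypes, panel$labels, model = model)
val
#> <cn_validation> oob mode, n = 400: CN-pair accuracy 0.9975, total-CN accuracy 0.9975

# impute a target dataset (here: the panel itself) at the default CT
calls <- predict(model, panel$genotypes, ct = 0.5)
dplyr::count(calls, cn1, cn2, called)
#> # A tibble: 5 x 4
#>     cn1   cn2 called     n
#>   <int> <int> <lgl>  <int>
#> 1     0     1 TRUE      14
#> 2     0     2 TRUE       2
#> 3     1     1 TRUE     345
#> 4     1     2 TRUE      33
#> 5     1     3 TRUE       6
```

`glance()` summarizes the ensemble (18 SNPs survive QC; 25 classifiers
averaging ~4 SNPs each, mean OOB accuracy 0.992); the validation object
reports the fraction of panel samples whose imputed unordered CN pair
matches the truth (0.9975 here); `calls` holds one row per target sample with the imputed pair, its
aggregated posterior probability, and whether it cleared the call
threshold. `ct_sweep()` and `window_sweep()` reproduce the call-threshold
and flanking-window evaluation harnesses, with `autoplot()` methods for
both.

A command-line interface wraps the same functions
(`exec/cnbag simulate|qc|build|predict|evaluate|sweep-window|sweep-ct`);
models serialize to versioned JSON that round-trips predictions bit for
bit.

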