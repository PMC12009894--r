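---
title: "Imputing copy-number genotypes from flanking SNPs with attribute bagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing copy-number genotypes from flanking SNPs with attribute bagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Several genes in the leukocyte receptor complex on chromosome 19q13.4 —
LILRB3, LILRA6 and LILRA3 are the prominent examples — segregate as
copy-number variants: a haplotype may carry zero, one or several copies of
the gene (up to four per haplotype for LILRA6). Standard SNP genotyping
arrays cannot type these genes directly: probes inside a copy-variable
segment do not cluster cleanly, so arrays carry few or no usable markers in
the gene itself. What arrays do measure well are the ordinary biallelic SNPs
in the flanking sequence, and because the CN alleles arose on particular
haplotype backgrounds, those flanking SNPs are in linkage disequilibrium
(LD) with the CN allele. `cnbag` exploits this: given a reference panel of
individuals with known CN genotypes (e.g. called from whole-genome
sequencing read depth) and SNP genotypes, it learns the joint
haplotype structure of flanking SNPs and CN alleles, and then imputes CN
genotypes for array-typed individuals who lack sequencing.

## The model

### Extended haplotypes

The unit of modeling is the *extended haplotype*: a phased allele vector
over a subset $S$ of flanking SNPs, augmented with the CN allele $c$ of the
gene, treated as one extra multiallelic locus. Write $f(h)$ for the
population frequency of extended haplotype $h$. Under Hardy–Weinberg
equilibrium (random pairing of haplotypes), the probability of an
individual's observed data — an unphased genotype vector $g$ over $S$ plus a
CN genotype — is

$$ P(g, \text{cn}) \;=\; \sum_{(h_1, h_2)\,\sim\,(g, \text{cn})} f(h_1)\, f(h_2), $$

the sum running over ordered haplotype pairs whose allele vectors add to
$g$ at every observed SNP and whose CN alleles reproduce the CN genotype —
as an unordered pair $(c_1, c_2)$ when the per-haplotype decomposition is
known, or as the diploid total when only the total CN is known. Missing
genotypes are marginalized (the site is unconstrained), never imputed.

Frequencies are estimated by EM from the unphased reference data
(`em_fit()`): the E-step distributes each individual's mass over its
compatible ordered pairs in proportion to $f(h_1) f(h_2)$; the M-step
re-estimates $f$ from the expected haplotype counts. The observed-data
log-likelihood is non-decreasing at every iteration — the fitted object
keeps the full trace (`$ll_trace`) and the tests assert it. Prediction
inverts the same model: for a new genotype $g$,

$$ P(\{c_1, c_2\} \mid g) \;\propto \sum_{(h_1,h_2)\,\sim\,g,\; \{c(h_1), c(h_2)\} = \{c_1,c_2\}} f(h_1)\, f(h_2), $$

computed by `posterior_cn()`. When no compatible pair exists the
distribution is undefined and the classifier abstains.

### Attribute bagging

A single EM fit over all flanking SNPs would be both statistically fragile
(hundreds of rare haplotypes, phase ambiguity) and combinatorially
explosive. Instead the model is an ensemble of $K$ weak classifiers
(default 25), built by attribute bagging — bootstrap aggregation over
samples combined with random subsetting over features:

1. **Bootstrap** (`bootstrap_split()`): classifier $k$ draws $N$ samples
   with replacement; the $\approx (1-1/N)^N \approx 37\%$ of samples never
   drawn form its out-of-bag (OOB) set, an internal validation set that
   costs nothing.
2. **Greedy SNP-subset growth** (`train_classifier()`): starting from the
   best single SNP among `mtry` randomly drawn candidates (default
   $\lceil\sqrt{P}\rceil$), the subset grows by repeatedly drawing `mtry`
   unused candidates, refitting the in-bag EM with each tentative addition,
   and accepting the best one only if it strictly improves the count of
   correctly imputed OOB samples. One failed round may be retried
   ("patience"), then growth stops; `max_snps` (default 25) caps the
   subset. Ties are broken by higher in-bag log-likelihood, then lower SNP
   index, so builds are exactly reproducible.
3. **Aggregation** (`predict()`): the ensemble posterior is the plain
   arithmetic mean of the per-classifier posteriors — no accuracy
   weighting — renormalized over the CN pairs seen. The call is the CN pair
   with the highest aggregated probability.

### Call threshold

The aggregated probability of the best pair is the confidence of the call.
A sample is reported only when it reaches the call threshold (CT, default
0.5); `ct_sweep()` tabulates the call-rate/accuracy trade-off over a CT
grid, and the default grid and threshold reflect the usual operating point
where the threshold removes low-quality calls without materially cutting
the call rate. Exact probability ties break toward the lexicographically
smallest CN pair. No-calls are data, not errors.

## Quality control and SNP matching

`snp_qc()` applies the standard array filters before training: a SNP is
removed when its minor allele frequency is ≤ 0.05, its call rate is ≤ 0.95,
or its exact Hardy–Weinberg p-value is < 1e-5. The HWE test
(`hwe_exact_test()`) enumerates all heterozygote counts compatible with the
observed allele counts and sums the probabilities no larger than the
observed configuration's — exact at the extreme cutoff, with no mid-p
adjustment and no asymptotic approximation. `select_flanking()` keeps SNPs
in the closed interval `center ± window_kb`; coordinates are 1-based
(PLINK/VCF convention). SNPs inside the gene body are *not* excluded by
default — the window is measured from the gene center and typically covers
the gene — but an explicit `gene_body` interval can be excluded for
workflows that only trust markers outside the copy-variable segment.

At prediction time `match_snps()` aligns the target dataset onto the
model's SNP universe: by `snp_id`, falling back to chromosome + position;
alleles are reconciled directly, by swap (genotypes recoded $2-g$), or by
strand flip. Palindromic A/T and C/G SNPs cannot be oriented and are
dropped unless `keep_palindromic = TRUE` asserts same-strand data. Model
SNPs absent from the target become missing columns and are marginalized by
the posterior; a classifier with no matched SNP abstains.

## Numerical choices

* **EM initialization.** Standalone `em_fit()` initializes uniformly over
  the union of haplotypes compatible with at least one individual — the
  likelihood has no support outside that union, so nothing is lost — with a
  guard on per-individual configuration counts.
* **Incremental refits during growth.** Re-deriving that union at every
  tentative SNP addition would be exponential in per-individual
  heterozygous-plus-missing sites. The grower instead expands the current
  *pruned* haplotype set by the new SNP (each haplotype splits in two, with
  frequencies divided by the in-bag allele frequency), runs EM, and prunes
  again — the standard state-space control for haplotype-ensemble
  imputation. Pruning removes haplotypes below `1/(4 N_{inbag})` after
  convergence and renormalizes.
* **Convergence.** `|Δ log-lik| < 1e-6` or 200 iterations; both
  configurable, both recorded in the model file.
* **Determinism.** Every random draw flows from one master seed through a
  documented integer mixing function (`derive_seed()`); per-classifier
  seeds, bootstrap redraws (an empty OOB set triggers a reseeded redraw,
  at most 10) and candidate draws are all derived, so a model build is a
  pure function of (data, parameters, seed).
* **Serialization.** Model JSON stores frequencies and accuracies as
  17-significant-digit decimal strings; plain JSON number emission loses
  the last ~2 bits and can perturb posterior ties, so the round trip is
  specified — and tested — to reproduce predictions bit for bit.

## The synthetic panel generator

`sim_config()` / `simulate_pool()` / `simulate_panel()` generate the panels
used throughout the tests, so nothing external is needed. Each CN allele
gets a "core" SNP haplotype; a founder haplotype copies its core allele at
each SNP with probability `ld_strength`, otherwise draws from the SNP's
background frequency. Panels pair founders at random (HWE), so the
generator matches the model's own pairing assumption — deliberately:
recovery tests then measure estimation quality, not model mismatch.
Designated *tag SNPs* are indicator markers of one CN allele each
(assigned round-robin), i.e. r² = 1 tags.

Default study conditions, fixed once: 400 diploid samples, 30 SNPs across
±100 kb of a chr19-like center, CN-allele frequencies
{1: 0.926, 2: 0.051, 0: 0.019, 3: 0.004} — the strongly skewed shape
typical of a CN-variable LILR gene in an East-Asian panel — LD strength
0.9, no missingness. The founder pool holds 2000 haplotypes: large relative
to the rarest CN allele (1/0.004 = 250), so the pool realizes the
configured frequencies instead of quantizing them away. SNP positions are
uniform over the region; tag positions are explicit so the window-sweep
fixtures can place all informative markers inside a chosen radius.
Simulated allele pairs are drawn from the non-palindromic pairs only, so a
simulated panel survives strand-aware model/target matching intact
(palindromic-SNP handling is exercised by dedicated fixtures instead).

What the generator does *not* emulate: genotyping error, batch effects,
population structure/admixture, inbreeding (non-HWE pairing), recombination
gradients with distance, and array-specific marker ascertainment. Passing
recovery tests therefore demonstrate correctness of the estimator under its
own assumptions, not field performance on any particular array.

## Validation harnesses and the problem sizes used

`internal_validation()` offers two modes. OOB mode (default): one model on
the full panel, each sample scored only by classifiers holding it out —
with $K = 25$ a sample is scored by ~9 classifiers and the chance of a
never-scored sample is $(1 - e^{-1})^{25} \approx 10^{-5}$. A sample that
no classifier held out carries no information about the model, so it is
excluded from the accuracy denominator and reported in `n_unscored`
(this only matters at small $K$, where ~$(1-e^{-1})^K$ of samples are
affected). K-fold mode:
stratified by CN genotype, falling back to unstratified (with a warning)
when a class is a singleton. Accuracy is matched unordered CN pairs;
total-CN accuracy and a total-CN confusion table (fed to
`class_metrics()` for per-class SEN/SPE/PPV/NPV) come along.

The test-suite study sizes, chosen to exercise the statistics at desk
scale: recovery and LD-ladder runs use the default 400-sample/30-SNP panel
with $K = 25$ over five seeds; the flanking-window sweep uses 40–60 SNPs
with $K = 8$; EM-versus-grid comparisons use 30 samples and 3 SNPs so a
coarse simplex grid (step 1/6) is an exhaustive oracle; unit fixtures are
smaller still.

## Known limitations

* A CN allele realized as a *single* carrier in the panel cannot be
  validated out-of-bag: every classifier holding that sample out never saw
  the allele. With the skewed default frequencies this caps OOB validation
  accuracy below 1 on unlucky draws — a property of the design, not a
  defect of the estimator.
* Greedy growth only adds SNPs (no deletion or backtracking), and with
  weak LD it stops early by design; under the default skewed CN
  distribution, LD strengths below ~0.5 are indistinguishable from no
  linkage and predictions collapse to the modal CN pair.
* The likelihood assumes HWE within the reference panel; strong inbreeding
  or structure violates it.
* Palindromic SNPs are dropped by default at matching time; opting in to
  `keep_palindromic` is only safe when model and target are known to share
  strand conventions.
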