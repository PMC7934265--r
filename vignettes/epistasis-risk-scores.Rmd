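---
title: "Pairwise epistasis screening and epistasis risk scores: methods"
author: "episcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise epistasis screening and epistasis risk scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcore)
```

# Scope and data model

`episcore` analyses biallelic genotypes for a binary disease phenotype.
The central container, `GenotypeData`, extends `SummarizedExperiment`:
SNPs are rows, samples are columns, the `calls` assay holds minor-allele
counts (0/1/2, `NA` = missing), `rowData` carries SNP metadata
(identifier, chromosome, 1-based position, counted and other allele) and
`colData` carries the phenotype and covariates (status, sex, age, batch,
onset age, censoring flag, principal components). Positions are taken on
a single stated genome build; no coordinate lifting is performed. The
minor allele is defined per dataset, with ties at frequency 0.5 broken
lexicographically by allele.

# Quality control

Filters run samples first, then SNPs, and are idempotent.

* **Samples** are removed when their genotype missing rate exceeds 0.2 or
  their heterozygosity rate (heterozygous calls / non-missing calls) lies
  more than 3 SD from the mean rate. If the SD is zero the z-score is
  undefined and nobody is removed on that rule.
* **SNPs** are removed when the missing rate exceeds 0.1, the minor-allele
  frequency is below 0.05, or the Hardy-Weinberg exact test gives
  p < 1e-6. The exact test conditions on the allele counts and sums the
  probabilities of all heterozygote counts no more probable than the one
  observed. We compute it on controls only by default — disease-associated
  SNPs deviate from HWE in cases by construction, and filtering on
  all samples would preferentially discard signal — with a flag to use
  everyone.
* **Annotation selection** keeps SNPs with a deleteriousness score of at
  least 15 lying within 5 kb of a protein-coding gene, the pre-filter
  that makes an exhaustive pairwise scan tractable and biases it toward
  plausibly functional variants. Imputation-quality masking is expected
  to arrive as missing calls in the input; imputation itself is out of
  scope.

Linkage disequilibrium between two SNPs is the squared Pearson
correlation of their dosages over pairwise-complete samples (composite
LD; no phasing). We compute it on all samples rather than cases or
controls alone — the quantity gates redundancy of *pairs*, not
association, so the larger sample is preferable. Principal components
come from the mean-imputed, unit-standardized genotype matrix; each
axis's sign is fixed so its largest-magnitude loading is positive,
making coordinates reproducible across runs.

# The three interaction tests

Every SNP pair is summarized by its 3×3×2 joint-genotype-by-status
table, counted over pairwise-complete samples. Counting is implemented
as three 64-bit bit-planes per SNP (one per genotype class) and case and
control masks; each of the 18 cells is the popcount of a three-way
conjunction, and this is required to agree exactly with a naive tally
(it is tested to).

A pair enters testing only if all 18 cells hold at least `min_cell = 3`
observations. This cell filter is the package's main defence against the
sparse-cell false positives that plague epistasis scans; its statistical
side effect is discussed below.

* **Logistic interaction (1 df).** logit P(case) = β0 + β1 g_a + β2 g_b +
  β3 g_a g_b with additive dosage coding; the LRT for β3. The 18 cell
  counts are sufficient for this model, so the fit is a small weighted
  Newton iteration per table rather than a per-sample regression. An
  allelic-coding dialect exists in other tools; we fix additive coding
  and document it rather than flag-switch the statistic.
* **BOOST (4 df).** 2(ℓ_sat − ℓ_hom), where ℓ_hom is the
  homogeneous-association log-linear model (all two-way margins, no
  three-way term) maximized by iterative proportional fitting to a cell
  tolerance of 1e-8 (at most 10^4 sweeps; non-convergence is an error
  that echoes the table, and never occurred in 10^5 random tables). The
  screening approximation sometimes used upstream of this statistic is
  treated as an optimization only; every reported p comes from the full
  statistic.
* **Joint effects (4 df).** In cases and controls separately, the four
  log odds ratios λ_ab of the 2×2 subtables anchored at genotype cell
  (0,0), a,b ∈ {1,2}; the statistic is (λ_case − λ_ctrl)ᵀ V⁻¹ (λ_case −
  λ_ctrl) with V the delta-method covariance (Poisson cell variances,
  shared-cell covariances), the case and control contributions summed.
  The literature's exact variance-correction constants live in the
  original reference; we fix the delta-method form as the package's
  definition. With the default cell filter all anchored cells are
  positive; below `min_cell = 3` a Haldane-Anscombe +0.5 option exists.

Screening applies no covariates — this matches common practice for these
table-based statistics and keeps them functions of the 18 counts — and
confounding is addressed afterwards by an 8-df genotypic LRT (indicator
terms for the joint-genotype cells, reference (0,0)) adjusted for sex,
age, batch and the leading principal components; empty cells collapse
out with the df reduced accordingly.

Multiple testing uses Benjamini-Hochberg over the pooled family of all
valid (pair, method) tests — tests removed by the cell filter are not
part of the family — with a per-method option. Pairs with LD r² > 0.2
are pruned as redundant. Ties in p are reported stably by (snp_a,
snp_b, method). The main-effect scan is a covariate-adjusted logistic
Wald test per SNP, with genomic inflation reported as median χ²/0.456.

## Calibration and the cell filter

All three tests are asymptotically χ² and, on well-filled tables, their
empirical type-I error at α = 0.05 sits within Monte-Carlo error of
nominal (e.g. 0.050/0.055/0.051 at n = 2000 with MAFs in 0.3–0.5). When
the MAF range reaches down to 0.05 at n = 2000, however, the pairs that
survive the cell filter have their smallest cells near the threshold of
3, and two things happen: the χ² approximation is stressed, and —
more importantly — conditioning on the filter truncates precisely those
tables whose sparse-cell fluctuations would have produced large
statistics. The surviving tests are therefore mildly *conservative*
(empirical α ≈ 0.040–0.047 at nominal 0.05, joint-effects lowest), never
anti-conservative. Type-I error is controlled in every regime we
simulated; users should simply not interpret the nominal α as exact at
the sparse end of the filter. At larger n the effect disappears.

# Risk scores

For each selected interaction, the **effect table** assigns cell k the
effect E_k = ln OR of the 2×2 table (cases in k, controls in k) vs
(cases elsewhere, controls elsewhere). Cell-vs-rest is the package
default — it keeps every cell's effect estimable after the cell filter —
with cell-vs-reference-(0,0) as an option. A cell is labelled
**high-risk** when its case:control ratio exceeds the table's overall
ratio (the standard MDR threshold); cells with no members in the
training data are labelled low-risk.

Per sample j:

* **PRS_j** = Σ_i G_ij E_i / N_j over weight SNPs, where G_ij counts the
  effect allele (resolved against the dataset's counted/other alleles;
  unresolvable weights are skipped with a warning) and N_j counts the
  weight SNPs observed for j. The per-sample denominator makes scores
  comparable under missingness.
* **ERS_j** = Σ_i E_i[cell_ij] / N_j over interactions: each sample
  contributes exactly one cell per interaction, and interactions with
  either genotype missing drop out of that sample's N_j. Effect tables
  must be trained on data disjoint from the scored samples; scoring a
  sample depends only on its own genotypes and the frozen tables, so
  there is no test-set leakage. Interactions are de-duplicated by
  unordered pair identity. Interaction sets are assembled by p-value
  tiers (1e-7, 1e-6, 1e-5 by default).
* **CRS_j** = w PRS_j + (1−w) ERS_j. The weight w is chosen by grid
  search (step 0.01) maximizing AUC on a *selection* dataset distinct
  from the evaluation dataset; ties take the smallest w. Note w weights
  raw scores, not standardized ones, so an interior w need not mean the
  two scores contribute equally — scale rides along.

**Permutation selection.** Each candidate interaction trains an MDR
model on the training data and predicts status in every test dataset;
the metric is balanced accuracy (the sources cite no specific metric;
balanced accuracy is insensitive to case:control imbalance). The null
distribution permutes the prediction vector against the fixed labels.
Because a permuted binary prediction enters the confusion table only
through the number of predicted positives that land on cases, the
permuted metric is drawn directly from that count's hypergeometric
distribution — an exact, O(1)-per-draw realization of the permutation
null, not an approximation to it. The p-value uses the add-one estimator
(1 + #{null ≥ observed})/(1 + n_perm), so a perfect predictor attains
1/(n_perm + 1) and p = 0 is impossible. An interaction is selected when
p < α in *every* test dataset; for pure noise and two independent test
sets the selection rate is ≈ α².

# Survival and ROC evaluation

Samples are split into q near-equal groups by score rank (default
q = 4), ties broken by stable input order, group sizes differing by at
most one — rank-based rather than interpolated quantiles, so the split
is well defined under heavy ties. Age at onset is analysed by the
product-limit estimator with right censoring at the last record;
groups are compared by the k-group log-rank test. Discrimination is the
Mann-Whitney AUC (ties counted ½), which is invariant to monotone score
transforms. Cohort-level comparisons use the two-sided Fisher exact test
(p = sum of hypergeometric masses ≤ observed) and two-sample t-tests
computed from (n, mean, SD) summaries — Welch by default, pooled as an
option, a choice that does not move any reported bound. Group summaries
pool as s² = [Σ(n_i−1)s_i² + Σ n_i(m_i − m̄)²]/(Σn_i − 1); note that
under this (n−1)-convention two equal groups with equal means pool to
slightly below the common SD.

# The synthetic-data generator

The generator emulates a case-control genotyping study: each SNP draws
a MAF uniformly from a configured range and genotypes independently per
sample in Hardy-Weinberg proportions; covariates (sex, age, batch) are
drawn from simple parametric families; the disease liability is
`baseline_logit` + covariate terms + Σ per-allele main effects + Σ
planted-pair terms, where a planted pair with penetrance table p
contributes logit p[g1, g2] − baseline_logit. Liability is therefore
logit-additive across pairs and main effects, matching the downstream
logistic analyses. Status is Bernoulli(inverse-logit(liability)). Age at
onset is `onset_base_age` plus an exponential waiting time whose rate
scales as exp(0.5·(liability − mean)); onsets beyond the last-record age
(uniform up to `onset_max_age`) and all controls are right-censored.
The cohorts emulated publish no generative onset model; the exponential
form is the simplest that makes onset decrease in risk with realistic
censoring. Missing calls are uniform at `missing_rate`, with
planted-pair SNPs exempt so effect recovery is unconfounded. One integer
seed fixes everything; the draw order (genotypes SNP-by-SNP, then
missingness, then covariates, status, onset, with the phenotype stream
reseeded at seed + 1) is part of the contract.

What the generator does **not** emulate: LD between non-planted SNPs
(each SNP is independent), family or cryptic relatedness, population
stratification (unless simulated deliberately as separated MAF sets),
imputation dosage uncertainty, genotyping batch artefacts. Tests passing
on this generator therefore demonstrate correctness of the statistics
and the pipeline's plumbing, not robustness to structure the generator
omits — in particular, on real data the LD-pruning and covariate steps
carry weight that synthetic data cannot exercise.

Default study conditions used by the shipped checks, chosen once as
realistic for a desk-scale replication of a cohort-style analysis:
screening recovery uses n = 4000 samples and 300 SNPs with two planted
interactions whose per-cell |log-OR| is ≈ 0.6 in a checkerboard pattern
(logit deviation ±0.6 by parity of g1 + g2) — the classic pure-epistasis
configuration with no marginal effect, so recovery is attributable to
the interaction statistics; null calibration uses 5000 filter-passing
pairs at n = 2000 with MAF ~ U(0.05, 0.5); risk-score combination uses
n = 3000 per dataset with twelve β = 0.25 main-effect SNPs (the PRS
signal) and one ±0.8 checkerboard pair (the ERS signal); permutation
selection uses n_perm = 1000 at these sizes, with 10000 the default for
real analyses.

# Numerical choices and degenerate inputs

IPF tolerance 1e-8 on cell changes; logistic Newton tolerance 1e-10 on
the step with a |β| > 50 separation guard; singular covariance or
non-convergence yields an absent p with a reason, never a silent drop.
Constant SNPs are flagged `"constant"` in the main-effect scan;
undefined LD keeps the pair with a warning; zero-margin Fisher tables
return p = 1 with a warning; all-tied scores still split into balanced
quantile groups with a warning; samples censored without a valid age are
excluded with a logged count. PLINK decoding errors name the byte
offset. The pipeline writes every stage's retained/removed counts into
`manifest.json`, and removed + retained equals the input count at every
stage by construction (and by test).

# Known limitations

* Only 2-way interactions; no k-way MDR or cross-validated MDR model
  selection.
* PRS and ERS combine only through the linear w-mixture; richer joint
  models of main effects and epistasis are out of scope.
* The joint-effects covariance uses the plain delta-method form, not the
  original reference's adjusted constants.
* Exhaustive screening is intended for annotation-reduced panels (10^2 to
  10^4 SNPs), not millions of SNPs; no distributed execution.
* Cox models, AUC-difference inference and calibration curves are not
  provided.
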