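---
title: "Multi-approach univariate GWAS: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-approach univariate GWAS: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasrank)
```

## The problem

In a case-control GWAS, "the" univariate association analysis is in fact a
family of analyses. The analyst chooses a method (logistic regression, a
contingency-table test, a machine-learning scorer), a genetic encoding of
the 0/1/2 alternate-allele count (additive, dominant, recessive,
codominant), and an implementation. Different choices are sensitive to
different genetic architectures: a logistic regression with additive
encoding has little power against a purely recessive locus at moderate
allele frequency, and none of the parametric encodings directly targets an
overdominant (heterozygote-risk) locus, which a one-locus MDR model finds
naturally. Running a single approach therefore risks systematic false
negatives for architectures that approach is blind to.

`gwasrank` operationalizes a multi-approach workflow: run a diverse suite
of per-SNP approaches, quantify how much their full SNP rankings actually
differ, cluster the approaches by ranking similarity, keep one
representative per cluster, and report the union of top-k SNP lists across
representatives, with per-SNP stability statistics.

## Per-SNP approaches

Every approach consumes the same genotype matrix (markers x samples,
alternate-allele counts, `NA` missing) and emits a full ranking of the SNP
universe (`rank_snps()`): rank 1 is the most associated SNP, ties are
broken by genomic order, and markers whose test failed (separation,
degenerate table, minimum-cell gate) are placed after all valid markers
rather than dropped, so that any two rankings are always comparable over
the same universe.

* **Logistic regression** (`logistic_test()`): IRLS maximum likelihood of
  case status on the encoded genotype, optionally adjusted for covariates
  (age, principal components). Wald p-value for one-column encodings, a
  2-df likelihood-ratio test for the codominant (Het/Hom dummy) encoding.
  Non-convergence or `|beta| > 15` (separation) flags the marker.
  Convergence tolerance is 1e-12 on the deviance change (max 25
  iterations); at looser tolerances the fitted coefficient visibly departs
  from the closed-form log odds ratio on saturated 2x2 problems.
* **Allelic tests** (`allelic_test()`): 1-df chi-square without continuity
  correction, or the two-sided Fisher exact test, on the 2x2 allele-count
  table.
* **Genotype-model tests**: Cochran-Armitage trend (`trend_test()`), 2-df
  genotypic chi-square (`genotypic_test()`), dominant/recessive collapsed
  1-df chi-square (`model_collapsed_test()`). These carry a minimum-cell
  gate (default 5, the convention of the standard GWAS toolkits): a tested
  table with any observed cell below the gate is flagged instead of fed to
  an asymptotic chi-square it would miscalibrate — at a MAF of 0.05 and 600
  samples the expected homozygous-alternate count is about 1.5, and the
  ungated recessive chi-square is visibly conservative under the null.
* **Best-model with permutation** (`model_best_perm()`): the observed
  statistic is the minimum p over {allelic, trend, genotypic, dominant,
  recessive}; its significance is calibrated by phenotype-label
  permutations with the estimator `(1 + b) / (1 + m)`, which is never
  exactly zero and is unbiased under exchangeability.
* **MDR balanced accuracy** (`mdr_1way()`): one-locus multifactor
  dimensionality reduction. A genotype is high-risk when its case:control
  ratio strictly exceeds the overall ratio (ties and unseen genotypes are
  low-risk, a deterministic and conservative default); balanced accuracy
  (sensitivity + specificity)/2 is averaged over stratified 10-fold CV.
  Being encoding-free, MDR adapts to overdominant loci: both homozygotes
  can be labeled high-risk while the heterozygote is not.
* **Entropy gain** (`entropy_gain()`): plug-in mutual information
  `H(Y) - H(Y|G)` in bits, with `0 log 0 = 0`.
* **Decision tree** (`decision_tree_score()`): a single-feature
  classification tree on the ternary genotype (at most two split points,
  0.5 and 1.5). Hyperparameters — impurity criterion in {gini, entropy}
  and minimum impurity decrease in {0, 0.1, ..., 0.5} — are selected by
  stratified 5-fold CV on a 75% training split, scored by the coefficient
  of determination of the 0/1 label predictions, and the selected model's
  r-squared on the held-out 25% is the SNP's score. The r-squared-on-labels
  reading of the quality measure is a documented choice: applied to a hard
  classifier it is an affine function of accuracy, so model selection is
  unaffected by it, but the emitted score scale is.
* **External imports** (`import_external_ranking()`): rankings computed by
  external mixed-model or liability-scale tools enter as TSV adapters and
  then behave like any internal approach. They are deliberately not
  reimplemented.

The default registry (`default_approach_registry()`) enumerates 25 named
(method, encoding, implementation) configurations, including two logistic
implementation variants, four basic-association variants (asymptotic,
Fisher, pointwise-permutation and max-T calibrated), the six genotype-model
entries, the three machine-learning scorers, and four external adapters.
The registry is data: approaches can be added, removed, or re-optioned per
study.

## Comparing rankings: Canberra location distances

For two rankings σ, τ of the same N SNPs the Canberra distance is
`sum |τ(s) − σ(s)| / (τ(s) + σ(s))`, which up-weights disagreement near the
top of the lists. The top-k variant truncates both ranks at `k + 1` before
summing, so SNPs deep in both lists contribute nothing; at `k = N` it
reduces exactly to the untruncated distance (asserted as a test property,
along with monotonicity in k and the metric axioms). Distances are
accumulated in marker-sorted order, so matrices are bit-reproducible.

Approaches are clustered from each per-k distance matrix with
average-linkage (UPGMA) hierarchical clustering; agreement between the
clusterings at different k is the cophenetic correlation (Pearson
correlation of the merge-height ultrametrics over all leaf pairs). The
workflow keeps the largest prefix of the ascending k grid whose clusterings
all agree pairwise at or above a threshold (default 0.97, overridable;
falls back to the smallest k with a warning when no prefix of two or more
qualifies), then forms a consensus.

**Consensus construction.** The least-squares ("euclidean") consensus of
several ultrametrics is approximated by averaging the input ultrametric
matrices elementwise and re-clustering the average with UPGMA. The
elementwise average is the exact least-squares consensus within the space
of symmetric matrices; projecting it back to an ultrametric via UPGMA is a
standard deterministic surrogate for iterative optimizers. We prefer it to
an iterative SUMT-style scheme because it is closed-form, order-invariant,
and reproducible to the bit.

Representatives are the cluster medoids (minimum summed within-cluster
consensus distance, ties by name); a config override can force any
hand-picked choice instead, since representative selection is
ultimately an analyst's judgment call.

## Union statistics and haplotype-block pruning

For the m representative rankings, the top-k union is the set of SNPs in
the top k of at least one representative; its size Σ_k lies in `[k, m k]`
— `k` under complete stability (identical top lists) and `m k` under
complete instability (pairwise disjoint top lists). `stability_fraction()`
reports `100 Σ_k / (m k)` by default; because the floor of that scale is
`100 / m` rather than 0, an alternative normalization
`100 (Σ_k − k) / ((m − 1) k)` is exposed as an option.

Each union SNP carries its extraction number (how many representatives
rank it in the top k) and average position (mean rank over those). To
reduce the union to independent signals, SNPs are grouped into haplotype
blocks and each block keeps its most stable member: highest extraction
number, then lowest average position, then best single rank, then smallest
coordinate (the last two tie-breaks are additions that make pruning a
total order).

Block inference (`infer_blocks()`) is a documented simplification of
confidence-interval-based block finders: two-locus haplotype frequencies
are estimated from unphased genotypes by EM (double-heterozygote
ambiguity resolved iteratively, tolerance 1e-9), `|D'|` is computed from
them, and blocks grow greedily while adjacent `|D'| >= 0.9` within a
200 kb span. Externally computed block definitions load verbatim from
`.blocks.det`-style files (`load_blocks()`) when fidelity to a specific
block finder matters.

## The synthetic-data generator

Controlled-access genotypes cannot ship with a package, so every stage is
validated against `simulate_gwas()`, which emulates the statistical
structure the workflow assumes:

* biallelic autosomal SNPs with MAF uniform in [0.05, 0.5] (the floor
  matches the MAF QC filter, so null markers survive QC);
* Hardy-Weinberg equilibrium by construction: each individual is the sum
  of two independently drawn haplotypes;
* block-wise LD from a Gaussian copula — per block, a latent AR(1) normal
  vector thresholded at the per-marker allele-frequency quantile. This
  gives directly controllable MAF and within-block correlation at desk
  scale, which is what the workflow needs; it does not reproduce
  coalescent genealogies, recombination hotspots, or realistic long-range
  LD decay, so passing tests speak to the machinery, not to any particular
  human LD landscape;
* a logistic liability phenotype: `logit P(case) = α + Σ β_j x_j + γ age`,
  with per-SNP planted effects under additive, dominant, recessive,
  heterozygote, or genotypic models (`β = log OR` on the model-specific
  indicator), an age-like covariate, and α tuned by root finding so the
  expected case fraction matches the target before exact case/control
  sampling from an oversampled pool;
* optional two-subpopulation structure (allele-frequency divergence) for
  exercising PCA covariates, and uniform missingness for exercising the
  QC filters.

Everything is a pure function of the seed: identical configurations
produce byte-identical PED/MAP/covariate/truth files.

**Calibration caveats at desk scale.** Test problem sizes are a few
hundred to two thousand samples. At 600 samples, SNPs near the 0.05 MAF
floor have ~1.5 expected homozygous-alternate carriers; asymptotic tests
of the recessive contrast are then genuinely conservative. The gated
model tests flag such markers; the logistic Wald test (which the standard
toolkits do not gate) is left faithful to its reference implementation,
and its null uniformity at small n and low MAF is accordingly marginal.

**Power-check design.** For the encoding-complementarity checks we plant
40 recessive SNPs of OR 2.5 at MAF ~0.3 among 1000 markers (n = 2000).
The per-SNP effect is strong enough that with only a handful of planted
SNPs *every* encoding recovers all of them in its top 50 and the
comparison degenerates to a tie; planting 40 keeps recall below
saturation so the recessive-encoding advantage (roughly 38/40 recovered
vs 25/40 for additive in our runs) is actually measurable. The same
consideration sets MAF near 0.5 in the heterozygote-model checks, where
the overdominant contrast is exactly orthogonal to allele count.

## QC and covariate construction

`apply_qc()` applies, in order: marker missingness (> 0.01 removed),
sample missingness (> 0.01), MAF (< 0.05), HWE exact test (p < 1e-5);
repeats that sequence once (removals at one step change the rates seen by
another); and finally removes markers with differential call rates
between cases and controls (two-sided Fisher exact, default floor 1e-5,
configurable because the reference recipe for this step lives outside the
toolkit). The HWE exact test is the conditional probability-ordering test,
computed by the mode-anchored two-term recurrence and verified against an
exhaustive enumeration oracle for every configuration with up to 50
genotypes.

`ld_prune()` mirrors the windowed pairwise-r² scheme (window 50 SNPs,
step 5, threshold 0.2; the lower-MAF member of an offending pair is
removed, equal MAFs drop the later coordinate — the reference tool's tie
rule is undocumented, so any fixed deterministic rule serves).
`pca_covariates()` standardizes markers by `2p` and `sqrt(2 p (1 − p))`,
mean-imputes missing calls (0 after centering, keeping the decomposition
well-defined), and returns eigenvalue-scaled sample eigenvectors.

## Problem sizes used by the checks

The shipped test-suite and acceptance script run, per invocation: the
full workflow twice on 1000 markers x 600 samples with six internal
approaches (determinism and artifact checks); twenty replicates of the
1000-marker / 2000-sample complementarity design; a 500-marker null
calibration; and the exhaustive statistical sweeps (HWE to 50 genotypes;
the saturated-logistic identity exhaustively to cell count 14 and on a
4000-table seeded sample across the 1..50 cell range, the full 50^4 grid
being out of proportion to what the identity check needs).

## Known limitations

* The codominant encoding is fit jointly (2-df LRT); per-dummy Wald
  p-values are not emitted.
* `plink.model.best.perm` computes pointwise (per-marker) empirical
  p-values; family-wise max-T calibration is available as the
  `plink.assoc.mperm` variant but not combined with best-model selection.
* Block inference is a |D'|-threshold simplification; use `load_blocks()`
  for fidelity to a specific block finder.
* The consensus is the averaged-ultrametric UPGMA surrogate, not an
  iterative least-squares optimizer; with strongly conflicting input
  clusterings the two can differ.
* X-chromosome markers, dosage/imputed genotypes, multi-allelic sites,
  relatedness pruning and sex checks are out of scope.
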