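---
title: "Methods: from multi-omics functional groups to causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-omics functional groups to causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hologuild)
```

`hologuild` implements a holo-omics inference chain for host-associated
microbiomes: it identifies the microbial *functional groups* (guilds) whose
transcripts, proteins, or metabolites separate efficient from inefficient
animals, and then asks whether a focal taxon *causes* the levels of those
molecules — and, through them, the host phenotype — using host genetics.
This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where the procedure was genuinely open.

## The synthetic cohort and what it emulates

Every stage of the chain can be exercised without external data through
`simulate_cohort()`, which draws a cohort with a known ground truth:

* **Genotypes.** `n_animals` (default 298) by `n_variants` (default 20,571)
  biallelic variants, minor-allele frequencies uniform on `maf_range`
  (default 0.05–0.5), allele counts Binomial(2, maf) centred to the
  −1/0/1 coding used by the association scan.
* **Causal chain.** A focal taxon's log-abundance is
  `sum(g_k alpha_k) + e`, with the `alpha` draws rescaled so the in-sample
  heritability equals `taxon_h2` (default 0.5, a moderately heritable
  taxon). A mediator (a protein or metabolite level) is
  `theta * taxon + noise` (default `theta = 0.5`), and the phenotype is
  `delta * mediator + gamma * taxon + noise` (defaults 0.4 and 0.2), so
  the true indirect effect is `theta * delta = 0.2`. Optional horizontal
  pleiotropy adds direct variant-to-mediator effects on a flagged subset of
  causal variants, which is what the MR-Egger intercept and the
  median/mode estimators are designed to detect and resist.
* **Genetic architecture.** The default is oligogenic
  (`n_causal_variants = 5`). The choice is a power argument: a taxon that
  yields many genome-wide-significant loci in a cohort of ~300 animals must
  have very large per-locus effects — if 28 equally contributing loci each
  had to reach a BH-adjusted p below 0.001 across ~20,000 tests, each would
  need roughly 12% of the trait variance, and 28 such loci would exceed
  100%. Concentrating a heritability of 0.5 in a handful of loci is the
  only architecture under which stringent genome-wide instrument selection
  has non-trivial power at this sample size; it typically yields one to
  four instruments at the adjusted threshold.
* **Feature layers.** Three log-normal abundance tables (transcripts,
  proteins, metabolites; defaults 300/400/150 features) over 18 samples.
  A feed-conversion-ratio (FCR) phenotype is drawn per sample and the
  efficient/inefficient labels assigned by median split (efficient = lower
  FCR), mirroring an extreme-group design of 9 vs 9 animals. Planted
  differential features (5–8% of each layer) are shifted by
  `planted_log2fc` (default 2) in the efficient group, half up and half
  down. The planted fraction is kept small deliberately: per-sample CPM
  normalization is compositional, and planting a large fraction of a layer
  visibly compresses the realized fold changes of everything else.
* **Functional redundancy.** Planted features are assigned round-robin to a
  small guild of species so that every ground-truth species is supported by
  at least two features. This mirrors the biology the package targets —
  multiple taxa carrying the same phenotype-linked function, and each taxon
  expressing it through several features — and it is also what makes
  species-level recovery a meaningful target: a guild inferred from a
  single feature would be hostage to single-test noise.
* **Missingness.** A fraction `dropout_prob` (default 0.05) of the layer's
  lowest-intensity cells is censored to zero, a detection-limit model of
  MS missingness. Absences therefore concentrate in low-abundance
  features, as in real intensity data, rather than striking uniformly.
* **Metabolite annotations.** Each metabolite carries an origin label
  (microbiota / host / co-metabolism / others, with proportions echoing a
  typical rumen metabolome origin split) and a spectral-match similarity
  score straddling 200. The origin table replaces an external
  database-driven origin classification with a user-suppliable lookup.

The distributional family of protein and metabolite intensities is an
assumption of this generator (log-normal), not an empirical finding; the
linear Gaussian scale for the taxon and mediators matches the linear
machinery (mixed-model GWAS, MR, OLS mediation) applied downstream.

What passing the synthetic checks does *not* show: the generator has no
compositional sequencing noise, no batch effects, no correlated feature
blocks beyond the planted guild structure, no population stratification or
relatedness structure beyond random mating, and mediators measured in the
same cohort as the genotypes (a real two-sample MR would draw exposure and
outcome summaries from different cohorts). Results on real rumen data will
be noisier in ways these tests cannot certify.

## Differential features and quartiles

Two-group testing uses the two-sided Wilcoxon rank-sum test per feature
(exact enumeration whenever both groups have at most 10 samples and no ties
occur — always the case at 9 vs 9 with continuous intensities — and the
tie-corrected normal approximation otherwise), with Benjamini–Hochberg
control across the layer (`alpha = 0.05` on adjusted p). Fold changes are
computed on group means of normalized abundance with a pseudo-count of half
the layer's smallest nonzero value, and reported as log2 efficient over
inefficient. Note the floor of the exact test: at 9 vs 9 the smallest
achievable two-sided p is 2/48620, so BH-adjusted significance requires
near-complete group separation — small planted effects are invisible at
this design size no matter the feature count.

Significant features are ranked by log2 fold change and cut at the
empirical 25/50/75 percentiles into quartiles Q1–Q4 (Q4 = most strongly up
in efficient animals); a value tied with a cut point goes to the lower
quartile, ties being resolved deterministically. Quartiling is skipped with
a warning below four significant features.

## Enrichment and the quartile z-matrix

Functional enrichment is the two-tailed Fisher exact test of the
differential set against all identified features, per category and per
vocabulary (COG letters, KEGG pathways, GO terms, protein domains), with
the common two-tail convention (total probability of tables no more likely
than the observed one) and BH adjustment within each vocabulary. The
quartile-wise clustering matrix keeps categories enriched at p < 0.05 in at
least one quartile, transforms p to `-log10(p)`, z-scores each category row
with the sample (n−1) standard deviation, and clusters rows and columns by
average-linkage hierarchical clustering on Euclidean distance. Rows with
zero variance are set to zero and flagged rather than dropped.

## Functional-group construction

Three builders, each a conjunction of strict filters:

* **Transcript-based (MTT):** mean CPM strictly above 5 in at least one
  group, BH-adjusted p < 0.05, up in efficient animals.
* **Protein-based (MTP):** differential proteins in quartiles Q3 and Q4.
* **Metabolite-based (MTB):** detected in strictly more than 50% of
  samples, similarity strictly above 200, significantly higher in efficient
  animals, Spearman-correlated with FCR (p < 0.05), and of microbiota or
  co-metabolism origin.

All threshold comparisons are strict (`>`), so a feature sitting exactly at
CPM 5, similarity 200, or 50% prevalence is excluded; "up in efficient" is
decided from the explicit sample label, never inferred from the direction
of an FCR coefficient. Surviving features are mapped
feature → species → family; the species set is the group. Group comparison
reports Venn-style intersection counts at species level, and per layer a
Bray–Curtis PERMANOVA on the member-feature submatrix with BH adjustment of
the three permutation p-values and the effect size `log2(pseudo-F / q)`
(the `q` here is that BH-adjusted permutation p, floored at the permutation
resolution `1/(n_perm + 1)` before division). Samples with a zero total
over the member features have no position in Bray–Curtis space and are
excluded from that layer's test.

## Community statistics

Shannon diversity uses the natural log; Chao1 is the classic
singleton/doubleton form `S_obs + F1^2 / (2 F2)` with the
`S_obs + F1 (F1 - 1) / 2` fallback when no doubletons exist (deliberately
not the +1-corrected variant most toolkits report, so that small worked
examples are exact). PERMANOVA decomposes squared Bray–Curtis distances,
permutes labels freely (999 permutations by default), and includes the
observed statistic in the null set so p is never zero; PERMDISP embeds the
samples by principal coordinates and permutation-tests the one-way F on
distances to group centroids. Both are computed with vegan (`adonis2`,
`betadisper` + `permutest`) behind this package's interface, seeded
explicitly for reproducibility.

## Mixed-model association scan

Each omics trait is scanned against every variant under
`y = mu + g b + u + e`, `u ~ N(0, K sigma_a2)`, with `K` the VanRaden
genomic relationship matrix built from the centred −1/0/1 coding. Variance
components are estimated once on the null model by REML — a single spectral
decomposition of `K` and a one-dimensional optimization of the profiled
criterion in `delta = sigma_e2 / sigma_a2` over `log(delta)` in ±12, with
the endpoints checked so boundary optima are honoured — and then reused for
every marker (the P3D strategy), reducing each marker test to a weighted
regression in the rotated basis with a Wald t test on n − 2 degrees of
freedom. With `sigma_a2 = 0` the scan reduces *exactly* to per-marker OLS,
which is the main correctness anchor of the implementation. Variant QC
removes low MAF (default 0.05), high missingness (default 0.1), and exact
Hardy–Weinberg p below 1e−6; these defaults are configuration values, not
claims about any particular study. A caveat that the acceptance report
surfaces deliberately: on an oligogenic trait at n ≈ 300 the GRM-REML
heritability is very noisy and can sit at the boundary; the estimator is
well behaved under the polygenic model it assumes (recovery within ±0.03 at
n = 2000 over 50 replicates).

## Two-sample Mendelian randomization

Instruments are variants associated with the exposure (BH-adjusted
p < 0.001 by default, after the microbes-vs-metabolites convention the
threshold is configurable to raw p), greedily LD-pruned in ascending p so
no retained pair has r² > 0.1. Harmonization aligns outcome effects to the
exposure's effect allele, sign-flipping swapped rows and dropping
palindromic variants whose allele frequency (≥ 0.42) cannot resolve the
strand. Five estimators are reported:

* **IVW**: fixed-effect inverse-variance meta-analysis of Wald ratios
  (equivalently, WLS of outcome on exposure effects through the origin),
  with multiplicative random-effect inflation of the SE when
  Cochran Q/(k−1) > 1.
* **MR-Egger**: weighted regression with a free intercept; the slope is
  the pleiotropy-adjusted estimate and the intercept tests directional
  pleiotropy (t on k − 2 df, residual SD floored at 1). Its nominal
  calibration presumes exposure effects measured essentially without error;
  with noticeable exposure-side noise the intercept test runs slightly hot,
  an estimator property the tests simulate around rather than hide.
* **Weighted median**: the 50% point of the inverse-variance-weighted
  empirical ratio distribution, linearly interpolated; consistent while
  valid instruments carry at least half the weight.
* **Simple and weighted mode**: the argmax of a normal-kernel density over
  the ratios, bandwidth = `bandwidth_factor` × the modified Silverman rule
  `0.9 min(sd, mad) k^(-1/5)`.

Median and mode standard errors come from a parametric bootstrap of the
per-variant effects (default 1000 resamples, seeded). Methods whose
instrument minimum (three) is not met are reported as flagged rows rather
than errors, so a single-instrument IVW (the Wald ratio) still yields a
report. At the default cohort scale the stringent adjusted threshold
typically leaves one to four instruments; the five-estimator properties are
therefore validated at the summary-statistic level (30 instruments), where
every estimator recovers a true effect of 0.3 within two standard errors,
IVW coverage is nominal, and the median/mode estimators beat IVW under 40%
invalid instruments. The pipeline falls back to raw-p selection (the
metabolite-exposure convention) only if no variant passes the adjusted
threshold, and records that it did so.

## Mediation

`fit_mediation()` decomposes the exposure→outcome effect with linear
no-interaction models: `m ~ x` gives `a`, `y ~ x + m` gives `b` and the
direct effect; ACME = `a·b`, ADE = the direct coefficient, and the total
effect from `y ~ x` equals their sum *exactly* (an OLS identity the tests
assert to 1e−10 on every input). Inference is a nonparametric
case-resampling bootstrap (default 1000 resamples, seeded) with two-sided
percentile p-values floored at `2/(n_boot + 1)`; the nonparametric choice
(over quasi-Bayesian draws) trades distributional assumptions for
determinism under a fixed seed. The proportion mediated is flagged
undefined when |total| < 1e−8.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → differential → enrichment → groups →
community → GWAS → MR → mediation from one flat configuration
(`pipeline_config()`, or YAML via `read_pipeline_config()`); every source
of randomness derives from the single cohort seed, all outputs are TSV/JSON
files with deterministic bytes, and the returned manifest carries MD5
digests of every file — two runs with one seed are byte-identical, which
the test suite asserts. `resume = TRUE` reuses existing simulation outputs
in the output directory.

## Problem sizes used by the checks

The test suite exercises the chain at sizes chosen to make each property
measurable while staying comfortable on a single core: exhaustive oracles
for Fisher (all margins ≤ 12) and the exact rank-sum test (all group sizes
≤ 6); PERMANOVA type-I error from 1000 label-permuted 18-sample data sets
at 999 permutations; GWAS calibration on one 300 × 20,000 polygenic-null
cohort and planted-variant ranking over 100 replicates at n = 1000;
REML recovery from 50 traits on a 2000-animal kinship; MR coverage over
500 replicates and robustness over 200; mediation calibration over 500
null replicates (n = 200, 499 bootstrap resamples each); and
functional-group recovery over 100 replicates of the 9 vs 9 design with
log2 fold change 2, where mean species-level recovery is required to reach
95%.

## Known limitations

Bray–Curtis is not a metric, so PERMDISP works in a principal-coordinate
embedding; the mixed model fits one variance-component pair per trait and
no covariates beyond the intercept; MR assumes linear effects and
homogeneous instruments apart from the modelled pleiotropy; mediation
assumes sequential ignorability, which no amount of bootstrap can test; and
the "two-sample" MR demonstration on the synthetic cohort reuses one cohort
for both scans, which real applications should not.
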