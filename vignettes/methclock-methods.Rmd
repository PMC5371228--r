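---
title: "Methods: an epigenetic clock pipeline for mouse liver methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an epigenetic clock pipeline for mouse liver methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methclock` implements, as a tested pipeline over a synthetic-cohort
generator, the standard analysis chain for DNA-methylation aging in mouse
liver: CpG filtering from bisulfite read counts, covariate-adjusted
age-association testing, a methylome disorder (entropy) statistic,
empirical-Bayes batch correction, an elastic-net age predictor
("epigenetic clock"), and the evaluation of lifespan-extending treatments
through the clock's predictions. This vignette records the models, the
parameters that matter, and the design choices that were genuinely open.

## The data model and the synthetic generator

All analyses act on a samples x sites matrix of methylation fractions
`MF = methylated reads / total reads`, with read counts retained where they
exist and 0-based site coordinates throughout. The generator
(`cohort_spec()`, `simulate_cohort()`) encodes the assumptions the
downstream statistics rely on:

* **Age drift linear in log2(age in days).** A planted age site follows
  `MF = baseline + slope * log2(effective_age_days)`, clamped to [0, 1].
  The clock regresses log2(age) on fractions, so this makes the linear
  model well-specified and recovery tests sharp. `slope_scale` (default
  0.04 fraction units per log2 day) sets the drift magnitude; half the
  drifting sites gain, half lose (`frac_gain = 0.5`, matching the roughly
  even gain/loss split reported for liver clocks).
* **Treatment slows the clock multiplicatively.** A treated animal's
  effective age is `treatment_rate * age_days` (default 0.55, in the range
  implied by reported reductions of ~10 months at 22 months). A
  multiplicative rate, rather than an additive offset, reproduces the
  observation that reductions grow with age.
* **Rising disorder.** All latent fractions contract toward 0.5 by
  `(effective_age / 7 days)^(-entropy_drift)` (default 0.05), so
  per-sample entropy over age-associated sites rises with age. A side
  effect worth knowing: this makes *every* site weakly age-dependent, so
  at a fixed FDR the age-associated set is typically larger than the
  planted drifting set. That is a property of the generator, not an FDR
  violation.
* **Batches after biology.** Per study/batch, observed values are
  `latent + location_shift + scale_factor * N(0, noise_sd)` - exactly the
  additive/multiplicative structure the batch corrector removes. Defaults
  emulate two RRBS batches and one WGBS batch with distinct shifts and
  noise scales.
* **Reads.** Depth is Poisson (`mean_depth = 20`), methylated reads are
  binomial in the distorted fraction; zero-depth cells and a
  `missing_rate` (default 5%) of random cells are missing. Fixing `seed`
  fixes every output bit.

What the generator does **not** emulate: spatial correlation along the
genome, bisulfite conversion error, beta-valued (non-Gaussian) noise,
cell-composition change with age, and nonlinear drift. Passing tests
therefore demonstrate correctness of the statistics and recovery under the
stated model, not performance on real RRBS data.

## Filtering profiles

Three profiles mirror common practice for RRBS site selection
(`filter_cross_species()`, `filter_clock()`, `project_relaxed()`):

* **Cross-species**: a cell is observed at >= 5 reads; keep sites missing
  in < 20% of samples pooled over >= 2 studies, uniquely mapped, autosomes
  1-19 only; then drop samples missing > 40% of kept sites; impute
  remaining holes with the site mean.
* **Clock**: observed at >= 2 reads; keep sites present in >= 97% of
  samples (inclusive threshold, consistent with the ">=" style of the
  other rules), autosomal, with observed-fraction sd in (0, 0.20]
  (n-1 denominator, computed before imputation); drop samples missing
  > 30%; mean-impute.
* **Relaxed**: restrict to a target site set, count any cell with >= 1
  read as observed, mean-impute. Used for single-timepoint cohorts so they
  maximally overlap the clock's sites.

Rules apply in a single pass in the stated order (site rules, sample rule,
imputation); the 97% presence rule is not iterated against the sample rule.
Imputation never moves a site's observed mean, and re-running a profile on
its own output is the identity. Note the interaction that matters in
practice: at 5% random missingness the 97% presence rule discards most
sites, which is realistic for RRBS but starves a 500-site toy cohort; the
treatment analyses therefore use the relaxed profile over all simulated
sites, while the strict profile is exercised on the wild-type cohort.

## Age association and entropy

`test_age_association()` fits, per site, ordinary least squares of the
fraction on covariates plus age and on covariates alone, and tests age with
the drop-one F statistic `F = (RSS_reduced - RSS_full) / (RSS_full /
(n - p_full))` against F(1, n - p_full). Categorical covariates are one-hot
encoded against a reference level; covariates constant in a cohort are
dropped with a message; rank deficiency is an error naming the collinear
columns. Benjamini-Hochberg q-values (via `p.adjust`) define the
age-associated set at 1% FDR. Replication (`replicate_associations()`)
re-tests only the primary-significant sites on pooled replication samples,
with BH applied within that subset - the within-subset choice follows the
workflow's "using the sites identified in the primary cohort" logic and is
the more conservative reading.

The age covariate enters untransformed by default (the plain "age" of a
covariate list); the analysis scripts pass `age_transform = "log2"` because
the generator drifts linearly in log age.

Entropy per sample over N age-associated sites is

    Entropy = 1 / (N * log(1/2)) * sum_i [ MF_i log MF_i + (1 - MF_i) log(1 - MF_i) ]

with terms at MF exactly 0 *or* 1 contributing zero (the published
convention states the 0 case; the limit at 1 is identical). The normalizer
cancels the logarithm base; values lie in [0, 1]; moving any fraction
toward 0.5 never decreases it. Its correlation with age is reported on
untransformed age in months (the axis convention for entropy plots), while
the clock works in log2 days.

## Batch correction

`fit_batch_model()` / `apply_batch_model()` implement the empirical-Bayes
location/scale adjustment: per site, a least-squares fit of batch means
plus covariates (age in log2 days, sex, treatment) standardizes the data
with the pooled variance; per-batch location (gamma) and scale (delta)
estimates are shrunk across sites and removed; the covariate-predicted
mean is restored. Two priors are available:

* **nonparametric** (default): each site's posterior expectation is the
  likelihood-weighted average of every other site's estimates - an exact
  summation over the empirical prior, with no Monte-Carlo randomness;
* **parametric**: normal / inverse-gamma priors with moment-matched
  hyperparameters, iterated to convergence; it serves as a fast
  cross-check, and the two modes agree to ~0.02 RMS on Gaussian data.

Two deliberate numerical choices. First, per-batch scale estimates use the
maximum-likelihood (1/n) variance rather than 1/(n-1): with that
convention, fitting on duplicated batches yields gamma = 0 and delta = 1
exactly and the adjustment of batch-free data is the identity, which is
the invariant the fit/apply contract promises (the n-1 convention leaves a
systematic n/(n-1) factor). Second, adjusted fractions are **not** clamped
to [0, 1] for modeling - clamping would bias the linear clock - and are
clamped only in exported per-site reports. The model object stores
everything needed for a frozen apply to new samples of known batches;
by default, train and evaluation data are adjusted with one joint fit.

`check_batch_removal()` quantifies success as the R-squared of each
leading principal component on the batch factor, before vs after.

## The clock

`train_clock()` minimizes the elastic-net objective
`(1/2n) * RSS + lambda * [alpha ||w||_1 + (1-alpha)/2 ||w||_2^2]`
(via glmnet) for log2(age in days) on methylation fractions. Samples are
shuffled once by the seed and split into contiguous blocks for k-fold CV
(default 4, unstratified). The grid spans alpha in {0.1, 0.3, 0.5, 0.7,
0.9, 1.0} and glmnet's auto-scaled 50-value lambda path per alpha.

Model selection minimizes mean held-out squared error. Held-out Pearson r -
the metric usually displayed per fold - is reported alongside, but it is
scale-invariant and therefore cannot distinguish shrinkage levels: selected
by r, the CV happily chooses a heavily shrunk model whose predictions are
compressed toward the mean training age, which destroys calibrated
downstream quantities (a 22-month control reads as ~10 months, and the
treated/control age ratio is biased toward 1). Squared-error selection is
also what the standard elastic-net CV implementations optimize. `"pearson"`
remains available as a configuration option.

Predictions are `2^(b + x'w)` days; months use 365.25/12 = 30.4375 days
throughout. `classify_direction()` labels sites gain/loss by the sign of
their correlation with log2 age (exact zeros reported as "flat" and
excluded from counts). `clock_site_enrichment()` tests selected vs
candidate sites per region after resolving multi-label sites by the
precedence enhancer > promoter > exon/intron/intergenic.
`permutation_control()` re-runs batch correction and training after
shuffling covariate rows within each study and ranks the real model's mean
absolute residual among the shuffles (the analysis scripts use 20
permutations; a full-scale control would use more).

## Treatment evaluation

`compare_treatments()` compares each treated group with untreated samples
of the same strain and age group: reduction = mean control minus mean
treated epigenetic age (months), Student's equal-variance two-sided t-test
by default (Welch via a flag; the underlying report only says "t-test",
and equal variances are the natural default for equal-design groups), and
a one-way ANOVA across the oldest age group. The recovered clock rate is
estimated as mean treated / mean control predicted age in days. Because a
regularized forward regression attenuates predictions toward the training
mean, this ratio is biased upward (toward 1); under the default study
conditions the bias stays within the 25% band around the planted rate.

`pca_clock_sites()` runs centered, unscaled PCA over the clock's sites;
PC1's sign is fixed to correlate positively with age (the SVD sign is
arbitrary) before regressing PC1 on age + treatment per genetic
background. `cluster_heatmap()` rescales each site to [0, 1] by min-max
(the plotting convention behind "standard scale"; z-scoring is available),
drops zero-range sites with a warning, and clusters samples by average
linkage on Euclidean distances; ties follow `hclust`'s deterministic
lower-index-first behavior, so results are invariant to input order up to
tie-breaks.

## Cross-species comparison

`build_ortholog_space()` consumes a precomputed coordinate-mapping table
(the output of a liftOver-style tool; chain arithmetic is out of scope)
and an array-probe manifest, intersecting lifted coordinates with probe
coordinates by exact equality (a `slop` window is available because probe
"intersection" could also be read as an interval overlap; the nearest
probe wins ties). Mouse sites sharing a probe are averaged per sample over
nonmissing members (`collapse_to_probes()`). Region enrichment uses the
sample odds ratio `ad/bc` with the two-sided Fisher exact p, one region at
a time so each site is counted once per test; overlap significance is the
upper-tail hypergeometric probability.

## Problem sizes and runtime

The test-suite and acceptance analyses run at deliberately compact sizes
chosen to keep the full suite in minutes while leaving each statistical
check well-powered: cohorts of 100-140 animals over 500 sites (100
drifting) for clock recovery and treatment evaluation across 20 seeds; 500
global-null replicates of 500 sites at n = 40 for FDR calibration; 100
seeds of 40 x 60 matrices for slope preservation under batch correction;
20 covariate shuffles for the permutation control. Exact expected values
(entropy anchors, F-tests, Fisher/hypergeometric p, BH q-values, filter
counts, linkage heights) are checked against independent brute-force
oracles written in the tests themselves.

## Known limitations

* Fractions are treated as Gaussian after imputation; no beta-binomial
  modeling of counts, no site-site correlation.
* Mean imputation shrinks per-site variance and can leak information
  across samples; the filters bound how much imputation occurs.
* The nonparametric prior costs O(sites^2) per batch; for very large site
  sets the parametric mode is the practical choice.
* The clock's predictions are attenuated toward the training mean age, as
  for any penalized forward regression; comparisons between groups remain
  valid, absolute ages are conservative at the extremes of the range.
* Synthetic results certify the machinery, not biology: effect sizes,
  missingness and batch structure are simplifications of real RRBS/WGBS
  cohorts.
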