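---
title: "Quantifying age-related gene expression heterogeneity across datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying age-related gene expression heterogeneity across datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agevar)
```

## The problem

Bulk transcriptome studies of the human brain show that expression *levels*
change with age. A separate question is whether the *spread* of expression
across individuals of the same age changes: stochastic genetic and epigenetic
damage would predict that individuals drift apart as they age, so
inter-individual heterogeneity should rise during aging but not necessarily
during postnatal development, when regulation is tight. Single datasets are
usually too small to detect such second-moment effects gene by gene, so the
package frames the question as a meta-analysis: score every gene in every
dataset, then ask whether weak per-dataset signals *agree* across many
datasets more often than a dependence-aware null allows.

A *dataset* here is one study x brain-region expression matrix (genes x
samples) with per-sample donor metadata. Datasets from one study share
donors across regions, which is the central statistical nuisance the
machinery is built around.

## Per-gene statistics

Each dataset is split at 20 years into development (`age < 20`) and aging
(`age >= 20`); the boundary age is assigned to aging so every sample has
exactly one period. For each gene in each dataset x period, expression is
regressed on the fourth root of age in days,

$$Y = \beta_0 + \beta_1\,\mathrm{age}^{1/4} + \varepsilon,$$

by ordinary least squares. The fourth-root scale spreads samples roughly
uniformly across the lifespan and makes the age trend approximately linear
in both periods; `transform_age()` also offers linear, square-root and log2
scales for sensitivity analyses, and the heterogeneity statistic below is
invariant to the choice because it is rank-based in age.

* **Expression change** is the slope $\beta_1$, with a two-sided t-test.
* **Heterogeneity change** is $\rho$, the Spearman correlation (mid-rank
  ties) between $|\varepsilon|$ and age: positive $\rho$ means individuals
  spread apart with age. It is computed for every gene, whether or not the
  mean trend is significant, because a gene can disperse without moving.

Both p-value families are Benjamini-Hochberg adjusted within a dataset.
Spearman p-values use the t approximation for $n \ge 10$ and exhaustive
permutation enumeration below that; genes with constant expression or
constant $|\varepsilon|$ are flagged and returned as zero-effect rather than
erroring, so a pathological gene cannot abort a 10,000-gene run. Two
sensitivity alternatives are exposed: a Breusch-Pagan score test
(`breusch_pagan_check()`, $nR^2$ against $\chi^2_1$) as a parametric check
on the rank statistic, and `loess_heterogeneity()`, which replaces the
linear mean model with a local regression. The loess route is documented as
sensitivity-only: it tracks the linear-model $\rho$ closely on linear data
but is more sensitive to sample size and span.

## The dependence-aware permutation null

Region datasets of one study contain the same donors, so their statistics
are correlated and any naive cross-dataset test is anti-conservative.
`permute_individual_ages()` therefore shuffles ages among *individuals*
within each study and propagates each donor's permuted age to all of their
samples in every region dataset. Per-study age multisets are conserved and
the cross-dataset coupling is retained, which makes the null distribution of
agreement counts wider — and the test more stringent — than independent
per-sample shuffling (this is asserted as a test invariant).

Under each permutation:

* heterogeneity is re-scored as the correlation between the *observed-age*
  residuals' magnitudes and the permuted ages — the mean model is not refit,
  so only the heterogeneity-age link is broken while the age-expression
  relationship is preserved;
* expression change *is* refit against the permuted ages, because there the
  age-expression link itself is under test.

Empirical p-values use the $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$
convention, so they are never zero and floor at about $10^{-3}$ for the
default 1,000 permutations. All permutation tests are one-sided in the
direction stated by each function.

## Cross-dataset consistency

For each gene, `consistency_counts()` counts the datasets with $\rho > 0$
($\rho = 0$ counts as not-increased). `heterogeneity_consistency()` compares,
for every level $N = 1..K$, the observed number of genes positive in exactly
$N$ datasets against the permutation distribution of that tally. Genes
positive in all $K$ datasets are the headline set; the same permutations
give the expected count at $N = K$, i.e. an estimate of how many of those
genes would agree fully by chance.

Two period-level comparisons reuse the same permutation set
(`period_difference_test()`): the median over matched datasets of
(median aging $\rho$ − median development $\rho$), and the difference in
median pairwise dataset correlations between the periods; a count-based
variant compares the numbers of significant genes. Because dependent pairs
dominate the within-period pairwise correlations,
`independent_triple_correlation_test()` additionally enumerates every
combination of one dataset per study (16 x 2 x 1 = 32 combinations for a
design with studies of 16, 2 and 1 datasets), takes the median pairwise
correlation within each combination, and uses the median over combinations
as the observed statistic — implemented as this median-of-medians because
the alternative reading (testing each combination separately) multiplies
tests without adding information. `pca_dispersion_summary()` gives the
complementary dataset-level view: each dataset's per-gene statistic vector
is scaled to mean 0 / sd 1, principal components are extracted by SVD with
no further centering (the scaling already centers each observation), and
each period's spread is summarized as the median pairwise Euclidean distance
on PC1-PC2.

## Heterogeneity trajectories

Genes consistent across all aging datasets are clustered by trajectory
shape. Per gene and dataset, $|\varepsilon|$ is scaled to mean 0 / sd 1
(scaling per gene x dataset, not per gene jointly, so that every dataset
contributes shape rather than amplitude), fit with `smooth.spline` at 3
effective degrees of freedom, and evaluated at 11 equally spaced transformed
ages spanning that dataset's range. Eleven points per dataset — the smallest
dataset size in the motivating design — keeps differently sized datasets
equally weighted. k-means (default k = 8, a deliberately liberal choice for
a ~150-gene set) with 10 restarts and a fixed seed clusters the concatenated
profiles; genes with constant heterogeneity in any dataset are dropped with
a warning, since their scaled profile is undefined.

## Enrichment and downstream associations

`preranked_gsea()` implements the weighted Kolmogorov-Smirnov running-sum
statistic with weight exponent 1 (the standard preranked choice; weight 0
recovers the classical KS statistic, which is cross-checked against a
brute-force oracle in the tests). The null permutes gene labels — forced by
the input being a single ranking — and is shared across sets of equal size.
NES is the ES divided by the mean magnitude of same-sign permutation scores;
p-values are one-sided among same-sign scores and BH-adjusted across sets.
Set sizes are bounded at 5-500 (10-500 for regulator target sets).

The headline ranking — the number of datasets with a heterogeneity increase
— is a small integer with massive tie blocks, so the ranking is ambiguous.
`tie_robustness_gsea()` reruns the analysis with ties re-broken at random
(default 1,000 repetitions, significance at q < 0.05 — the cutoff is a
package choice, made explicit here) and reports per set the fraction of
repetitions in which it stays significant; with a tie-free ranking the
fraction is exactly 0 or 1 because the internal permutation seed is fixed.

Downstream association tests are thin, well-specified wrappers:
regulator-count association (fraction of matched datasets where the aging
correlation between $\rho$ and the number of distinct TFs/miRNAs exceeds
the development one, against a shared randomization of the counts),
interaction-network degree resampling (median target degree against 10,000
same-size draws, score cutoff applied as $\ge$), cell-type specificity
(one-vs-rest Cohen's D with pooled n−1 sd, genes called specific at
$D \ge 2$, boundary included), Fisher's exact overlap tests, per-sample
linear deconvolution of bulk profiles onto cell-type means (OLS with
intercept; coefficient series can be fed back through the change models to
ask whether composition drifts or disperses with age), and a per-gene
two-sample Wilcoxon test on *signed* residuals for sex-trajectory
differences (exact null at combined $n \le 20$ without ties, normal
approximation with continuity correction otherwise).

## The synthetic-data generator

`simulate_collection()` generates collections with exactly the structure the
analysis assumes, so every stage is testable without downloads. Defaults
describe the emulated design and were fixed before any testing: three
studies contributing 16, 2 and 1 region datasets (19 in total); ages 0-98
years drawn uniformly on the fourth-root-of-days scale, half of each study's
donors below and half above the 20-year cutoff so both periods are
populated; per-gene slopes drawn per period and shared across all datasets;
Gaussian residuals with sd $0.5\,e^{v z}$, where $z$ is the standardized
transformed age and the log-sd slope $v$ is drawn from (0.5, 1.5) for the
planted 5% of heterogeneity-increasing genes, with development left
homoskedastic. The multiplicative form keeps the sd positive for any slope;
Gaussian residuals are the default because the primary statistic is
rank-based, so heavier tails are a test variant rather than a modelling
commitment.

What the generator does *not* emulate: probe-level microarray artifacts,
count noise of RNA-seq, batch structure (available separately through the
`batch` metadata and `batch_mean_restore()`), cell-type mixing, and any
mean-variance coupling beyond what the planted model induces. Passing tests
therefore demonstrate calibration, power and structural correctness of the
machinery under the assumed model — not that real brain data satisfy that
model.

```{r example, eval = FALSE}
col <- simulate_collection(sim_config(regions_per_study = c(2, 2, 1),
                                      n_individuals = 60, n_genes = 300,
                                      frac_het_increase = 0.1, seed = 1))
periods <- split_collection_periods(col)
fits <- lapply(periods, fit_collection_changes)
perms <- permute_individual_ages(col, n_perm = 1000, seed = 2)
cons <- heterogeneity_consistency(fits$aging, perms)
glance(cons)
autoplot(cons)
```

## Numerical choices and problem sizes

* Empirical p-values: +1 convention, one-sided as stated per test.
* Quantile normalization resolves ties to the mean of the reference values
  over the tied rank span, so tied inputs stay tied and column multisets
  match exactly.
* Batch correction standardizes each batch per gene (n−1 sd) and restores
  the gene's grand mean; batches of size one or zero within-batch variance
  are errors because the transform is undefined there.
* k-means keeps the best of `n_init` restarts under a fixed seed; spline
  smoothness is requested as effective degrees of freedom from
  `smooth.spline` directly.
* Constant genes, constant residual magnitudes, one-sex datasets and
  all-tied rankings are flagged-and-skipped rather than fatal, with the
  flags carried in the output tables.
* The test suite and the acceptance script run on deliberately scaled-down
  collections (hundreds of genes, tens of donors, 100-1,000 permutations);
  these sizes are a package choice to keep the full property suite fast
  while leaving every Monte-Carlo check enough resolution for its stated
  tolerance.

## Known limitations

* The unit of inference is cross-dataset consistency; the package makes no
  region-specific discovery claims from single datasets.
* The permutation floor at 1,000 permutations is ~0.001; smaller p-values
  are not resolvable without more permutations.
* The expected-consistency null is computed per level N (genes positive in
  exactly N datasets); at the headline level N = K this coincides with the
  cumulative count.
* Deconvolution assumes profiles on a positive expression scale and full
  column rank; collinear cell-type profiles are a hard error.
* Covariate-adjusted mean models (post-mortem interval, RNA integrity) are
  out of scope.
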