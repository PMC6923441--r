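---
title: "Models and methods behind methsam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methsam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsam)
```

# The scientific problem

Severe acute childhood malnutrition (SAM) presents in two clinically
distinct forms: edematous SAM (ESAM, kwashiorkor and marasmic-kwashiorkor)
and non-edematous SAM (NESAM, marasmus). Acute ESAM is accompanied by
reduced methionine concentrations and slower methyl-group flux through
1-carbon metabolism, which predicts reduced genomic DNA methylation during
the acute illness and its normalization after recovery. `methsam`
implements the statistical machinery for testing that prediction on
450K-style methylation arrays: per-CpG differential methylation between
ESAM and NESAM, clustering of concordant CpGs, disease-context enrichment
of the implicated genes, genotype-by-condition (nutrition-sensitive)
cis-meQTL analysis, and methylation-expression correlation.

# Data model and transforms

Methylation is carried as **beta values** (methylated fraction,
strictly inside (0,1)) and **M values**, `M = log2(beta/(1-beta))`.
Testing happens on the M scale, where array noise is approximately
homoscedastic; effect sizes are reported on the beta scale, where they are
interpretable as methylation-fraction differences. The two transforms are
exact inverses (round-trip to 1e-12 across (0.001, 0.999)).

Before regression, each probe's M values are mapped to normal quantiles of
their Blom rank fractions, `qnorm((r - 3/8)/(n + 1/4))`, with average
ranks for ties. The package applies the 3/8 offset at every sample size;
this is the package's fixed convention for the rank-based inverse normal
transform, chosen so the transform has one closed form at all `n`.
Constant probes transform to zeros with a warning. Missing beta values are
not allowed in the core matrices: synthetic data are complete, and real
data must be imputed or filtered upstream (a documented limitation).

Probe-level QC is flag-based (`filter_probes()`): internal controls,
detection failures, low bead counts, sex chromosomes, cross-reactive
probes, and probes with common SNPs at or near the single-base extension
site, mirroring standard 450K exclusions.

# Single-site model

Each probe is fit by ordinary least squares,

$$M_i = C\alpha + Y\beta + e,$$

with `C` the covariate matrix (age, sex, and optionally the first
principal component of the transformed-M matrix, recomputed from the data
by `add_methylation_pcs()`) and `Y` the ESAM indicator. Two parallel fits
are made on the identical design: the transformed-M fit supplies the t
statistic and two-sided p value (residual df `n - k - 2`); the beta-scale
fit supplies the covariate-adjusted ESAM-NESAM methylation difference
(`beta_slope`). This dual-scale reading is the minimal design consistent
with testing M values while reporting and filtering beta-scale effects.

Multiple testing uses Benjamini-Hochberg FDR and the Bonferroni threshold
`alpha / m` (quoted to 2 significant digits: `0.05/420500 = 1.2e-7`,
`0.05/135053 = 3.7e-7`). Genomic inflation is
`lambda = median(chi^2_1)/qchisq(0.5, 1)`; `lambda_adjust()` deflates
chi-square statistics by lambda before recomputing p values, which is how
cohort-specific results are made comparable in `cohort_concordance()`.
Concordance between two cohorts removes age-sensitive probes first
(country-specific fits omit age as a covariate), counts direction
agreement, and tests it against 0.5 with a two-sided exact binomial test
(the package fixes the two-sided exact convention; only "binomial test" is
conventionally specified).

# Differentially methylated clusters

`build_clusters()` implements the bespoke DMC rule:

1. drop probes with `beta_slope` strictly inside the **open** interval
   (-0.05, +0.05) — marginal effects whose direction is ambiguous. A
   slope of exactly ±0.05 is retained; this boundary convention is
   configurable.
2. scan retained probes left-to-right per chromosome and chain them while
   the gap to the previous retained probe is ≤ 10 kb and the effect sign
   is unchanged. Dropped probes neither bridge nor break chains (filtering
   precedes binning). Singletons are allowed; cluster spans are
   min/max member positions with no flanking extension.

Filtered ("marginal") probes falling inside a final cluster span are
counted retrospectively and clusters with more than two are flagged — an
annotation only, never an exclusion. Cluster-level testing
(`fit_clusters()`) regresses the per-sample mean of member probes'
transformed M values on the same design; the Bonferroni threshold becomes
`alpha / n_clusters`. A singleton cluster therefore reproduces its
probe's single-site p exactly, which the tests assert. Recovered-cohort
(DL) clustering uses the same operation on its own results, with no
special casing.

The scan is verified against an exhaustive O(n²) maximal-run oracle on
1,000 random instances, and is invariant to input order; increasing the
gap never increases the cluster count, and tightening the effect window
never increases the retained-probe count.

# Enrichment scores

**Gene mapping** links a gene to a cluster when its interval overlaps or
lies within 10 kb of the cluster span (1-based positions; "within 10 kb"
means ≤ 10,000 bp). The same cis window is used for SNP-CpG pairing and
expression pairing.

**Gene-context composition** of DMC CpGs versus the tested background is
assessed with two-tailed hypergeometric tests per category (TSS1500,
TSS200, 5'UTR, 1stExon, Body, 3'UTR, IGR), and effect-size differences
across contexts with a Kruskal-Wallis omnibus plus Dunn's pairwise
z-tests (unadjusted by default; Bonferroni/BH optional).

**GWAS-catalog (EFO) scoring**: candidate genes are joined to the catalog
and each (EFO, gene) pair scored by its genome-wide-significant SNP
count; EFO terms with ≥ 2 candidate genes are retained. The joint
statistic (G = genes with any catalog entry, E = EFO terms with ≥ 2
genes) is calibrated by drawing size-matched random gene sets from a
user-supplied universe; the empirical probability is the fraction of
draws with `G >= G_obs` and `E >= E_obs`. Two universe presets mirror the
two natural choices — all array-linked genes, or the catalog∩array
subset — and the universe is deliberately an explicit input rather than a
hidden default. Empirical p values are reported both as raw fractions and
as the bias-corrected `(b+1)/(n+1)` (never exactly zero).

**HPO overlap**: the overlap between candidate genes and
phenotype-linked genes is compared with size-matched random draws,
summarized as `Z = (obs - mean)/sd`; a degenerate null (sd = 0) is
flagged rather than divided through.

**SGO-KGO score**: study gene ontologies (SGOs) and kwashiorkor-phenotype
gene ontologies (KGOs) are ranked by enrichment p; each list position maps
to a quartile value (1, 0.75, 0.5, 0.25 from most to least significant;
assignment is `ceiling(4*rank/n)` with average-rank ties, the package's
tie convention). The quartile score is the product of the two quartile
values (0 when the SGO is absent from the KGO list); the proportion score
is the fraction of a phenotype's genes mapping to the SGO; the final score
is their arithmetic mean, bounded in [0, 1], equal to 1 for an SGO in the
top quartile of both lists covering all of a phenotype's genes and to
`proportion/2` for an SGO missing from the KGO list.

# Nutrition-sensitive cis-meQTLs

Genotypes are 0/1/2 minor-allele dosages. QC removes samples with > 2%
missingness, then SNPs with > 2% missingness, exact Hardy-Weinberg
p < 1e-3, or MAF < 0.05. The HWE test is the exact test conditional on
allele counts (minimum-likelihood two-sided rule), enumerated directly;
the suite verifies it against an independent `choose()`-based enumeration
for all n ≤ 20.

For each cis pair (SNP within 10 kb of the CpG), the additive model is
`probe value = covariates + dosage`, and the interaction model adds
`group + dosage:group`. The methylation response is the same
rank-transformed M value used in the differential analysis. A pair is
classified **nutrition-sensitive** when (i) it is a nominal meQTL in the
acute (DC) samples, `p_main ≤ 0.05` on the pooled DC fit — a precondition
of classification; (ii) the SNP-by-group interaction is significant
acutely (`p_interaction ≤ 0.05` in DC); and (iii) there is no similar
interaction among recovered (DL) samples (`p_interaction > 0.05`). A
stringent tier requires DC `p_interaction < 1e-4`. The pooled-DC reading
of the screen is the default; per-group screening is available by flag.
Overlap of sensitive vs insensitive pairs with an external reference
meQTL catalog is tested with the two-sided Fisher exact test
(point-probability rule, the convention of `fisher.test`). The
genome-wide meQTL threshold (3.4e-8) is an ordinary configurable
constant. Relatedness and inbreeding exclusions are consumed as a
precomputed sample list; kinship estimation is out of scope.

# Methylation-expression correlation

Genes are "expressed" when their per-gene mean intensity is at least
twice the mean of the antigenomic control probes (inclusive boundary).
For every CpG inside a significant cluster and every expressed gene
within 10 kb, the Spearman correlation is computed on both the beta and M
scales — identical by rank invariance under the monotone logit transform,
and both emitted. The p value uses the t approximation
`t = rho sqrt((n-2)/(1-rho^2))`; an exact permutation option is provided
for n ≤ 8 (8! enumerations — beyond that the approximation is already
accurate and full enumeration is disproportionate). Direction within a
gene context is tested with the two-sided Wilcoxon signed-rank test on
the rho values (exact for n ≤ 25, normal approximation with continuity
correction otherwise).

`correlation_power_exact()` computes the power of the two-sided exact
test of zero correlation for a bivariate normal sample: the critical
value comes from the null t distribution of
`r sqrt((n-2)/(1-r^2))` (df `n - 2`), and the power integrates the exact
non-null density of the sample correlation (Hotelling's form, with the
Gauss hypergeometric factor evaluated by an adaptively truncated series)
over `|r| > r_c`:

```{r power}
correlation_power_exact(20, 0.45)$power_pct
correlation_power_exact(20, 0.65)$power_pct
```

The suite cross-checks the integral against a large Monte-Carlo sample of
correlation coefficients.

# The synthetic-data generator

`simulate_study()` emulates the statistical structure the analysis
assumes, not raw array data:

* **Probe layout is cluster-first**: blocks of 2-10 probes with 50-2,000
  bp internal gaps and > 10 kb between blocks, so that a true DMC is
  chainable by the 10 kb rule while distinct blocks never merge.
* **Baselines are bimodal**: block-level baseline betas are drawn from a
  mixture (40% Beta(2,8), 40% Beta(8,2), 20% Beta(5,5)) with small
  per-probe jitter — the characteristic two-peaked distribution of CpG
  methylation with a minority of intermediate probes.
* **Group effects are injected on the beta scale** (a
  `true_effect_beta = 0.05` shift with a per-block shared sign, for ESAM
  samples at the acute timepoint only), then transformed: effects are
  reported in beta units but tested on M values. The shift direction is
  chosen away from a boundary it would cross (random otherwise), so the
  designed effect is fully realizable; means pushed outside
  (0.001, 0.999) are clamped with a warning.
* Noise is normal on the M scale (`noise_sd_m = 0.5`); age, sex and a
  latent sample axis (pc1) act as global M-scale covariates.
* **Genotypes** are Binomial(2, MAF) dosages; additive meQTL pairs add
  `0.4 M/allele` in all samples, interaction-only pairs only in ESAM-DC
  samples, with the SNP within 10 kb of its target CpG.
* **Expression** couples genes over true DMC blocks to the block's mean M
  value; antigenomic control intensities set the expressed threshold.
* **Gene sets** (EFO catalog, HPO terms, ontologies) are drawn over a
  configurable universe, optionally with planted hit-enriched sets; a
  null configuration yields calibrated (uniform) permutation p values.

Default cohort sizes — 150 acute samples per group, 50 recovered per
group, 20 expression samples — match the scale of a two-country acute
cohort with a smaller adult follow-up arm and a small paired-expression
subset. Everything is driven by a single master seed with deterministic
per-component sub-seeds (R's default Mersenne-Twister stream), so
identical configurations reproduce bit-identical matrices.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: array intensity artifacts and
normalization, cell-composition mixtures, LD between SNPs, spatially
correlated residual noise within clusters, batch structure, and missing
values.

# Numerical and design choices

* Per-probe OLS is computed by shared-design matrix algebra (one
  Cholesky per design); collinear covariates are dropped with a warning,
  and an aliased group term is an error. p values are floored at the
  smallest positive double so they remain in (0, 1].
* Null-calibration checks use a two-sided 99% binomial interval around
  the nominal level (10,000 probes: 0.05 ± 0.0056) and require lambda in
  [0.9, 1.1].
* The classifier characterization conditions on its stated precondition
  (acute `p_main ≤ 0.05`): planted interaction-only pairs that pass the
  acute screen are flagged nutrition-sensitive in ≥ 90% of replicates at
  the default study scale; the unconditional rate is lower (~0.82)
  because the pooled screen sees only half the group-specific slope.
* Problem sizes in the test-suite simulations (10,000 probes for
  calibration and recovery; 300-probe replicates for the classifier;
  1,000 random instances for the clustering oracle) were chosen as the
  smallest sizes at which the Monte-Carlo error of each check is
  comfortably below its margin.
* Fisher's two-sided test uses the point-probability rule; the doubling
  rule can be obtained by doubling the smaller one-sided tail if needed.
* Degenerate inputs are first-class: constant probes, constant dosages,
  empty hit lists, empty phenotype gene sets and degenerate permutation
  nulls all return flagged records rather than errors, while genuinely
  unanswerable requests (empty probe intersections, inestimable
  interactions) raise.

# Known limitations

* No empirical-Bayes moderation of probe variances and no cell-type
  deconvolution or adjustment.
* No smoothing/kernel DMR methods; the cluster rule is deliberately the
  simple chain rule described above.
* Real-data ingestion starts from a beta matrix: no IDAT parsing or
  intensity normalization.
* The Spearman p approximation differs from the exact small-n
  distribution for n < 10; use the permutation option there.
* meQTL models assume independent SNPs (no LD pruning or imputation).
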