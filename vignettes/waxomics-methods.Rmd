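---
title: "Methods: from wax abundances to cuticular conductance genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wax abundances to cuticular conductance genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

waxomics implements an integrative quantitative-genetic pipeline for leaf
cuticular waxes in inbred diversity panels: plot-level trait QC and
mixed-model BLUPs, kinship mixed-linear-model GWAS and TWAS, evidence
integration by Fisher's combined test, sliding-window hotspot detection,
candidate-gene declaration, and random-forest prediction of cuticular
conductance (g_c) from wax profiles. This vignette describes the models,
their assumptions, the tunable parameters, and the design decisions taken
where reasonable alternatives existed.

## The trait model and its preparation pipeline

Wax abundances (µg·dm⁻²) are measured on field plots of inbred lines grown
in two environments and quantified by GC-FID. The pipeline applies, in this
order:

1. **Zero filter.** A compound with zeros (not detected) in more than 40%
   of the panel's lines is dropped; a line counts as zero only when all its
   plots are zero. The inequality is strict: a trait at exactly 40% is
   retained.
2. **Uniform imputation.** Remaining zeros are below-detection values, not
   absences; each is replaced by a Uniform(0, m) draw where m is the
   smallest positive value of that compound in the same environment.
   Imputation is seeded and reproducible.
3. **Mixed model.** Per trait, REML (via lme4) fits
   `value ~ grand mean + is_check + (1|line) + (1|env) + (1|line:env) +
   (1|env:block) + (1|env:column) + (1|instrument) + (1|instrument:column)`.
   The repeated check line is a fixed binary covariate and its plots never
   yield BLUPs. Terms that the data cannot support (single level, all
   missing) are dropped automatically; optionally terms whose estimated
   variance pins at zero are removed and the final term set recorded.
4. **Outlier screen (plot level).** Studentized deleted residuals of the
   conditional residuals, flagged at the Bonferroni cutoff
   t(1 − α/(2n), n − p − 1), α = 0.05, single pass. The screen is applied
   to the conditional residuals with an intercept-only working design — a
   deliberate simplification that keeps the deletion formula exact.
5. **Heritability.** On a line-mean basis,
   h² = σ²G / (σ²G + σ²GE/ē + σ²ε/(ē·r̄)), with ē and r̄ the harmonic means
   of environments per line and plots per line within an environment.
6. **Box–Cox.** λ maximizes the profile log-likelihood of an intercept-only
   model on the grid −2…2 (step 0.1) and is then snapped to the nearest
   "convenient" value in {−2, −1, −0.5, 0, 0.5, 1, 2} whenever that value
   lies inside the 95% profile-likelihood interval. Non-positive BLUPs are
   shifted first and the shift recorded.
7. **Outlier screen (BLUP level).** The same deletion-residual screen on
   the transformed BLUPs; removed lines become missing.

Re-running the filters on their own output changes nothing, which the test
suite asserts.

Expression values go through the analogous route: per-gene line values are
standardized and the top k latent factors (default 20; the
maximum-likelihood probabilistic-PCA subspace) are removed, standing in for
PEER-style confounder correction, followed by the per-gene deletion-residual
screen. The trait-model instrument terms are replaced by a sequencing-lane
effect in the expression simulator.

## Association scans

Both scans use the model y = Xβ + g·b + u + e with u ~ N(0, K·σ²G), where K
is VanRaden's centered cross-product kinship K = WW′ / (2Σpⱼ(1−pⱼ)). The
eigendecomposition of K reduces REML/ML estimation to a one-dimensional
profile over the variance ratio λ = σ²ε/σ²G (the EMMA device), optimized on
log λ ∈ [−14, 14].

* **GWAS** defaults to P3D: variance components are estimated once on the
  null model and reused for every SNP, reducing each marker test to a
  weighted least-squares Wald test. An `exact` mode re-optimizes per SNP.
  SNP filters (MAF ≥ 5%, DR2 ≥ 0.80) are applied up front; constant markers
  report p = 1.
* **TWAS** defaults to per-gene REML (the P3D = FALSE convention),
  re-estimating variance components for every gene; lines missing a gene's
  screened expression are dropped for that gene only.
* **R²_LR** = 1 − exp(−(2/n)(LL_full − LL_null)) approximates the variance
  explained by one marker. The likelihoods are maximum-likelihood values
  evaluated at the fitted variance ratio; under identity kinship R²_LR
  equals the classical R², which the tests verify.
* **Model choice.** The null covariate set (none, flowering time, genotype
  PCs) is picked by BIC = −2LL + q·ln n over ML fits, kinship always
  included; ties go to the smaller model.

## Integration and candidates

Fisher's combined test pairs, per gene, the best GWAS p among the top 10%
of SNPs assigned to that gene (nearest gene by distance to the interval,
ties to the smaller gene start then lexicographic id) with the TWAS p, set
to 1 for genes never tested by TWAS so that purely GWAS-supported genes
still enter. X = −2(ln p₁ + ln p₂) is χ²₄, giving p = e^(−X/2)(1 + X/2) in
closed form (computed in log space).

Candidates per trait: GWAS loci are the top 0.002% of SNPs clustered
greedily within 200 kb of successive p-minima, and candidate genes are all
genes overlapping ±200 kb of each peak; TWAS and FCT candidates are the top
0.25% of their gene rankings. All top-fraction counts use
k = max(1, round(frac·N)). Genes found by all three methods are partitioned
into confidence groups: same compound by all three (group 1), same wax
class (group 2), otherwise group 3 — disjoint by construction. The
conductance/wax intersection reports, per method, genes detected for both
phenotype families, flagging genes shared under more than one method.

## Hotspots

Loci are counted in 200-kb windows stepping by one-fifth of the window;
the flagging threshold is the 95% quantile of the genome-wide per-window
count distribution, ceiled to an integer with a floor of 2. Qualifying,
partially overlapping windows merge into hotspots whose boundaries are the
union of those windows (0-based half-open in outputs). Interclass hotspots
additionally require member traits from ≥ 2 classes. The reference
distribution is pooled over all windows per scan rather than per
chromosome or per class — with per-class locus sets of a few dozen loci,
per-chromosome quantiles would be too granular to be meaningful. Two
hotspot sets are "coincident" when intervals overlap by at least 50% of the
shorter one.

## Conductance prediction

A random forest (1000 trees, mtry = 10) predicts g_c BLUPs from the 60
untransformed wax BLUPs under 5-fold cross-validation repeated 50 times;
predictive ability is the Pearson correlation between pooled out-of-fold
predictions and observations (per repeat), averaged over repeats. Variable
importance is unscaled permutation importance (mean increase in out-of-bag
squared error). Two deliberate substitutions: a CART random forest with
permutation importance stands in for conditional-inference forests with
conditional importance (the backend is isolated behind `rf_config()` so it
could be swapped), and "predictive ability" is defined as the pooled
out-of-fold correlation, one of the two conventions in use; per-fold
averaging gives very similar values at n ≈ 300.

## The synthetic-data generator

The generator produces data with the statistical structure the pipeline
assumes, plus a truth record for parameter-recovery tests.

* **Genotypes.** Fully homozygous dosages {0, 2} (a `het_rate` option adds
  heterozygotes); LD from a Gaussian autoregressive copula whose latent
  correlation decays as exp(−d/200 kb), matching the distance at which LD
  in diverse maize panels reaches nominal levels; population structure from
  the Balding–Nichols model. Finite-sample minor-allele frequencies are
  constrained to the configured range by redrawing drifting SNPs — those
  redraws use independent latent values, so a redrawn SNP loses its local
  LD; at the default settings this affects a small minority of SNPs.
* **Gene models.** Non-overlapping intervals placed by sorted random
  offsets into the free space of each chromosome (1-based inclusive).
* **Expression.** Per gene: a cis effect from one SNP within the cis
  window (variance share cis_h2), shared latent factors (default 5 at desk
  scale; confounder correction on real data typically uses 20),
  a sequencing-lane effect, and residual noise; environment replicates
  share the genetic and factor values.
* **Wax traits.** Six classes with the published panel's compound counts
  (7 PA, 11 FA, 9 HC, 4 AD, 14 WE, 8 AC). Each trait's genetic value mixes
  class-shared causal SNPs — which carry a single class-level effect reused
  by every trait drawing them, so same-class traits correlate positively,
  as shared biosynthesis implies — with private SNPs and optional causal
  expression genes, scaled to the configured genotypic variance. The
  default variance components (σ²G = 1, σ²GE = 0.25, σ²env = 0.5,
  σ²block = 0.1, σ²col = 0.05, σ²instr = σ²instr:col = 0.05, σ²ε = 0.5)
  imply a line-mean heritability near 0.74 under the default design
  (2 environments × 8 blocks, one plot per line per environment, a check
  plot per block, 2 instruments × 2 columns), inside the range reported for
  real wax panels. Zeros arise by left-censoring at a per-trait detection
  threshold set to the requested zero-rate quantile, mimicking limits of
  detection while keeping a coherent latent abundance; class sums and the
  grand total are computed from the censored compounds and never
  re-censored.
* **Conductance.** g_c = Σ w_t · (trait genetic value) + environment +
  noise; the default weights sit on five wax esters and one free fatty
  acid, mirroring the compound set that dominates conductance prediction
  in real panels.

What the generator does **not** emulate: coalescent genealogies and
recombination maps, allele-frequency spectra of real imputation panels,
spatial field trends beyond block/column effects, sequencing-depth noise,
and compositional constraints among compounds. Passing recovery tests
therefore show the pipeline's statistics are implemented and calibrated
correctly — not that the biological effect sizes of any real panel will be
recovered.

## Numerical choices and degenerate inputs

* Variance-ratio optimization on log λ ∈ [−14, 14] by golden-section
  (`optimize`); kinship eigenvalues clipped at zero with a warning when the
  matrix is numerically indefinite.
* p-values floored at the smallest positive double; zero inputs to the
  combined test floored likewise with a warning.
* Deletion residuals are undefined at leverage 1; such observations are
  excluded from the screen and reported.
* Entirely zero trait × environment cells cannot bound the imputation and
  raise an error; an all-zero trait panel raises an explicit empty-panel
  error.
* Ranks over p-values are dense (ties share a rank); ties in BIC go to the
  smaller model; nearest-gene ties to the smaller gene start.

## Validation studies and their sizes

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) runs seeded desk-scale studies chosen to finish in
minutes while leaving clear statistical margins: null-GWAS inflation on
300 lines × 5,000 SNPs; type-I error pooled over 10 null traits × 3,000
SNPs (10 × 150 genes for TWAS); QTL recovery (10% variance, MAF ≈ 0.3,
n = 300) over 25 replicates against the top-0.002% rule; TWAS causal-gene
recovery over 25 replicates; an end-to-end group-1 recovery study over 20
replicates whose candidate thresholds are scaled so a handful of loci and
genes qualify at 2,000 SNPs / 150 genes (the published fractions would
select a single SNP at this scale); heritability recovery over 50 traits
spanning h² ∈ {0.2, 0.5, 0.8}; 50 planted interclass-hotspot replicates;
and the three random-forest studies on ~310 lines. The noiseless
conductance study is the fully degenerate limit: every non-genetic variance
exactly zero (features equal the trait genetic values) and a fully shared
within-class genetic architecture. The second condition matters: on
partially shared architectures the out-of-fold correlation of a CART forest
on an additive six-trait signal is limited by the learner's own
approximation error (we measure roughly 0.92–0.98 depending on the panel
draw, near the known behavior of axis-aligned forests on linear targets),
which would turn the limit check into a benchmark of the learner rather
than of the pipeline.

## Known limitations

* The BLUP-stage model is the full random-terms fit (optionally pruning
  zero-variance terms); no iterative model-search heuristic is reproduced.
* Factor residualization is probabilistic PCA, not a variational Bayes
  factor model; with few strong confounders the subspaces coincide in
  practice.
* The hotspot scan does no LD-aware merging beyond the upstream locus
  clumping, and the combined test assumes the GWAS and TWAS p-values are
  independent under the null — a standard, slightly anticonservative
  simplification when both scans share lines.
* P3D Wald tests use n − p − 1 degrees of freedom and do not propagate
  variance-component uncertainty.
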