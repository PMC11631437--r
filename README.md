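# waxomics

Integrative quantitative genetics of adult leaf cuticular waxes and their
relationship to cuticular conductance (g\_c) in inbred diversity panels.

The leaf cuticle limits water loss when stomata close; its waxes — primary
alcohols (PA), free fatty acids (FA), hydrocarbons (HC), aldehydes (AD),
wax esters (WE), and alicyclics (AC) — vary widely among maize inbred
lines, and that variation is heritable. `waxomics` implements the full
analysis chain for dissecting this variation:

* **Trait preparation** — zero filtering of undetected compounds, uniform
  imputation of below-detection zeros, REML mixed models over the
  multi-environment field/instrument design, Studentized-deleted-residual
  outlier screens, line-mean heritability
  h² = σ²G / (σ²G + σ²GE/ē + σ²ε/(ē·r̄)), BLUPs, and Box–Cox
  transformation with "convenient" λ.
* **Association** — VanRaden kinship, genotype PCs, BIC model selection,
  mixed-linear-model GWAS (P3D or exact) and per-gene-REML TWAS, with the
  likelihood-ratio statistic R²\_LR = 1 − exp(−(2/n)(LL₁ − LL₀)).
* **Integration** — Fisher's combined test over paired GWAS/TWAS evidence
  (X = −2Σln p ~ χ²₄, nearest-gene SNP assignment, unexpressed genes at
  p = 1), top-fraction candidate declaration (0.002% SNPs, ±200 kb; 0.25%
  genes), and confidence groups 1/2/3 for genes hit by all three methods.
* **Hotspots** — 200-kb sliding windows (step one-fifth), empirical 95%
  quantile thresholds, merged intraclass/interclass hotspot intervals, and
  coincidence at ≥ 50% overlap.
* **Prediction** — random-forest regression of g\_c on wax BLUPs
  (ntree = 1000, mtry = 10, 5-fold CV × 50) with permutation importance
  and a univariate Pearson screen.
* **Synthetic data** — a seeded generator for genotypes with LD and
  population structure, cis-regulated expression with latent confounders,
  six classes of correlated zero-inflated wax traits over a realistic
  field/instrument design, and a conductance phenotype with a
  machine-readable truth record.

## Worked example

```r
library(waxomics)

# a small simulated panel: 120 lines, 800 SNPs, 80 genes
geno <- simulate_population(120, 800, c(chr1 = 2e7, chr2 = 2e7),
                            n_subpops = 3, fst = 0.12, seed = 11)
lay  <- simulate_gene_models(80, c(chr1 = 2e7, chr2 = 2e7), seed = 12)
ex   <- simulate_expression(geno, lay, cis_h2 = 0.5, seed = 13)
sim  <- simulate_traits_and_gc(geno, ex, lay,
                               class_config = wax_class_config(c(WE = 3, PA = 2)),
                               seed = 14)

panel <- prepare_trait_panel(sim$wax, seed = 1)
panel
#> trait_panel: 120 lines x 8 traits
#>   mean line-mean heritability 0.70 (range 0.65-0.75)

K  <- compute_kinship(geno)
y  <- panel$transformed[, "WE_01"]
gw <- gwas_scan(y, geno, kinship = K, trait_id = "WE_01")
tw <- twas_scan(y, residualize_expression(expression_line_means(ex), 5),
                K, layout = lay, trait_id = "WE_01")
fc <- fct_scan(gw, tw, lay)
head(fc[order(fc$p), c("feature", "p", "rank")], 3)
#>       feature            p rank
#> 18 gene_00042 1.838839e-08    1
#> 3  gene_00008 2.069657e-06    2
#> 35 gene_00076 5.425891e-05    3
```

The 8 traits are the 5 simulated compounds plus their class sums and the
grand total; heritabilities are the per-trait line-mean values from the
REML fits. The combined-test table ranks genes by paired GWAS/TWAS
evidence: here the top hit is a gene adjacent to one of the trait's causal
SNPs, and the second-ranked gene (`gene_00008`) is the trait's planted
causal expression gene (`sim$truth$causal_genes$WE_01`). Printed numbers
come from this exact script; your platform's BLAS may alter trailing
digits.

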