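# Synthetic-data generator: genotypes, gene models, expression, traits.

test_that("simulated genotypes honour the MAF contract and are reproducible", {
  geno <- simulate_population(150, 800, c(chr1 = 1e7, chr2 = 1e7), seed = 1)
  expect_equal(dim(geno$dosages), c(150, 800))
  expect_true(all(geno$dosages %in% c(0, 2)))
  expect_true(all(geno$snp_meta$maf >= 0.05 - 1e-12))
  expect_true(all(geno$snp_meta$maf <= 0.5 + 1e-12))
  # stored MAF matches the realized dosage frequencies exactly
  f <- colMeans(geno$dosages) / 2
  expect_equal(geno$snp_meta$maf, unname(pmin(f, 1 - f)), tolerance = 1e-12)
  # positions strictly increasing within chromosome
  for (chr in unique(geno$snp_meta$chrom)) {
    pos <- geno$snp_meta$pos[geno$snp_meta$chrom == chr]
    expect_true(all(diff(pos) > 0))
  }
  expect_equal(geno$snp_meta$dr2, rep(1, 800))
  # bit-identical under the same seed
  geno2 <- simulate_population(150, 800, c(chr1 = 1e7, chr2 = 1e7), seed = 1)
  expect_identical(geno$dosages, geno2$dosages)
  expect_identical(geno$snp_meta, geno2$snp_meta)
  expect_error(simulate_population(1, 10, c(chr1 = 1e6)), "n_lines")
  expect_error(simulate_population(10, 10, c(chr1 = 1e6),
                                   maf_range = c(0, 0.6)), "maf_range")
})

test_that("heterozygote option produces dosage 1 and LD decays with distance", {
  geno <- simulate_population(200, 300, c(chr1 = 5e6), het_rate = 0.4,
                              seed = 3)
  expect_true(any(geno$dosages == 1))
  # adjacent SNPs more correlated than distant ones
  g <- simulate_population(300, 400, c(chr1 = 4e6), ld_decay_bp = 2e5,
                           seed = 4)
  r <- cor(g$dosages)
  d <- abs(outer(g$snp_meta$pos, g$snp_meta$pos, "-"))
  near <- d > 0 & d < 5e4
  far <- d > 1e6
  expect_gt(mean(abs(r[near])), mean(abs(r[far])) + 0.1)
})

test_that("population structure separates on the leading PCs", {
  geno <- simulate_population(120, 1200, c(chr1 = 1e7), n_subpops = 3,
                              fst = 0.15, seed = 7)
  pcs <- compute_pcs(geno, 2)
  expect_gt(silhouette_score(pcs, geno$subpop), 0.3)
})

test_that("gene models are sorted, non-overlapping, and within bounds", {
  lay <- simulate_gene_models(200, c(chr1 = 1e7, chr2 = 1e7), seed = 2)
  gm <- lay$gene_models
  expect_equal(nrow(gm), 200)
  expect_true(all(gm$start >= 1 & gm$end <= 1e7))
  expect_true(all(gm$start <= gm$end))
  for (chr in c("chr1", "chr2")) {
    g <- gm[gm$chrom == chr, ]
    expect_true(all(diff(g$start) > 0))           # sorted
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))  # non-overlapping
  }
  # already sorted: re-sorting is the identity
  ord <- order(match(gm$chrom, names(lay$chrom_lengths)), gm$start)
  expect_identical(ord, seq_len(nrow(gm)))
  # exact-length single gene
  one <- simulate_gene_models(1, c(chr1 = 1e6), min_len = 1000,
                              max_len = 1000, seed = 5)
  expect_equal(one$gene_models$end - one$gene_models$start + 1, 1000)
  # capacity error when genes cannot fit
  expect_error(simulate_gene_models(100, c(chr1 = 5e4), min_len = 1000,
                                    max_len = 1000, seed = 1), "fit")
})

test_that("expression has no genotype association when cis_h2 = 0", {
  geno <- simulate_population(150, 150, c(chr1 = 5e6), seed = 3)
  lay <- simulate_gene_models(15, c(chr1 = 5e6), seed = 3)
  ex <- simulate_expression(geno, lay, cis_h2 = 0, n_latent_factors = 0,
                            seed = 3)
  eb <- expression_line_means(ex)
  # pooled regression p-values of every gene on every SNP ~ uniform
  X <- scale(geno$dosages)
  E <- scale(eb)
  n <- nrow(X)
  r <- crossprod(E, X) / (n - 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  pv <- 2 * pt(-abs(tval), n - 2)
  expect_gt(ks.test(as.vector(pv), "punif")$p.value, 0.01)
})

test_that("a strong cis effect places the minimum-p SNP inside the cis window", {
  geno <- simulate_population(200, 400, c(chr1 = 1e7), seed = 4)
  lay <- simulate_gene_models(12, c(chr1 = 1e7), seed = 4)
  ex <- simulate_expression(geno, lay, cis_h2 = 0.8, cis_window_bp = 1e5,
                            n_latent_factors = 2, seed = 4)
  eb <- expression_line_means(ex)
  X <- scale(geno$dosages)
  for (g in which(!ex$truth$no_cis)[1:5]) {
    r <- abs(drop(crossprod(scale(eb[, g]), X)))
    best <- which.max(r)
    gm <- lay$gene_models[g, ]
    pos <- geno$snp_meta$pos[best]
    expect_true(pos >= gm$start - 1e5 && pos <= gm$end + 1e5)
  }
})

test_that("expression is constant across lines in the degenerate limit", {
  geno <- simulate_population(30, 50, c(chr1 = 1e6), seed = 5)
  lay <- simulate_gene_models(5, c(chr1 = 1e6), seed = 5)
  ex <- simulate_expression(geno, lay, cis_h2 = 0, n_latent_factors = 0,
                            noise_sd = 0, seed = 5)
  for (e in 1:2) {
    expect_equal(max(apply(ex$expr[, , e], 2, sd)), 0)
  }
})

test_that("trait zero rates, class sums, and determinism hold", {
  geno <- simulate_population(300, 400, c(chr1 = 1e7), seed = 6)
  cc <- wax_class_config(counts = c(WE = 3, PA = 2))
  zr <- c(WE_01 = 0.5, WE_02 = 0.05, WE_03 = 0, PA_01 = 0.05, PA_02 = 0.05)
  sim <- simulate_traits_and_gc(geno, class_config = cc,
                                zero_rate_per_trait = zr, seed = 6)
  wax <- sim$wax
  expect_true(all(wax$value >= 0 & is.finite(wax$value)))
  z <- with(wax[wax$trait_id == "WE_01" & !wax$is_check, ], mean(value == 0))
  expect_lt(abs(z - 0.5), 0.05)
  # class sums equal the sum of censored compound values, exactly
  key <- with(wax, paste(line_id, env, block_id, sep = "|"))
  for (cl in c("WE", "PA")) {
    cmp <- paste0(cl, "_0", seq_len(if (cl == "WE") 3 else 2))
    m <- sapply(c(cmp, paste0(cl, "_total")), function(t)
      tapply(wax$value[wax$trait_id == t], key[wax$trait_id == t], sum))
    expect_equal(unname(rowSums(m[, cmp])), unname(m[, paste0(cl, "_total")]))
  }
  sim2 <- simulate_traits_and_gc(geno, class_config = cc,
                                 zero_rate_per_trait = zr, seed = 6)
  expect_identical(sim$wax$value, sim2$wax$value)
  expect_identical(sim$gc$value, sim2$gc$value)
  expect_error(
    simulate_traits_and_gc(geno, class_config = cc,
                           truth_spec = wax_truth_spec(
                             gc_weights = c(NOPE = 1)), seed = 1),
    "unknown traits")
})

test_that("within-class trait correlations exceed between-class correlations", {
  geno <- simulate_population(200, 800, c(chr1 = 2e7), seed = 1)
  sim <- simulate_traits_and_gc(geno, seed = 2)
  wax <- sim$wax[!sim$wax$is_check, ]
  lm_ <- sapply(split(seq_len(nrow(wax)), wax$trait_id), function(i)
    tapply(wax$value[i], wax$line_id[i], mean))
  reg <- attr(sim$wax, "trait_meta")
  cmp <- reg$trait_id[!reg$is_sum]
  cm <- cor(lm_[, cmp])
  cls <- reg$class[match(cmp, reg$trait_id)]
  same <- outer(cls, cls, "==")
  ut <- upper.tri(cm)
  expect_gt(mean(cm[same & ut]), mean(cm[!same & ut]))
})

test_that("every line/environment pair is present for each trait", {
  geno <- simulate_population(40, 100, c(chr1 = 1e6), seed = 9)
  sim <- simulate_traits_and_gc(
    geno, class_config = wax_class_config(counts = c(HC = 2)), seed = 9)
  wax <- sim$wax[!sim$wax$is_check, ]
  tab <- table(wax$trait_id, wax$line_id, wax$env)
  expect_true(all(tab == 1))
})
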