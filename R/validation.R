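# Seeded validation studies: calibration, oracle agreement, and
# parameter-recovery rates for the whole pipeline. Each function runs a
# self-contained simulation study at desk scale and returns the measured
# quantity; the test suite asserts on these and the acceptance script
# reports them.

#' Trait-registry bookkeeping
#'
#' Counts the traits defined by a class configuration: compounds per class,
#' compound total, and the full trait count including the class sums and the
#' grand total.
#'
#' @param class_config output of [wax_class_config()].
#' @return named numeric vector with per-class counts, `n_compounds`,
#'   `n_sums`, and `n_traits`.
#' @export
registry_counts <- function(class_config = wax_class_config()) {
  reg <- trait_registry(class_config)
  per_class <- table(reg$class[!reg$is_sum])
  out <- c(as.numeric(per_class), attr(reg, "counts"))
  names(out) <- c(names(per_class), names(attr(reg, "counts")))
  out
}

#' Agreement of the combined test with the chi-squared survival function
#'
#' Evaluates [fisher_combine()] against `pchisq(X, 4, lower.tail = FALSE)`
#' over a log-spaced grid of input pairs.
#'
#' @param n_grid grid points per input.
#' @return maximum absolute deviation.
#' @export
validate_fisher_oracle <- function(n_grid = 40) {
  p <- 10^seq(-12, 0, length.out = n_grid)
  p[p > 1] <- 1
  grid <- expand.grid(p1 = p, p2 = p)
  got <- fisher_combine(grid$p1, grid$p2)
  x <- -2 * (log(grid$p1) + log(grid$p2))
  want <- stats::pchisq(x, df = 4, lower.tail = FALSE)
  max(abs(got - want))
}

#' Agreement of the kinship mixed model with ordinary least squares
#'
#' With identity kinship the mixed model collapses to OLS, so GWAS and TWAS
#' p-values must match `stats::lm` t-test p-values.
#'
#' @param seed integer seed.
#' @param n_lines,n_snps,n_genes problem size.
#' @return named vector: maximum absolute p-value differences for GWAS and
#'   TWAS.
#' @export
validate_mlm_vs_ols <- function(seed = 1, n_lines = 120, n_snps = 300,
                                n_genes = 40) {
  geno <- simulate_population(n_lines, n_snps, c(chr1 = 5e6), seed = seed)
  withr::with_seed(seed + 1, {
    y <- stats::setNames(stats::rnorm(n_lines), geno$line_ids)
    E <- matrix(stats::rnorm(n_lines * n_genes), n_lines, n_genes,
                dimnames = list(geno$line_ids, sprintf("g%02d", seq_len(n_genes))))
  })
  Kid <- diag(n_lines)
  dimnames(Kid) <- list(geno$line_ids, geno$line_ids)
  gw <- gwas_scan(y, geno, kinship = Kid)
  p_ols <- apply(geno$dosages, 2, function(g) {
    if (stats::sd(g) == 0) 1 else summary(stats::lm(y ~ g))$coefficients[2, 4]
  })
  tw <- twas_scan(y, E, Kid)
  p_ols_tw <- apply(E, 2, function(g)
    summary(stats::lm(y ~ g))$coefficients[2, 4])
  c(gwas = max(abs(gw$p - p_ols[gw$feature])),
    twas = max(abs(tw$p - p_ols_tw[tw$feature])))
}

#' Genomic inflation of a null GWAS scan
#'
#' Simulates a structured panel, draws a null trait with a polygenic
#' component matching the kinship plus independent noise, scans it, and
#' returns the genomic-inflation factor (median chi-squared over its null
#' median).
#'
#' @param seed integer seed.
#' @param n_lines,n_snps panel size.
#' @return lambda_GC.
#' @export
validate_gwas_inflation <- function(seed = 1, n_lines = 300, n_snps = 5000) {
  geno <- simulate_population(n_lines, n_snps,
                              c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                              n_subpops = 3, fst = 0.1, seed = seed)
  K <- compute_kinship(geno)
  withr::with_seed(seed + 1, {
    L <- t(chol(K + diag(1e-6, n_lines)))
    y <- drop(L %*% stats::rnorm(n_lines)) + stats::rnorm(n_lines)
  })
  names(y) <- geno$line_ids
  tab <- gwas_scan(y, geno, kinship = K)
  stats::median(stats::qchisq(1 - tab$p, 1)) / stats::qchisq(0.5, 1)
}

#' Empirical type-I error of the association scans
#'
#' Repeated null traits on one simulated panel; returns the fraction of
#' tests rejected at the nominal level, pooled over replicates, for the
#' GWAS scan and (on a smaller gene set) the TWAS scan.
#'
#' @param seed integer seed.
#' @param n_lines,n_snps,n_genes,n_reps study size.
#' @param alpha nominal level.
#' @return named vector `gwas`, `twas` of empirical rejection rates.
#' @export
validate_type1_error <- function(seed = 1, n_lines = 250, n_snps = 3000,
                                 n_genes = 150, n_reps = 10, alpha = 0.01) {
  geno <- simulate_population(n_lines, n_snps, c(chr1 = 5e7, chr2 = 5e7),
                              n_subpops = 3, fst = 0.1, seed = seed)
  K <- compute_kinship(geno)
  lay <- simulate_gene_models(n_genes, c(chr1 = 5e7, chr2 = 5e7), seed = seed)
  ex <- simulate_expression(geno, lay, cis_h2 = 0.3, seed = seed + 1)
  E <- residualize_expression(expression_line_means(ex), k_factors = 5)
  L <- t(chol(K + diag(1e-6, n_lines)))
  rej_g <- 0; tot_g <- 0; rej_t <- 0; tot_t <- 0
  for (r in seq_len(n_reps)) {
    y <- withr::with_seed(seed + 10 + r, {
      drop(L %*% stats::rnorm(n_lines)) + stats::rnorm(n_lines)
    })
    names(y) <- geno$line_ids
    pg <- gwas_scan(y, geno, kinship = K)$p
    rej_g <- rej_g + sum(pg < alpha); tot_g <- tot_g + length(pg)
    pt <- twas_scan(y, E, K)$p
    rej_t <- rej_t + sum(pt < alpha); tot_t <- tot_t + length(pt)
  }
  c(gwas = rej_g / tot_g, twas = rej_t / tot_t,
    n_gwas = tot_g, n_twas = tot_t)
}

#' Hotspot scan calibration under uniform loci
#'
#' Places loci uniformly at random and measures the fraction of windows at
#' or above the empirical threshold, together with the quantile granularity
#' (the probability mass exactly at the threshold). A calibrated scan keeps
#' the flagged fraction below `1 - q` plus that granularity.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_loci loci per replicate.
#' @param q quantile used by the threshold.
#' @return named vector: mean `flagged_frac` and mean `granularity`.
#' @export
validate_hotspot_null <- function(seed = 1, n_reps = 100, n_loci = 100,
                                  q = 0.95) {
  cl <- c(chr1 = 2e7, chr2 = 2e7)
  res <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      loci <- data.frame(
        chrom = sample(names(cl), n_loci, replace = TRUE),
        peak_pos = sample.int(2e7, n_loci, replace = TRUE))
      wc <- window_counts(loci, cl)
      thr <- empirical_threshold(wc$count, q)
      c(mean(wc$count >= thr), mean(wc$count == thr))
    }, numeric(2))
  })
  c(flagged_frac = mean(res[1, ]), granularity = mean(res[2, ]))
}

#' Power to rank a planted QTL first
#'
#' Plants one QTL explaining a given share of phenotypic variance at a SNP
#' of moderate allele frequency in a structured panel and asks how often
#' the causal SNP reaches the top `0.002%` of the scan (which at desk scale
#' is rank one).
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_lines,n_snps panel size.
#' @param qtl_var variance share of the QTL.
#' @return recovery rate in `[0, 1]`.
#' @export
validate_qtl_power <- function(seed = 1, n_reps = 25, n_lines = 300,
                               n_snps = 4000, qtl_var = 0.10) {
  hits <- vapply(seq_len(n_reps), function(r) {
    geno <- simulate_population(n_lines, n_snps,
                                c(chr1 = 1e8, chr2 = 1e8), n_subpops = 3,
                                fst = 0.1, seed = seed + r)
    K <- compute_kinship(geno)
    withr::with_seed(seed + 1000 + r, {
      maf <- geno$snp_meta$maf
      cand <- which(abs(maf - 0.3) < 0.05)
      j <- sample(cand, 1)
      x <- scale(geno$dosages[, j])
      L <- t(chol(K + diag(1e-6, n_lines)))
      poly <- drop(L %*% stats::rnorm(n_lines))
      poly <- poly / stats::sd(poly)
      y <- sqrt(qtl_var) * drop(x) +
        sqrt(1 - qtl_var) * (sqrt(0.5) * poly + sqrt(0.5) * stats::rnorm(n_lines))
      names(y) <- geno$line_ids
      tab <- gwas_scan(y, geno, kinship = K)
      k <- top_k(2e-5, nrow(tab))
      topf <- tab$feature[order(tab$p)][seq_len(k)]
      geno$snp_meta$snp_id[j] %in% topf
    })
  }, logical(1))
  mean(hits)
}

#' Power to rank a planted causal gene first in TWAS
#'
#' The trait draws a given variance share from one gene's expression; the
#' rate at which that gene is the minimum-p TWAS gene is returned.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_lines,n_snps,n_genes study size.
#' @param gene_var variance share of the causal gene.
#' @return recovery rate.
#' @export
validate_twas_power <- function(seed = 1, n_reps = 25, n_lines = 300,
                                n_snps = 1500, n_genes = 150,
                                gene_var = 0.30) {
  cl <- c(chr1 = 5e7, chr2 = 5e7)
  geno <- simulate_population(n_lines, n_snps, cl, n_subpops = 3, fst = 0.1,
                              seed = seed)
  K <- compute_kinship(geno)
  lay <- simulate_gene_models(n_genes, cl, seed = seed)
  hits <- vapply(seq_len(n_reps), function(r) {
    ex <- simulate_expression(geno, lay, cis_h2 = 0.5, seed = seed + r)
    E <- residualize_expression(expression_line_means(ex), k_factors = 5)
    withr::with_seed(seed + 500 + r, {
      g <- sample(n_genes, 1)
      x <- expression_line_means(ex)[, g]
      y <- sqrt(gene_var) * drop(scale(x)) +
        sqrt(1 - gene_var) * stats::rnorm(n_lines)
      names(y) <- geno$line_ids
      tab <- twas_scan(y, E, K)
      tab$feature[which.min(tab$p)] == colnames(E)[g]
    })
  }, logical(1))
  mean(hits)
}

#' End-to-end recovery of a coupled GWAS + TWAS gene into group 1
#'
#' Simulates a gene with a strong cis-regulated expression effect on a
#' trait (so both its cis SNP and its expression carry signal), runs the
#' GWAS, TWAS and combined-test scans, declares candidates with
#' desk-scaled top fractions, and checks that the gene lands in confidence
#' group 1.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_lines,n_snps,n_genes study size.
#' @param trait_h2 variance share of the causal gene on the trait.
#' @param snp_top_frac,gene_top_frac candidate thresholds, scaled so a
#'   handful of loci/genes qualify at desk scale.
#' @return recovery rate.
#' @export
validate_group1_recovery <- function(seed = 1, n_reps = 20, n_lines = 250,
                                     n_snps = 2000, n_genes = 150,
                                     trait_h2 = 0.5,
                                     snp_top_frac = 1.5e-3,
                                     gene_top_frac = 2e-2) {
  cl <- c(chr1 = 5e7, chr2 = 5e7)
  hits <- vapply(seq_len(n_reps), function(r) {
    geno <- simulate_population(n_lines, n_snps, cl, seed = seed + r)
    K <- compute_kinship(geno)
    lay <- simulate_gene_models(n_genes, cl, seed = seed + r)
    ex <- simulate_expression(geno, lay, cis_h2 = 0.8, cis_window_bp = 2e5,
                              n_latent_factors = 3, seed = seed + 100 + r)
    eb <- expression_line_means(ex)
    E <- residualize_expression(eb, k_factors = 3)
    withr::with_seed(seed + 200 + r, {
      cis_ok <- which(!ex$truth$no_cis & !is.na(ex$truth$cis_snp))
      g <- sample(cis_ok, 1)
      gv <- ex$genetic_values[, g]
      y <- sqrt(trait_h2) * drop(scale(gv)) +
        sqrt(1 - trait_h2) * stats::rnorm(n_lines)
      names(y) <- geno$line_ids
      gw <- gwas_scan(y, geno, kinship = K, trait_id = "trait1")
      tw <- twas_scan(y, E, K, trait_id = "trait1")
      fc <- fct_scan(gw, tw, lay)
      loci <- declare_gwas_loci(gw, top_frac = snp_top_frac)
      cand <- select_candidates(loci, lay, tw, fc,
                                gene_top_frac = gene_top_frac)
      grp <- confidence_groups(cand, stats::setNames("WE", "trait1"))
      colnames(eb)[g] %in% grp$group1$gene_id
    })
  }, logical(1))
  mean(hits)
}

#' Recovery of line-mean heritability by the trait pipeline
#'
#' Simulates traits whose variance components imply heritabilities of 0.2,
#' 0.5 and 0.8 under the default two-environment design, estimates
#' heritability with the REML trait model, and returns the mean absolute
#' error.
#'
#' @param seed integer seed.
#' @param n_traits number of simulated traits (split over the three levels).
#' @param n_lines panel size.
#' @return mean absolute error of the heritability estimate.
#' @export
validate_h2_recovery <- function(seed = 1, n_traits = 50, n_lines = 200) {
  targets <- rep(c(0.2, 0.5, 0.8), length.out = n_traits)
  geno <- simulate_population(n_lines, 60, c(chr1 = 1e6), seed = seed)
  errs <- vapply(seq_len(n_traits), function(i) {
    h2 <- targets[i]
    # solve sigma_e for the target h2 at sigma_G = 1, sigma_GE = 0.25,
    # 2 environments x 1 plot
    se <- 2 * (1 / h2 - 1 - 0.25 / 2)
    vc <- list(G = 1, GE = 0.25, env = 0.5, block = 0.1, col = 0.05,
               instr = 0.05, instr_col = 0.05, resid = se)
    sim <- simulate_traits_and_gc(
      geno, class_config = wax_class_config(counts = c(WE = 1),
                                            shared_frac = 0),
      truth_spec = wax_truth_spec(variance_components = vc,
                                  class_means = c(WE = 30)),
      zero_rate_per_trait = 0, seed = seed + i)
    fit <- fit_trait_mixed_model(sim$wax, "WE_01")
    abs(line_mean_heritability(fit$vc, 2, 1) - h2)
  }, numeric(1))
  mean(errs)
}

#' Recovery of a planted interclass hotspot
#'
#' Places a cluster of five loci from three wax classes inside a 100-kb
#' span plus a sparse uniform background, scans in interclass mode, and
#' checks the cluster is called as a single interclass hotspot containing
#' all five loci.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_background background loci.
#' @return recovery rate.
#' @export
validate_interclass_recovery <- function(seed = 1, n_reps = 50,
                                         n_background = 40) {
  cl <- c(chr1 = 2e7, chr2 = 2e7)
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      center <- sample.int(2e7 - 2e5, 1) + 1e5
      cluster <- data.frame(
        trait = paste0("t", 1:5),
        class = c("WE", "WE", "PA", "PA", "AD"),
        chrom = "chr1",
        peak_pos = center + sample(-5e4:5e4, 5))
      bg <- data.frame(
        trait = paste0("b", seq_len(n_background)),
        class = sample(wax_classes(), n_background, replace = TRUE),
        chrom = sample(names(cl), n_background, replace = TRUE),
        peak_pos = sample.int(2e7, n_background, replace = TRUE))
      loci <- rbind(cluster, bg)
      hs <- call_hotspots(loci, cl, mode = "interclass")
      cover <- hs$chrom == "chr1" & hs$start < min(cluster$peak_pos) &
        hs$end >= max(cluster$peak_pos)
      sum(cover) == 1 &&
        all(cluster$trait %in% hs$members[[which(cover)]]$trait)
    }, logical(1))
  })
  mean(hits)
}

#' Random-forest behavior on simulated conductance
#'
#' Three seeded studies of the conductance predictor:
#' `rf_noiseless_ability` -- conductance is an exact linear function of six
#' wax-trait genetic values in a near-noiseless panel (class-correlated
#' features, as in the real panel); `rf_null_ability` -- conductance
#' independent of all features; `rf_importance_top10_rate` -- how often all
#' six planted causal features rank in the importance top 10 over repeated
#' runs.
#'
#' @param seed integer seed.
#' @param n_lines panel size.
#' @param n_repeats_noiseless,n_repeats_null CV repeats for the two ability
#'   studies.
#' @param n_importance_runs importance replicates.
#' @return named vector with the three measurements.
#' @export
validate_rf_behavior <- function(seed = 1, n_lines = 310,
                                 n_repeats_noiseless = 10,
                                 n_repeats_null = 50,
                                 n_importance_runs = 20) {
  # degenerate noiseless limit: all non-genetic variances zero, no
  # censoring, and a fully shared within-class genetic architecture, so the
  # features equal the trait genetic values and the forest's own
  # approximation error is negligible
  geno <- simulate_population(n_lines, 400, c(chr1 = 2e7), seed = seed)
  vc <- list(G = 1, GE = 0, env = 0, block = 0, col = 0,
             instr = 0, instr_col = 0, resid = 0)
  sim <- simulate_traits_and_gc(
    geno, class_config = wax_class_config(shared_frac = 1),
    truth_spec = wax_truth_spec(variance_components = vc, gc_noise_sd = 0),
    zero_rate_per_trait = 0, seed = seed + 1)
  feats <- sapply(split(seq_len(nrow(sim$wax)), sim$wax$trait_id),
                  function(i) {
                    d <- sim$wax[i, ]
                    tapply(d$value[!d$is_check], d$line_id[!d$is_check], mean)
                  })
  feats <- feats[geno$line_ids, , drop = FALSE]
  target <- sim$truth$gc_genetic[rownames(feats)]
  rep_noiseless <- rf_cross_validate(
    feats, target, rf_config(n_repeats = n_repeats_noiseless, seed = seed))

  # null study: independent features, target independent of all of them
  X_null <- withr::with_seed(seed + 2, {
    matrix(stats::rnorm(n_lines * 60), n_lines, 60,
           dimnames = list(NULL, sprintf("f%02d", 1:60)))
  })
  y_null <- withr::with_seed(seed + 4, stats::rnorm(n_lines))
  rep_null <- rf_cross_validate(
    X_null, y_null,
    rf_config(n_trees = 500, n_repeats = n_repeats_null, seed = seed))

  # importance: 6 causal of 60 independent features, effect 1, noise 0.5
  top10 <- withr::with_seed(seed + 3, {
    vapply(seq_len(n_importance_runs), function(r) {
      X <- matrix(stats::rnorm(n_lines * 60), n_lines, 60,
                  dimnames = list(NULL, sprintf("f%02d", 1:60)))
      y <- rowSums(X[, 1:6]) + stats::rnorm(n_lines, sd = 0.5)
      imp <- rf_importance(X, y, rf_config(seed = seed + 100 + r))
      all(sprintf("f%02d", 1:6) %in% imp$feature[1:10])
    }, logical(1))
  })
  c(rf_noiseless_ability = rep_noiseless$mean_ability,
    rf_null_ability = rep_null$mean_ability,
    rf_importance_top10_rate = mean(top10))
}
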