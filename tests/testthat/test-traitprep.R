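# Trait QC: zero filter, imputation, outlier screening, heritability,
# Box-Cox, and expression residualization.

test_that("zero filter removes traits undetected in over 40% of lines", {
  n <- 310
  over <- make_zero_pattern_table(n, zero_lines = seq_len(round(0.41 * n)),
                                  trait_id = "T_over")
  at <- make_zero_pattern_table(n, zero_lines = seq_len(round(0.40 * n)),
                                trait_id = "T_at")
  clean <- make_zero_pattern_table(n, trait_id = "T_clean")
  pt <- rbind(over, at, clean)
  class(pt) <- c("plot_table", "data.frame")
  res <- filter_detectable_traits(pt)
  kept <- unique(res$plot_table$trait_id)
  expect_false("T_over" %in% kept)   # 41% > 40%: excluded
  expect_true("T_at" %in% kept)      # exactly 40%: retained (strict rule)
  expect_true("T_clean" %in% kept)
  expect_equal(res$report$zero_frac[res$report$trait_id == "T_at"], 0.40,
               tolerance = 1e-9)
  all_zero <- make_zero_pattern_table(20, zero_lines = 1:20)
  expect_error(filter_detectable_traits(all_zero), "all traits")
})

test_that("zero filter counts a line as zero only if all its plots are zero", {
  pt <- make_zero_pattern_table(10, trait_id = "T")
  # half the plots of every line are zero, but no line is fully zero
  pt$value[pt$env == 1] <- 0
  res <- filter_detectable_traits(pt)
  expect_equal(res$report$zero_frac, 0)
})

test_that("imputation draws lie strictly inside (0, env minimum positive)", {
  pt <- make_zero_pattern_table(40, zero_lines = 1:5, trait_id = "T")
  m1 <- min(pt$value[pt$env == 1 & pt$value > 0])
  m2 <- min(pt$value[pt$env == 2 & pt$value > 0])
  res <- impute_zero_abundances(pt, seed = 2)
  out <- res$plot_table
  expect_true(all(out$value > 0))
  imp1 <- out$value[pt$value == 0 & pt$env == 1]
  imp2 <- out$value[pt$value == 0 & pt$env == 2]
  expect_true(all(imp1 > 0 & imp1 < m1))
  expect_true(all(imp2 > 0 & imp2 < m2))
  # deterministic under the seed; identity when nothing is zero
  res2 <- impute_zero_abundances(pt, seed = 2)
  expect_identical(res$plot_table$value, res2$plot_table$value)
  clean <- make_zero_pattern_table(10)
  expect_identical(impute_zero_abundances(clean, seed = 1)$plot_table$value,
                   clean$value)
  allz <- pt
  allz$value[allz$env == 1] <- 0
  expect_error(impute_zero_abundances(allz, seed = 1), "entirely zero")
})

test_that("Studentized deleted residuals match the leave-one-out oracle", {
  withr::with_seed(42, {
    n <- 25
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  })
  got <- screen_outliers_sdr(y, X)
  want <- sdr_loo_oracle(y, X)
  expect_equal(got$sdr, want, tolerance = 1e-10)
})

test_that("a gross outlier is removed, and only it", {
  withr::with_seed(7, {
    y <- rnorm(30)
    y[13] <- y[13] + 10
  })
  res <- screen_outliers_sdr(y)
  expect_equal(res$removed, 13L)
})

test_that("the Bonferroni screen controls the family-wise removal rate", {
  withr::with_seed(99, {
    removed <- vapply(seq_len(1000), function(i)
      length(screen_outliers_sdr(rnorm(30))$removed) > 0, logical(1))
  })
  alpha <- 0.05
  expect_lte(mean(removed), alpha + 2 * sqrt(alpha * (1 - alpha) / 1000))
})

test_that("line-mean heritability follows the harmonic-mean formula", {
  expect_equal(line_mean_heritability(list(G = 1, GE = 0, resid = 0), 2, 1), 1)
  expect_equal(line_mean_heritability(list(G = 0, GE = 1, resid = 1), 2, 1), 0)
  # 1 / (1 + 1/2 + 1/(2*2)) = 1/1.75
  expect_equal(line_mean_heritability(list(G = 1, GE = 1, resid = 1), 2, 2),
               1 / 1.75)
  expect_error(line_mean_heritability(list(G = 0, GE = 0, resid = 0), 2, 1),
               "undefined")
})

test_that("Box-Cox snaps to convenient lambdas and transforms exactly", {
  withr::with_seed(1, {
    ln <- exp(rnorm(300, mean = 1, sd = 0.6))
    nm <- rnorm(300, mean = 20, sd = 2)
  })
  expect_equal(boxcox_transform(ln)$lambda, 0)
  expect_equal(boxcox_transform(nm)$lambda, 1)
  # the lambda = 1 branch is exactly y - 1
  bc <- boxcox_transform(nm)
  expect_equal(bc$transformed, nm - 1)
  # log branch
  bl <- boxcox_transform(ln)
  expect_equal(bl$transformed, log(ln))
  # non-positive values are shifted, and the shift is reported
  sh <- boxcox_transform(c(-1, nm))
  expect_gt(sh$shift, 1)
})

test_that("BLUPs equal centered line means when residual variance vanishes", {
  withr::with_seed(3, {
    lines <- sprintf("L%02d", 1:40)
    eff <- rnorm(40, sd = 2)
    pt <- data.frame(
      line_id = rep(lines, each = 2), env = rep(1:2, 40),
      block_id = 1L, column_id = 1L, instrument_id = 1L,
      instrument_column_id = 1L, is_check = FALSE, trait_id = "T",
      value = 10 + rep(eff, each = 2))
  })
  fit <- fit_trait_mixed_model(pt, "T", random_terms = "line")
  lm_ <- tapply(pt$value, pt$line_id, mean)
  expect_equal(unname(fit$blups[names(lm_)]),
               as.vector(lm_ - fit$grand_mean), tolerance = 1e-8)
})

test_that("BLUPs shrink to zero when genotypic variance vanishes", {
  withr::with_seed(4, {
    lines <- sprintf("L%02d", 1:60)
    pt <- data.frame(
      line_id = rep(lines, each = 4), env = rep(1:2, 120),
      block_id = 1L, column_id = 1L, instrument_id = 1L,
      instrument_column_id = 1L, is_check = FALSE, trait_id = "T",
      value = rnorm(240))
  })
  fit <- fit_trait_mixed_model(pt, "T", random_terms = c("line", "env"))
  expect_lt(max(abs(fit$blups)), 0.1 * sd(pt$value))
  expect_lt(fit$vc$components$G, 0.05)
})

test_that("REML estimates are nearly unbiased over repeated simulation", {
  truth <- c(G = 1, GE = 0.4, resid = 0.6)
  withr::with_seed(5, {
    est <- t(vapply(seq_len(200), function(r) {
      lines <- sprintf("L%02d", 1:60)
      g <- rnorm(60); ge <- matrix(rnorm(120, sd = sqrt(0.4)), 60, 2)
      pt <- do.call(rbind, lapply(1:2, function(e) data.frame(
        line_id = lines, env = e, block_id = rep(1:4, 15),
        column_id = 1L, instrument_id = 1L, instrument_column_id = 1L,
        is_check = FALSE, trait_id = "T",
        value = 5 + g + ge[, e] + rnorm(60, sd = sqrt(0.6)))))
      # two plots per line per env so GE separates from residual
      pt2 <- pt; pt2$value <- 5 + g[match(pt$line_id, lines)] +
        ge[cbind(match(pt$line_id, lines), pt$env)] + rnorm(120, sd = sqrt(0.6))
      fit <- fit_trait_mixed_model(rbind(pt, pt2), "T",
                                   random_terms = c("line", "env", "line:env"))
      unlist(fit$vc$components[c("G", "GE", "resid")])
    }, numeric(3)))
  })
  rel_bias <- abs(colMeans(est) - truth) / truth
  expect_true(all(rel_bias < 0.10))
})

test_that("residualization removes planted factors and keeps cis signals", {
  withr::with_seed(6, {
    n <- 200; m <- 150
    fac <- matrix(rnorm(n * 5), n, 5)
    lam <- matrix(rnorm(m * 5), m, 5)
    E <- tcrossprod(fac, lam) + matrix(rnorm(n * m), n, m)
  })
  res <- residualize_expression(E, k_factors = 5, screen = FALSE)
  sv <- svd(res, nu = 0, nv = 0)$d
  expect_lt(sv[1]^2 / sum(sv^2), 0.05)
  # k = 0 returns the column-standardized input
  std <- residualize_expression(E, k_factors = 0, screen = FALSE)
  expect_equal(std, scale(E), ignore_attr = TRUE)
  expect_error(residualize_expression(E, k_factors = 200), "k_factors")
})

test_that("cis-eQTL top SNPs survive factor residualization", {
  geno <- simulate_population(150, 300, c(chr1 = 1e7), seed = 8)
  lay <- simulate_gene_models(40, c(chr1 = 1e7), seed = 8)
  ex <- simulate_expression(geno, lay, cis_h2 = 0.6, n_latent_factors = 4,
                            seed = 8)
  eb <- expression_line_means(ex)
  res <- residualize_expression(eb, k_factors = 4, screen = FALSE)
  X <- scale(geno$dosages)
  cis_genes <- which(!ex$truth$no_cis)
  same <- vapply(cis_genes, function(g) {
    b1 <- which.max(abs(drop(crossprod(scale(eb[, g]), X))))
    b2 <- which.max(abs(drop(crossprod(scale(res[, g]), X))))
    b1 == b2
  }, logical(1))
  expect_gte(mean(same), 0.9)
})

test_that("the full pipeline runs in order and is idempotent for the filters", {
  geno <- simulate_population(80, 300, c(chr1 = 5e6), seed = 10)
  sim <- simulate_traits_and_gc(
    geno, class_config = wax_class_config(counts = c(PA = 2, WE = 2)),
    zero_rate_per_trait = c(PA_01 = 0.85, PA_02 = 0.05, WE_01 = 0.05,
                            WE_02 = 0), seed = 10)
  panel <- prepare_trait_panel(sim$wax, seed = 1)
  # PA_01 is censored in 85% of plots, so most lines are all-zero: dropped
  expect_false("PA_01" %in% colnames(panel$blups))
  # the filter's report is internally consistent with the strict 40% rule
  rep_ <- filter_detectable_traits(sim$wax)$report
  expect_equal(rep_$dropped, rep_$zero_frac > 0.4)
  expect_true(all(c("PA_02", "WE_01", "WE_02") %in% colnames(panel$blups)))
  expect_true(all(panel$h2 >= 0 & panel$h2 <= 1))
  # transformed columns keep at least 80% of lines
  frac_ok <- colMeans(!is.na(panel$transformed))
  expect_true(all(frac_ok >= 0.8))
  # filters are a no-op on retained, imputed data
  kept <- sim$wax[sim$wax$trait_id %in% colnames(panel$blups), ]
  class(kept) <- c("plot_table", "data.frame")
  imp <- impute_zero_abundances(kept, seed = 1)$plot_table
  again <- filter_detectable_traits(imp)
  expect_identical(sort(unique(again$plot_table$trait_id)),
                   sort(colnames(panel$blups)))
  expect_identical(impute_zero_abundances(imp, seed = 2)$plot_table$value,
                   imp$value)
})

test_that("stronger shrinkage lowers the largest BLUP magnitude", {
  withr::with_seed(12, {
    lines <- sprintf("L%02d", 1:50)
    g <- rnorm(50)
    e <- matrix(rnorm(100), 50, 2)
    mx <- vapply(c(0.5, 2, 8), function(s) {
      pt <- do.call(rbind, lapply(1:2, function(ev) data.frame(
        line_id = lines, env = ev, block_id = 1L, column_id = 1L,
        instrument_id = 1L, instrument_column_id = 1L, is_check = FALSE,
        trait_id = "T", value = g + s * e[, ev])))
      fit <- fit_trait_mixed_model(pt, "T", random_terms = c("line"))
      max(abs(fit$blups)) / sd(pt$value)
    }, numeric(1))
  })
  expect_true(all(diff(mx) < 0))
})
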