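# GWAS/TWAS integration: nearest genes, Fisher's combined test, loci,
# candidate sets, confidence groups, and shared-gene intersection.

make_layout <- function(genes, chrom_lengths = c(chr1 = 1e6)) {
  gm <- data.frame(gene_id = names(genes),
                   chrom = vapply(genes, `[[`, character(1), "chrom"),
                   start = vapply(genes, function(g) g$start, numeric(1)),
                   end = vapply(genes, function(g) g$end, numeric(1)),
                   strand = "+", stringsAsFactors = FALSE)
  gm <- gm[order(gm$chrom, gm$start), ]
  rownames(gm) <- NULL
  structure(list(chrom_lengths = as_cl(chrom_lengths), gene_models = gm),
            class = "genome_layout")
}
as_cl <- function(x) { names(x) <- names(x); x }

test_that("SNPs map to the nearest gene with documented tie-breaks", {
  lay <- make_layout(list(
    gA = list(chrom = "chr1", start = 4000, end = 6000),
    gB = list(chrom = "chr1", start = 12000, end = 13000),
    gC = list(chrom = "chr1", start = 20000, end = 21000)))
  snps <- data.frame(snp_id = c("in", "near", "tie", "far"),
                     chrom = "chr1",
                     pos = c(5000, 10000, 16500, 990000))
  asg <- nearest_gene_assignment(snps, lay)
  expect_equal(asg$gene_id[1], "gA"); expect_equal(asg$distance[1], 0)
  # 10,000 is 4,000 from gA's end but 2,000 from gB's start
  expect_equal(asg$gene_id[2], "gB"); expect_equal(asg$distance[2], 2000)
  # equidistant between gB (end 13,000) and gC (start 20,000): 16,500 is
  # 3,500 from both; the gene with the smaller start wins
  expect_equal(asg$gene_id[3], "gB")
  expect_equal(asg$gene_id[4], "gC")
  # chromosome without genes: unassigned and logged
  snps2 <- data.frame(snp_id = "s", chrom = "chr9", pos = 100)
  asg2 <- nearest_gene_assignment(snps2, lay)
  expect_true(is.na(asg2$gene_id))
  expect_equal(attr(asg2, "n_unassigned"), 1L)
})

test_that("the combined test matches its closed form and the chi-squared tail", {
  expect_equal(fisher_combine(1, 1), 1)
  # closed form: 0.05^2 * (1 - 2 ln 0.05)
  expect_equal(fisher_combine(0.05, 0.05), 0.017478661368, tolerance = 1e-9)
  expect_lt(validate_fisher_oracle(), 1e-12)
  # adding an uninformative test can only dilute the evidence
  p <- 10^seq(-10, 0, length.out = 30)
  expect_true(all(fisher_combine(p, 1) >= p))
  # strictly increasing in each argument
  expect_true(all(diff(fisher_combine(p, 0.3)) > 0))
  expect_true(all(diff(fisher_combine(0.3, p)) > 0))
  expect_warning(out <- fisher_combine(0, 0.5), "floored")
  expect_gt(out, 0)
})

test_that("the combined-test scan keeps the best SNP-gene pair and handles
           unexpressed genes", {
  lay <- make_layout(list(
    gA = list(chrom = "chr1", start = 1000, end = 2000),
    gB = list(chrom = "chr1", start = 500000, end = 501000)))
  gwas <- structure(data.frame(
    trait = "T", method = "GWAS",
    feature = sprintf("s%02d", 1:20), chrom = "chr1",
    pos = c(1500, 1800, seq(400000, 999999, length.out = 18)),
    p = c(1e-6, 1e-3, 1e-8, seq(0.1, 0.9, length.out = 17)),
    effect = 0, r2_lr = 0, rank = NA), class = c("assoc_table", "data.frame"))
  twas <- structure(data.frame(
    trait = "T", method = "TWAS", feature = "gA", chrom = "chr1", pos = 1500,
    p = 0.2, effect = 1, r2_lr = 0, rank = 1),
    class = c("assoc_table", "data.frame"))
  fct <- fct_scan(gwas, twas, lay, snp_top_frac = 0.2)  # top 4 SNPs enter
  # gA combines its best SNP (1e-6, not 1e-3) with TWAS p 0.2
  expect_equal(fct$p[fct$feature == "gA"], fisher_combine(1e-6, 0.2))
  # gB is unexpressed: TWAS p treated as 1
  expect_equal(fct$p[fct$feature == "gB"], fisher_combine(1e-8, 1))
  expect_equal(attr(fct, "n_top_snps"), 4L)
  expect_error(fct_scan(gwas[0, ], twas, lay), "empty")
})

test_that("the top-fraction rule selects the documented SNP counts", {
  expect_equal(waxomics:::top_k(2e-5, 9715072), 194L)
  expect_equal(waxomics:::top_k(2.5e-3, 20013), 50L)
  expect_equal(waxomics:::top_k(0.10, 10000), 1000L)
  expect_equal(waxomics:::top_k(2e-5, 4000), 1L)  # floor of one
})

test_that("loci are clumped greedily around successive p-minima", {
  gwas <- structure(data.frame(
    trait = "T", method = "GWAS", feature = sprintf("s%d", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr1"),
    pos = c(1e6, 1e6 + 5e4, 3e6, 1e6, 5e6, 9e6),
    p = c(1e-10, 1e-8, 1e-7, 1e-9, 1e-6, 1e-5),
    effect = 0, r2_lr = 0, rank = NA), class = c("assoc_table", "data.frame"))
  loci <- declare_gwas_loci(gwas, top_frac = 1)  # all six are top SNPs
  # s1 and s2 are 50 kb apart: one locus with the smaller p as peak
  l1 <- loci[loci$chrom == "chr1" & loci$peak_pos == 1e6, ]
  expect_equal(l1$peak_snp, "s1")
  expect_equal(l1$n_members, 2L)
  # different chromosomes never merge
  expect_equal(nrow(loci[loci$chrom == "chr2", ]), 2L)
  expect_equal(nrow(loci), 5L)
})

test_that("candidate windows are +/-200 kb and gene fractions are exact", {
  lay <- make_layout(list(
    near = list(chrom = "chr1", start = 149000, end = 151000),
    far = list(chrom = "chr1", start = 549000, end = 551000)),
    chrom_lengths = c(chr1 = 1e6))
  loci <- data.frame(trait = "T", chrom = "chr1", peak_pos = 3e5,
                     peak_snp = "s1", peak_p = 1e-9, n_members = 1)
  cand <- select_candidates(loci, lay)
  # 150 kb away: candidate; 250 kb away: not
  expect_true("near" %in% cand$gene_id)
  expect_false("far" %in% cand$gene_id)
  # 20,013 TWAS genes yield exactly 50 candidates
  twas <- structure(data.frame(
    trait = "T", method = "TWAS", feature = sprintf("g%05d", 1:20013),
    chrom = "chr1", pos = 1, p = runif(20013), effect = 0, r2_lr = 0,
    rank = NA), class = c("assoc_table", "data.frame"))
  cand2 <- select_candidates(loci[0, ], lay, twas_table = twas)
  expect_equal(sum(cand2$method == "TWAS"), 50L)
  # empty loci: empty GWAS set, no error
  cand3 <- select_candidates(loci[0, ], lay)
  expect_equal(nrow(cand3), 0L)
})

test_that("confidence groups follow the same-trait / same-class / otherwise rule", {
  class_map <- c("WE 49:0" = "WE", "WE 50:0" = "WE", "WE 54:0" = "WE",
                 "PA 26:0" = "PA", "HC 27:0" = "HC")
  cs <- data.frame(
    gene_id = c(rep("g1", 3), rep("g2", 3), rep("g3", 3), rep("g4", 2)),
    trait = c(rep("WE 49:0", 3),
              "WE 50:0", "WE 54:0", "WE 49:0",
              "PA 26:0", "HC 27:0", "WE 49:0",
              "WE 49:0", "WE 49:0"),
    method = c("GWAS", "TWAS", "FCT",
               "GWAS", "TWAS", "FCT",
               "GWAS", "TWAS", "FCT",
               "GWAS", "TWAS"),
    stringsAsFactors = FALSE)
  grp <- confidence_groups(cs, class_map)
  expect_true("g1" %in% grp$group1$gene_id)   # same compound, all methods
  expect_true("g2" %in% grp$group2$gene_id)   # same class, different compounds
  expect_true("g3" %in% grp$group3$gene_id)   # different classes
  expect_false("g4" %in% grp$all_three)       # only two methods
  # set algebra: disjoint, union equals the all-three set
  g1 <- unique(grp$group1$gene_id); g2 <- unique(grp$group2$gene_id)
  g3 <- unique(grp$group3$gene_id)
  expect_equal(length(intersect(g1, g2)), 0L)
  expect_equal(length(intersect(g1, g3)), 0L)
  expect_equal(length(intersect(g2, g3)), 0L)
  expect_setequal(c(g1, g2, g3), grp$all_three)
})

test_that("group partition is exhaustive over random candidate sets", {
  withr::with_seed(50, {
    for (r in 1:20) {
      genes <- sprintf("g%02d", 1:15)
      traits <- sprintf("t%d", 1:6)
      class_map <- setNames(sample(wax_classes(), 6, replace = TRUE), traits)
      cs <- data.frame(
        gene_id = sample(genes, 60, replace = TRUE),
        trait = sample(traits, 60, replace = TRUE),
        method = sample(c("GWAS", "TWAS", "FCT"), 60, replace = TRUE),
        stringsAsFactors = FALSE)
      grp <- confidence_groups(cs, class_map)
      all_g <- unique(c(grp$group1$gene_id, grp$group2$gene_id,
                        grp$group3$gene_id))
      expect_setequal(all_g, grp$all_three)
    }
  })
})

test_that("shared conductance/wax genes are intersected per method", {
  gc_cand <- data.frame(gene_id = c("gA", "gB", "gC", "gC"),
                        trait = "gc",
                        method = c("GWAS", "TWAS", "TWAS", "FCT"),
                        stringsAsFactors = FALSE)
  wax_cand <- data.frame(gene_id = c("gA", "gC", "gC", "gZ"),
                         trait = c("WE 49:0", "PA 26:0", "HC 27:0", "WE 50:0"),
                         method = c("GWAS", "TWAS", "FCT", "GWAS"),
                         stringsAsFactors = FALSE)
  sh <- shared_candidates(gc_cand, wax_cand)
  expect_true(all(c("gA", "gC") %in% sh$gene_id))
  expect_false("gB" %in% sh$gene_id)  # wax never found gB by TWAS
  expect_false("gZ" %in% sh$gene_id)  # conductance never found gZ
  expect_equal(sh$method[sh$gene_id == "gA"], "GWAS")
  # gC is shared under both TWAS and FCT: multi-method flag set
  expect_true(all(sh$multi_method[sh$gene_id == "gC"]))
  expect_false(any(sh$multi_method[sh$gene_id == "gA"]))
  # disjoint sets give an empty table
  none <- shared_candidates(gc_cand[1, ], wax_cand[4, ])
  expect_equal(nrow(none), 0L)
})
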