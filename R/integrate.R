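# Integration of GWAS and TWAS evidence: nearest-gene assignment, Fisher's
# combined test, locus declaration, candidate sets, confidence groups, and
# the conductance/wax shared-gene intersection.

#' Assign SNPs to their nearest gene
#'
#' Each SNP maps to the gene minimizing the distance from the SNP position
#' to the gene interval (0 when the SNP lies inside the gene). Ties are
#' broken by the smaller gene start, then by lexicographic gene id. SNPs on
#' chromosomes without genes stay unassigned (`NA`) and are counted in the
#' attribute `n_unassigned`.
#'
#' @param snp_table data frame with columns `feature` (or `snp_id`),
#'   `chrom`, `pos`, and optionally `p`.
#' @param layout a `genome_layout`.
#' @return data frame `snp_id`, `gene_id`, `distance` (bp), plus `gwas_p`
#'   when the input carries p-values.
#' @export
nearest_gene_assignment <- function(snp_table, layout) {
  gm <- layout$gene_models
  snp_id <- if ("feature" %in% names(snp_table)) snp_table$feature else
    snp_table$snp_id
  out <- data.frame(snp_id = snp_id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (chr in unique(snp_table$chrom)) {
    gi <- which(gm$chrom == chr)
    si <- which(snp_table$chrom == chr)
    if (length(gi) == 0L || length(si) == 0L) next
    g <- gm[gi, , drop = FALSE]   # sorted by start, non-overlapping
    pos <- snp_table$pos[si]
    # candidate genes: the last one starting at or before the SNP, plus the next
    k <- findInterval(pos, g$start)
    best_gene <- character(length(pos))
    best_dist <- numeric(length(pos))
    for (ii in seq_along(pos)) {
      cand <- unique(pmax(1L, pmin(nrow(g), c(k[ii], k[ii] + 1L))))
      if (k[ii] == 0L) cand <- 1L
      d <- pmax(0, g$start[cand] - pos[ii], pos[ii] - g$end[cand])
      ord <- order(d, g$start[cand], g$gene_id[cand])
      best_gene[ii] <- g$gene_id[cand[ord[1]]]
      best_dist[ii] <- d[ord[1]]
    }
    out$gene_id[si] <- best_gene
    out$distance[si] <- best_dist
  }
  if ("p" %in% names(snp_table)) out$gwas_p <- snp_table$p
  attr(out, "n_unassigned") <- sum(is.na(out$gene_id))
  out
}

#' Fisher's combined probability for a GWAS/TWAS pair
#'
#' Combines two p-values with the sumlog method:
#' \eqn{X = -2(\ln p_1 + \ln p_2)} is chi-squared with 4 degrees of freedom
#' under the joint null, giving \eqn{p = e^{-X/2}(1 + X/2)} in closed form.
#' Computed in log space for numerical stability; zero inputs are floored at
#' the smallest positive normal double with a warning.
#'
#' @param p_gwas,p_twas p-values in (0, 1] (vectorized).
#' @return combined p-value(s).
#' @examples
#' fisher_combine(0.05, 0.05)  # ~0.01744
#' @export
fisher_combine <- function(p_gwas, p_twas) {
  fl <- .Machine$double.xmin
  if (any(p_gwas <= 0) || any(p_twas <= 0)) {
    warning("zero p-value(s) floored at the smallest positive double")
    p_gwas <- pmax(p_gwas, fl)
    p_twas <- pmax(p_twas, fl)
  }
  if (any(p_gwas > 1) || any(p_twas > 1)) stop("p-values must be in (0, 1]")
  x <- -2 * (log(p_gwas) + log(p_twas))
  # exp(-x/2) * (1 + x/2), stable in log space
  exp(-x / 2 + log1p(x / 2))
}

#' Fisher's combined test scan over a trait
#'
#' Integrates a GWAS and a TWAS scan of the same trait: the top
#' `snp_top_frac` of SNPs by GWAS p-value are assigned to their nearest
#' gene; if several SNPs land on one gene only the most significant SNP-gene
#' pair is kept; each gene's GWAS p is paired with its TWAS p (1 for genes
#' never tested by TWAS, which lets purely GWAS-supported genes enter the
#' test); the pair is combined with [fisher_combine()]. Genes with neither
#' an assigned SNP nor expression are absent from the result.
#'
#' @param gwas_table `assoc_table` from [gwas_scan()].
#' @param twas_table `assoc_table` from [twas_scan()] for the same trait.
#' @param layout a `genome_layout`.
#' @param snp_top_frac fraction of SNPs entering assignment (default 10
#'   percent).
#' @return an `assoc_table` (method `"FCT"`) with one row per gene; `effect`
#'   is `NA`, `pos` is the gene midpoint.
#' @export
fct_scan <- function(gwas_table, twas_table, layout, snp_top_frac = 0.10) {
  if (nrow(gwas_table) == 0L) stop("empty GWAS table")
  k <- top_k(snp_top_frac, nrow(gwas_table))
  top <- gwas_table[order(gwas_table$p), , drop = FALSE][seq_len(k), ]
  asg <- nearest_gene_assignment(top, layout)
  asg <- asg[!is.na(asg$gene_id), , drop = FALSE]
  # best SNP-gene pair per gene (minimum GWAS p)
  best <- tapply(asg$gwas_p, asg$gene_id, min)
  genes <- names(best)
  twas_p <- twas_table$p[match(genes, twas_table$feature)]
  twas_p[is.na(twas_p)] <- 1
  p_comb <- fisher_combine(as.numeric(best), twas_p)

  gm <- layout$gene_models
  i <- match(genes, gm$gene_id)
  out <- .assoc_table(gwas_table$trait[1], "FCT", genes, gm$chrom[i],
                      as.integer(round((gm$start[i] + gm$end[i]) / 2)),
                      p_comb, NA_real_, NA_real_)
  attr(out, "n_top_snps") <- k
  out
}

#' Declare GWAS loci from top SNPs
#'
#' Takes the top `max(1, round(top_frac * N))` SNPs of a scan and clusters
#' them greedily: the most significant unclustered SNP becomes a peak and
#' absorbs every remaining top SNP within `clump_bp` on the same chromosome,
#' repeating until all top SNPs are assigned.
#'
#' @param gwas_table `assoc_table` from [gwas_scan()].
#' @param top_frac top fraction of SNPs used to declare loci (default
#'   0.002 percent).
#' @param clump_bp clustering distance; the default matches a panel whose LD
#'   decays by about 200 kb.
#' @return data frame of loci: `trait`, `chrom`, `peak_pos`, `peak_snp`,
#'   `peak_p`, `n_members`, with member SNP ids in the list column
#'   `members`.
#' @export
declare_gwas_loci <- function(gwas_table, top_frac = 2e-5, clump_bp = 2e5) {
  if (nrow(gwas_table) < 1L) stop("empty GWAS table")
  k <- top_k(top_frac, nrow(gwas_table))
  top <- gwas_table[order(gwas_table$p), , drop = FALSE][seq_len(k), ]
  top$used <- FALSE
  loci <- list()
  while (any(!top$used)) {
    i <- which(!top$used)[which.min(top$p[!top$used])]
    near <- !top$used & top$chrom == top$chrom[i] &
      abs(top$pos - top$pos[i]) <= clump_bp
    loci[[length(loci) + 1L]] <- data.frame(
      trait = top$trait[i], chrom = top$chrom[i], peak_pos = top$pos[i],
      peak_snp = top$feature[i], peak_p = top$p[i],
      n_members = sum(near), stringsAsFactors = FALSE)
    loci[[length(loci)]]$members <- list(top$feature[near])
    top$used[near] <- TRUE
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Candidate genes per association method
#'
#' GWAS candidates are all genes overlapping a `interval_bp` window either
#' side of each declared locus peak (windows running past a chromosome end
#' are truncated silently); TWAS and FCT candidates are the top
#' `max(1, round(gene_top_frac * n_genes))` genes of the respective scans,
#' where `n_genes` counts the genes testable by that method.
#'
#' @param loci output of [declare_gwas_loci()] (may have zero rows).
#' @param layout a `genome_layout`.
#' @param twas_table,fct_table `assoc_table`s for the same trait (either may
#'   be `NULL` to skip that method).
#' @param interval_bp half-width of the GWAS gene search window.
#' @param gene_top_frac top fraction of genes kept from TWAS/FCT.
#' @return data frame `gene_id`, `trait`, `method`, `rank`, `peak_snp`
#'   (`NA` for TWAS/FCT entries).
#' @export
select_candidates <- function(loci, layout, twas_table = NULL,
                              fct_table = NULL, interval_bp = 2e5,
                              gene_top_frac = 2.5e-3) {
  gm <- layout$gene_models
  out <- list()
  if (!is.null(loci) && nrow(loci) > 0) {
    for (i in seq_len(nrow(loci))) {
      lo <- max(1, loci$peak_pos[i] - interval_bp)
      hi <- min(layout$chrom_lengths[[loci$chrom[i]]],
                loci$peak_pos[i] + interval_bp)
      hit <- gm$chrom == loci$chrom[i] & gm$end >= lo & gm$start <= hi
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gm$gene_id[hit], trait = loci$trait[i], method = "GWAS",
          rank = i, peak_snp = loci$peak_snp[i], stringsAsFactors = FALSE)
      }
    }
  }
  for (mt in c("TWAS", "FCT")) {
    tab <- if (mt == "TWAS") twas_table else fct_table
    if (is.null(tab) || nrow(tab) == 0L) next
    k <- top_k(gene_top_frac, nrow(tab))
    top <- tab[order(tab$p), , drop = FALSE][seq_len(k), ]
    out[[length(out) + 1L]] <- data.frame(
      gene_id = top$feature, trait = top$trait, method = mt,
      rank = seq_len(k), peak_snp = NA_character_, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), trait = character(),
               method = character(), rank = integer(),
               peak_snp = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  unique(res)
}

#' Partition triple-evidence genes into confidence groups
#'
#' Genes detected by all three methods (GWAS, TWAS, FCT) across any traits
#' are split into: group 1 -- some single trait is hit by all three methods;
#' group 2 -- not group 1, but all three methods hit traits sharing a wax
#' class; group 3 -- the rest (different classes by different methods). The
#' three groups are disjoint and their union is exactly the
#' all-three-methods gene set.
#'
#' @param candidate_sets data frame as returned by [select_candidates()],
#'   accumulated over traits (columns `gene_id`, `trait`, `method`).
#' @param class_map named character vector mapping trait id to wax class.
#' @return object of class `confidence_groups`: list of data frames
#'   `group1`, `group2`, `group3` (columns `gene_id` and the supporting
#'   evidence), plus `all_three` (the gene ids).
#' @export
confidence_groups <- function(candidate_sets, class_map) {
  cs <- candidate_sets
  methods_by_gene <- tapply(cs$method, cs$gene_id, function(m) unique(m))
  all3 <- names(methods_by_gene)[vapply(methods_by_gene, function(m)
    all(c("GWAS", "TWAS", "FCT") %in% m), logical(1))]

  assign_group <- function(g) {
    d <- cs[cs$gene_id == g, , drop = FALSE]
    by_trait <- tapply(d$method, d$trait, function(m) unique(m))
    if (any(vapply(by_trait, function(m)
      all(c("GWAS", "TWAS", "FCT") %in% m), logical(1)))) return(1L)
    cls <- split(class_map[d$trait], d$method)
    shared <- Reduce(intersect, lapply(cls, unique))
    shared <- shared[!is.na(shared)]
    if (length(shared) > 0) return(2L)
    3L
  }
  grp <- vapply(all3, assign_group, integer(1))
  mk <- function(k) {
    g <- all3[grp == k]
    d <- cs[cs$gene_id %in% g, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  structure(list(group1 = mk(1L), group2 = mk(2L), group3 = mk(3L),
                 all_three = all3,
                 sizes = c(group1 = sum(grp == 1), group2 = sum(grp == 2),
                           group3 = sum(grp == 3))),
            class = "confidence_groups")
}

#' @export
print.confidence_groups <- function(x, ...) {
  cat(sprintf(
    "confidence_groups: %d genes by all 3 methods (g1 %d, g2 %d, g3 %d)\n",
    length(x$all_three), x$sizes[1], x$sizes[2], x$sizes[3]))
  invisible(x)
}

#' Genes shared between conductance and wax candidate sets
#'
#' Per-method intersection of the candidate genes for cuticular conductance
#' and for the wax traits: a gene is reported under a method when that
#' method detected it for conductance and for at least one wax trait. Genes
#' recovered by more than one method carry `multi_method = TRUE`.
#'
#' @param gc_candidate_sets,wax_candidate_sets data frames as returned by
#'   [select_candidates()].
#' @return data frame `gene_id`, `method`, `wax_traits` (comma-separated),
#'   `multi_method`.
#' @export
shared_candidates <- function(gc_candidate_sets, wax_candidate_sets) {
  rows <- list()
  for (mt in c("GWAS", "TWAS", "FCT")) {
    g_gc <- unique(gc_candidate_sets$gene_id[gc_candidate_sets$method == mt])
    wx <- wax_candidate_sets[wax_candidate_sets$method == mt, , drop = FALSE]
    shared <- intersect(g_gc, wx$gene_id)
    if (length(shared) == 0L) next
    rows[[mt]] <- data.frame(
      gene_id = shared, method = mt,
      wax_traits = vapply(shared, function(g)
        paste(sort(unique(wx$trait[wx$gene_id == g])), collapse = ","),
        character(1)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), method = character(),
               wax_traits = character(), stringsAsFactors = FALSE)
  n_meth <- table(out$gene_id)
  out$multi_method <- as.vector(n_meth[out$gene_id] > 1)
  rownames(out) <- NULL
  out
}
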