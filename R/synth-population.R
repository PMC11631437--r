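#' Simulate a structured inbred genotype panel
#'
#' Generates biallelic SNP dosages for a panel of inbred lines with linkage
#' disequilibrium (LD) that decays with physical distance and optional
#' population structure. LD is induced by a Gaussian autoregressive copula
#' over the ordered SNP positions: the latent correlation between adjacent
#' SNPs is `exp(-d / ld_decay_bp)` for distance `d` within a chromosome and
#' zero across chromosomes. Subpopulation allele-frequency divergence follows
#' the Balding-Nichols model with differentiation `fst`.
#'
#' Lines are fully homozygous by default, so dosages are in \{0, 2\}; a
#' positive `het_rate` lets the two alleles of that fraction of entries
#' segregate independently, producing \{0, 1, 2\}. Realized (finite-sample)
#' minor allele frequencies are constrained to `maf_range`: any SNP drifting
#' outside the range is redrawn (with fresh allele frequencies and
#' independent latent values) until it complies.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param n_snps total number of SNPs across the genome.
#' @param chrom_lengths named numeric vector (or two-column data frame) of
#'   chromosome lengths in bp.
#' @param maf_range length-2 numeric, the admissible minor-allele-frequency
#'   interval, a subset of (0, 0.5].
#' @param ld_decay_bp distance at which latent LD decays by `1/e`; default
#'   200 kb, the scale at which LD in diverse maize panels reaches nominal
#'   levels.
#' @param n_subpops number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols differentiation among subpopulations.
#' @param het_rate fraction of entries whose alleles segregate independently.
#' @param seed integer seed; identical seeds reproduce the output bit-exactly.
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (lines x SNPs integer matrix), `snp_meta` (data frame with `snp_id`,
#'   `chrom`, `pos`, `maf`, `dr2`), `line_ids`, and `subpop` (integer
#'   subpopulation labels per line).
#' @examples
#' geno <- simulate_population(50, 200, c(chr1 = 1e6), seed = 1)
#' dim(geno$dosages)
#' @export
simulate_population <- function(n_lines, n_snps,
                                chrom_lengths,
                                maf_range = c(0.05, 0.5),
                                ld_decay_bp = 2e5,
                                n_subpops = 1,
                                fst = 0,
                                het_rate = 0,
                                seed = 1) {
  if (n_lines < 2 || n_snps < 1) {
    stop("n_lines must be >= 2 and n_snps >= 1")
  }
  if (ld_decay_bp <= 0) stop("ld_decay_bp must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  chrom_lengths <- as_chrom_lengths(chrom_lengths)

  withr::with_seed(seed, {
    per_chrom <- apportion(n_snps, chrom_lengths)
    line_ids <- sprintf("L%03d", seq_len(n_lines))
    subpop <- rep(seq_len(max(1L, n_subpops)), length.out = n_lines)
    subpop <- sort(subpop)

    dosages <- matrix(0L, n_lines, n_snps)
    chrom <- character(n_snps)
    pos <- integer(n_snps)

    draw_freqs <- function() {
      p0 <- stats::runif(1, maf_range[1], maf_range[2])
      if (n_subpops > 1 && fst > 0) {
        a <- p0 * (1 - fst) / fst
        b <- (1 - p0) * (1 - fst) / fst
        stats::rbeta(n_subpops, a, b)
      } else {
        rep(p0, max(1L, n_subpops))
      }
    }
    genotype_col <- function(u, p_sub) {
      p_line <- p_sub[subpop]
      g <- 2L * as.integer(u < p_line)
      if (het_rate > 0) {
        flip <- stats::runif(n_lines) < het_rate
        if (any(flip)) {
          u2 <- stats::runif(sum(flip))
          g[flip] <- as.integer(u[flip] < p_line[flip]) +
            as.integer(u2 < p_line[flip])
        }
      }
      g
    }

    j <- 0L
    for (c_i in seq_along(chrom_lengths)) {
      m <- per_chrom[c_i]
      if (m == 0L) next
      cl <- chrom_lengths[c_i]
      if (m > cl) stop("more SNPs than positions on chromosome ", names(chrom_lengths)[c_i])
      p_chr <- sort(sample.int(cl, m))
      z_prev <- NULL
      for (k in seq_len(m)) {
        j <- j + 1L
        chrom[j] <- names(chrom_lengths)[c_i]
        pos[j] <- p_chr[k]
        if (is.null(z_prev)) {
          z <- stats::rnorm(n_lines)
        } else {
          rho <- exp(-(p_chr[k] - p_chr[k - 1]) / ld_decay_bp)
          z <- rho * z_prev + sqrt(1 - rho^2) * stats::rnorm(n_lines)
        }
        z_prev <- z
        p_sub <- draw_freqs()
        g <- genotype_col(stats::pnorm(z), p_sub)
        # enforce the finite-sample MAF contract by redrawing drifting SNPs
        tries <- 0L
        repeat {
          f <- mean(g) / 2
          maf <- min(f, 1 - f)
          if (maf >= maf_range[1] - 1e-12 && maf <= maf_range[2] + 1e-12 &&
              maf > 0) break
          tries <- tries + 1L
          if (tries > 500L) stop("could not satisfy maf_range for a SNP; widen the range")
          p_sub <- draw_freqs()
          g <- genotype_col(stats::runif(n_lines), p_sub)
        }
        dosages[, j] <- g
      }
    }

    snp_id <- sprintf("snp_%06d", seq_len(n_snps))
    dimnames(dosages) <- list(line_ids, snp_id)
    f <- colMeans(dosages) / 2
    snp_meta <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      maf = pmin(f, 1 - f), dr2 = 1.0,
      stringsAsFactors = FALSE
    )
    structure(
      list(dosages = dosages, snp_meta = snp_meta,
           line_ids = line_ids, subpop = subpop,
           chrom_lengths = chrom_lengths),
      class = "genotype_matrix"
    )
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(x$chrom_lengths)))
  cat(sprintf("  MAF range [%.3f, %.3f], %d subpopulation(s)\n",
              min(x$snp_meta$maf), max(x$snp_meta$maf), length(unique(x$subpop))))
  invisible(x)
}

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` non-overlapping gene intervals on the given chromosomes,
#' apportioned by chromosome length. Coordinates are 1-based inclusive (GFF3
#' convention), genes are sorted by (chromosome, start) and never overlap.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param min_len,max_len gene length bounds in bp.
#' @param seed integer seed.
#' @return an object of class `genome_layout`: list with `chrom_lengths` and
#'   `gene_models` (data frame `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @examples
#' lay <- simulate_gene_models(20, c(chr1 = 1e6), seed = 1)
#' head(lay$gene_models)
#' @export
simulate_gene_models <- function(n_genes, chrom_lengths,
                                 min_len = 2000, max_len = 6000,
                                 seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (min_len <= 0 || min_len > max_len) stop("need 0 < min_len <= max_len")
  chrom_lengths <- as_chrom_lengths(chrom_lengths)

  withr::with_seed(seed, {
    per_chrom <- apportion(n_genes, chrom_lengths)
    rows <- vector("list", length(chrom_lengths))
    for (c_i in seq_along(chrom_lengths)) {
      m <- per_chrom[c_i]
      if (m == 0L) next
      cl <- chrom_lengths[c_i]
      lens <- if (min_len == max_len) rep(min_len, m) else
        sample(seq.int(min_len, max_len), m, replace = TRUE)
      free <- cl - sum(lens)
      if (free < 0) {
        stop("genes cannot fit on chromosome ", names(chrom_lengths)[c_i],
             " without overlap")
      }
      # sorted random offsets into the free space guarantee non-overlap
      off <- sort(sample.int(free + 1, m, replace = TRUE) - 1L)
      start <- off + c(0L, cumsum(lens[-m])) + 1L
      rows[[c_i]] <- data.frame(
        chrom = names(chrom_lengths)[c_i],
        start = start, end = start + lens - 1L,
        strand = sample(c("+", "-"), m, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    gm <- do.call(rbind, rows)
    gm <- gm[order(match(gm$chrom, names(chrom_lengths)), gm$start), , drop = FALSE]
    gm <- data.frame(gene_id = sprintf("gene_%05d", seq_len(nrow(gm))), gm,
                     stringsAsFactors = FALSE)
    rownames(gm) <- NULL
    structure(list(chrom_lengths = chrom_lengths, gene_models = gm),
              class = "genome_layout")
  })
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d genes on %d chromosome(s)\n",
              nrow(x$gene_models), length(x$chrom_lengths)))
  invisible(x)
}
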