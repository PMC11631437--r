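#' Simulate cis-regulated gene expression with latent confounders
#'
#' For every gene in `layout`, expression across lines is built from a
#' cis-genetic component, shared latent factors (technical / hidden
#' confounders of the kind latent-factor residualization is meant to remove),
#' a sequencing-lane effect, and residual noise:
#'
#' \deqn{e_{ige} = \mu_g + \sqrt{h^2_{cis}}\,\tilde x_{i,s(g)} +
#'   \sum_k \lambda_{gk} f_{ik} + lane_{l(i,e),g} + \epsilon_{ige}}
#'
#' where \eqn{\tilde x_{i,s(g)}} is the standardized dosage of one SNP drawn
#' uniformly from within `cis_window_bp` of the gene. Factor scores
#' \eqn{f_{ik}} are standard normal per line and shared across environments;
#' loadings \eqn{\lambda_{gk}} are N(0, `factor_sd`^2). The lane and residual
#' standard deviations scale with `noise_sd` so that `noise_sd = 0` with no
#' factors and no cis effect yields expression constant across lines.
#' Environment replicates share the genetic (cis) and factor values.
#'
#' Genes with `cis_h2 > 0` but no SNP inside the cis window get a zero cis
#' effect and are flagged in the truth record (`no_cis = TRUE`).
#'
#' @param genotypes a `genotype_matrix`.
#' @param layout a `genome_layout`.
#' @param cis_window_bp half-width of the cis window around the gene interval.
#' @param cis_h2 variance share of the cis effect relative to a unit
#'   residual budget, in `[0, 1)`.
#' @param n_latent_factors number of shared latent factors (>= 0).
#' @param factor_sd standard deviation of factor loadings.
#' @param noise_sd scale of the non-genetic noise (lane + residual).
#' @param n_envs number of environment replicates.
#' @param n_lanes sequencing lanes per environment.
#' @param lane_frac fraction of `noise_sd` assigned to the lane effect.
#' @param seed integer seed.
#' @return list with `expr` (array lines x genes x envs), `genetic_values`
#'   (lines x genes matrix, the cis components), `truth` (data frame
#'   `gene_id`, `cis_snp`, `cis_h2`, `no_cis`), `loadings`, `factors`, and
#'   `lane` (lane assignment, lines x envs).
#' @examples
#' geno <- simulate_population(40, 100, c(chr1 = 1e6), seed = 1)
#' lay  <- simulate_gene_models(10, c(chr1 = 1e6), seed = 1)
#' ex   <- simulate_expression(geno, lay, cis_h2 = 0.5, seed = 2)
#' dim(ex$expr)
#' @export
simulate_expression <- function(genotypes, layout,
                                cis_window_bp = 1e5,
                                cis_h2 = 0.4,
                                n_latent_factors = 5,
                                factor_sd = 0.5,
                                noise_sd = 1,
                                n_envs = 2,
                                n_lanes = 8,
                                lane_frac = 0.3,
                                seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(layout, "genome_layout"))
  if (cis_h2 < 0 || cis_h2 >= 1) stop("cis_h2 must be in [0, 1)")
  if (n_latent_factors < 0) stop("n_latent_factors must be >= 0")

  gm <- layout$gene_models
  meta <- genotypes$snp_meta
  X <- genotypes$dosages
  n <- nrow(X)
  n_genes <- nrow(gm)

  withr::with_seed(seed, {
    # latent factor scores per line, shared across environments
    fac <- if (n_latent_factors > 0) {
      matrix(stats::rnorm(n * n_latent_factors), n, n_latent_factors)
    } else {
      matrix(0, n, 0)
    }
    loadings <- if (n_latent_factors > 0) {
      matrix(stats::rnorm(n_genes * n_latent_factors, sd = factor_sd),
             n_genes, n_latent_factors)
    } else {
      matrix(0, n_genes, 0)
    }
    lane <- matrix(sample.int(n_lanes, n * n_envs, replace = TRUE), n, n_envs)

    mu <- stats::rnorm(n_genes)
    cis_snp <- rep(NA_character_, n_genes)
    no_cis <- rep(FALSE, n_genes)
    gvals <- matrix(0, n, n_genes, dimnames = list(genotypes$line_ids, gm$gene_id))

    for (g in seq_len(n_genes)) {
      if (cis_h2 > 0) {
        in_win <- meta$chrom == gm$chrom[g] &
          meta$pos >= gm$start[g] - cis_window_bp &
          meta$pos <= gm$end[g] + cis_window_bp
        idx <- which(in_win)
        if (length(idx) == 0L) {
          no_cis[g] <- TRUE
        } else {
          s <- if (length(idx) == 1L) idx else sample(idx, 1L)
          cis_snp[g] <- meta$snp_id[s]
          x <- X[, s]
          sdx <- stats::sd(x)
          if (sdx > 0) gvals[, g] <- sqrt(cis_h2) * (x - mean(x)) / sdx
        }
      }
    }

    lane_sd <- noise_sd * lane_frac
    res_sd <- noise_sd * sqrt(max(0, 1 - lane_frac^2)) * sqrt(1 - cis_h2)
    expr <- array(0, dim = c(n, n_genes, n_envs),
                  dimnames = list(genotypes$line_ids, gm$gene_id,
                                  paste0("env", seq_len(n_envs))))
    base <- sweep(gvals + fac %*% t(loadings), 2, mu, "+")
    for (e in seq_len(n_envs)) {
      lane_eff <- matrix(stats::rnorm(n_lanes * n_genes, sd = lane_sd),
                         n_lanes, n_genes)
      expr[, , e] <- base + lane_eff[lane[, e], , drop = FALSE] +
        matrix(stats::rnorm(n * n_genes, sd = res_sd), n, n_genes)
    }

    list(
      expr = expr,
      genetic_values = gvals,
      truth = data.frame(gene_id = gm$gene_id, cis_snp = cis_snp,
                         cis_h2 = ifelse(no_cis, 0, cis_h2), no_cis = no_cis,
                         stringsAsFactors = FALSE),
      loadings = loadings, factors = fac, lane = lane
    )
  })
}

#' Combine expression replicates into per-line values
#'
#' Averages the environment replicates of a simulated expression array into a
#' single lines x genes matrix. With the balanced one-plot-per-environment
#' replication used by the simulator, the line mean is the natural combined
#' expression value fed to latent-factor residualization.
#'
#' @param expr_sim output of [simulate_expression()].
#' @return lines x genes numeric matrix.
#' @export
expression_line_means <- function(expr_sim) {
  apply(expr_sim$expr, c(1, 2), mean)
}
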