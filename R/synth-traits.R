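#' Wax trait class configuration
#'
#' Defines the compound panel: how many compound traits each of the six
#' cuticular wax classes contains, and the fraction of each trait's causal
#' loci drawn from a class-shared pool (which induces the within-class trait
#' correlations seen in real wax panels). The default counts reproduce the
#' standard adult-leaf panel: 7 primary alcohols (PA), 11 free fatty acids
#' (FA), 9 hydrocarbons (HC), 4 aldehydes (AD), 14 wax esters (WE), and 8
#' alicyclics (AC) -- 53 compounds, which with the 6 class sums and the grand
#' total gives 60 traits.
#'
#' @param counts named integer vector of compounds per class; names must be
#'   drawn from PA, FA, HC, AD, WE, AC.
#' @param shared_frac fraction of causal SNPs per trait drawn from its
#'   class-shared pool (0 = independent traits).
#' @return list with `traits` (data frame `trait_id`, `class`) and
#'   `shared_frac`.
#' @export
wax_class_config <- function(counts = c(PA = 7, FA = 11, HC = 9,
                                        AD = 4, WE = 14, AC = 8),
                             shared_frac = 0.6) {
  stopifnot(all(names(counts) %in% wax_classes()), all(counts >= 1))
  traits <- do.call(rbind, lapply(names(counts), function(cl) {
    data.frame(trait_id = sprintf("%s_%02d", cl, seq_len(counts[[cl]])),
               class = cl, stringsAsFactors = FALSE)
  }))
  list(traits = traits, shared_frac = shared_frac)
}

#' The six cuticular wax classes
#' @return character vector of class codes.
#' @export
wax_classes <- function() c("PA", "FA", "HC", "AD", "WE", "AC")

#' Trait registry for a class configuration
#'
#' Expands a class configuration into the full trait panel: compound traits,
#' one sum trait per class (total mass of the class), and the grand total.
#'
#' @param class_config output of [wax_class_config()].
#' @return data frame with `trait_id`, `class`, `is_sum`; the attribute
#'   `counts` holds `n_compounds`, `n_sums`, `n_traits`.
#' @examples
#' reg <- trait_registry(wax_class_config())
#' attr(reg, "counts")  # 53 compounds, 7 sums, 60 traits
#' @export
trait_registry <- function(class_config = wax_class_config()) {
  tr <- class_config$traits
  classes <- unique(tr$class)
  reg <- rbind(
    data.frame(trait_id = tr$trait_id, class = tr$class, is_sum = FALSE,
               stringsAsFactors = FALSE),
    data.frame(trait_id = paste0(classes, "_total"), class = classes,
               is_sum = TRUE, stringsAsFactors = FALSE),
    data.frame(trait_id = "wax_total", class = "TOTAL", is_sum = TRUE,
               stringsAsFactors = FALSE)
  )
  rownames(reg) <- NULL
  attr(reg, "counts") <- c(
    n_compounds = sum(!reg$is_sum),
    n_sums = sum(reg$is_sum),
    n_traits = nrow(reg)
  )
  reg
}

#' Field and instrument design for the trait simulator
#'
#' The default mirrors a two-environment augmented field trial: one plot per
#' line per environment, incomplete blocks and column positions nested in
#' environment, a repeated check line in every block, and measurement on two
#' GC-FID instruments with two columns each.
#'
#' @param n_envs,n_blocks,n_columns,n_instruments,n_instr_columns design sizes.
#' @param include_check add one check plot per block per environment.
#' @param check_id line id used for the check.
#' @return list of design settings.
#' @export
field_design <- function(n_envs = 2, n_blocks = 8, n_columns = 12,
                         n_instruments = 2, n_instr_columns = 2,
                         include_check = TRUE, check_id = "CHECK") {
  list(n_envs = n_envs, n_blocks = n_blocks, n_columns = n_columns,
       n_instruments = n_instruments, n_instr_columns = n_instr_columns,
       include_check = include_check, check_id = check_id)
}

#' Ground-truth specification for the trait simulator
#'
#' Variance components are on the plot-value scale. The defaults give an
#' expected line-mean heritability of about 0.74 under the default design
#' (2 environments, 1 plot each), in the middle of the range observed for
#' real wax traits.
#'
#' @param n_causal_snps causal SNPs per compound trait.
#' @param n_causal_genes causal (cis-regulated expression) genes per trait;
#'   used only when an expression simulation is supplied.
#' @param gene_effect_sd standard deviation of causal-gene effects relative
#'   to SNP effects.
#' @param variance_components named list with elements `G`, `GE`, `env`,
#'   `block`, `col`, `instr`, `instr_col`, `resid` (all >= 0).
#' @param gc_weights named numeric vector of weights on trait genetic values
#'   defining cuticular conductance; `NULL` selects the default (five wax
#'   esters and one free fatty acid, mirroring the compounds that dominate
#'   conductance prediction in real panels).
#' @param gc_noise_sd non-genetic noise of the conductance phenotype.
#' @param class_means named baseline abundance per class (micrograms per
#'   square decimeter).
#' @param check_effect_sd spread of the per-trait check-line offset.
#' @return list of specification settings.
#' @export
wax_truth_spec <- function(n_causal_snps = 5,
                           n_causal_genes = 1,
                           gene_effect_sd = 1,
                           variance_components = list(
                             G = 1, GE = 0.25, env = 0.5, block = 0.1,
                             col = 0.05, instr = 0.05, instr_col = 0.05,
                             resid = 0.5),
                           gc_weights = NULL,
                           gc_noise_sd = 0.5,
                           class_means = c(PA = 5, FA = 4, HC = 8,
                                           AD = 3, WE = 4, AC = 5),
                           check_effect_sd = 0.5) {
  if (any(unlist(variance_components) < 0)) stop("variances must be >= 0")
  list(n_causal_snps = n_causal_snps, n_causal_genes = n_causal_genes,
       gene_effect_sd = gene_effect_sd,
       variance_components = variance_components,
       gc_weights = gc_weights, gc_noise_sd = gc_noise_sd,
       class_means = class_means, check_effect_sd = check_effect_sd)
}

#' Simulate plot-level wax traits and cuticular conductance
#'
#' Builds a long-format plot table of zero-inflated wax abundances with the
#' random-effect structure the downstream mixed model assumes (genotype,
#' environment, genotype-by-environment, block and column nested in
#' environment, instrument, and column nested in instrument), plus a
#' conductance phenotype driven by a weighted sum of trait genetic values.
#'
#' Each compound trait's genetic value is a sum of standardized-dosage SNP
#' effects (partly shared within its wax class, see [wax_class_config()]) and
#' optionally of cis-genetic expression values of causal genes, rescaled so
#' its variance equals the specified genotypic variance. Zeros arise by
#' left-censoring at a per-trait detection threshold chosen as the
#' `zero_rate` quantile of the latent plot values, mimicking a limit of
#' detection. Class sums and the grand total are computed from the censored
#' compound values (so sum traits are internally consistent with their
#' components) and are never re-censored.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression optional output of [simulate_expression()]; enables
#'   causal-gene effects.
#' @param layout optional `genome_layout` (recorded for provenance).
#' @param class_config output of [wax_class_config()].
#' @param truth_spec output of [wax_truth_spec()].
#' @param design output of [field_design()].
#' @param zero_rate_per_trait scalar or named vector of target zero rates.
#' @param seed integer seed.
#' @return list with `wax` (plot table, class `plot_table`), `gc` (plot
#'   table of conductance), and `truth` (class `truth_record`: causal SNPs
#'   and genes per trait, variance components, conductance weights and noise,
#'   per-line genetic values, detection thresholds, seed).
#' @examples
#' geno <- simulate_population(40, 300, c(chr1 = 2e6), seed = 1)
#' sim  <- simulate_traits_and_gc(geno, seed = 2)
#' head(sim$wax)
#' @export
simulate_traits_and_gc <- function(genotypes,
                                   expression = NULL,
                                   layout = NULL,
                                   class_config = wax_class_config(),
                                   truth_spec = wax_truth_spec(),
                                   design = field_design(),
                                   zero_rate_per_trait = 0.05,
                                   seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  traits <- class_config$traits
  n_tr <- nrow(traits)
  vc <- truth_spec$variance_components
  lines <- genotypes$line_ids
  n <- length(lines)

  zr <- zero_rate_per_trait
  if (length(zr) == 1L && is.null(names(zr))) {
    zr <- stats::setNames(rep(zr, n_tr), traits$trait_id)
  } else if (is.null(names(zr)) || !all(traits$trait_id %in% names(zr))) {
    stop("zero_rate_per_trait must be a scalar or named for every trait")
  }

  gcw <- truth_spec$gc_weights
  if (is.null(gcw)) {
    we <- traits$trait_id[traits$class == "WE"]
    fa <- traits$trait_id[traits$class == "FA"]
    picks <- c(utils::head(we, 5), utils::head(fa, 1))
    gcw <- stats::setNames(rep(1, length(picks)), picks)
  }
  if (!all(names(gcw) %in% traits$trait_id)) {
    stop("gc_weights reference unknown traits: ",
         paste(setdiff(names(gcw), traits$trait_id), collapse = ", "))
  }

  withr::with_seed(seed, {
    X <- genotypes$dosages
    sdx <- apply(X, 2, stats::sd)
    usable <- which(sdx > 0)
    Xs <- scale(X[, usable, drop = FALSE])

    # per-class shared pools of causal SNPs; pool SNPs carry a class-level
    # effect reused by every trait drawing them, so traits of one class
    # correlate positively (shared biosynthetic pathway)
    pool <- lapply(unique(traits$class), function(cl) {
      data.frame(idx = sample(usable, truth_spec$n_causal_snps),
                 beta = stats::rnorm(truth_spec$n_causal_snps))
    })
    names(pool) <- unique(traits$class)

    has_expr <- !is.null(expression) && truth_spec$n_causal_genes > 0
    expr_gv <- if (has_expr) expression$genetic_values else NULL
    expr_ok <- if (has_expr) {
      which(apply(expr_gv, 2, stats::sd) > 0)
    } else integer(0)

    gmat <- matrix(0, n, n_tr, dimnames = list(lines, traits$trait_id))
    causal_snps <- vector("list", n_tr)
    causal_genes <- vector("list", n_tr)
    names(causal_snps) <- names(causal_genes) <- traits$trait_id

    for (t_i in seq_len(n_tr)) {
      cl <- traits$class[t_i]
      k <- truth_spec$n_causal_snps
      k_sh <- min(round(class_config$shared_frac * k), nrow(pool[[cl]]))
      sh <- if (k_sh > 0) pool[[cl]][sample(nrow(pool[[cl]]), k_sh), ] else
        data.frame(idx = integer(), beta = numeric())
      k_pr <- k - k_sh
      idx <- c(sh$idx, sample(setdiff(usable, pool[[cl]]$idx), k_pr))
      beta <- c(sh$beta, stats::rnorm(k_pr))
      g <- as.vector(Xs[, match(idx, usable), drop = FALSE] %*% beta)
      genes <- character(0); gamma <- numeric(0)
      if (has_expr && length(expr_ok) > 0) {
        gi <- sample(expr_ok, min(truth_spec$n_causal_genes, length(expr_ok)))
        genes <- colnames(expr_gv)[gi]
        gamma <- stats::rnorm(length(gi), sd = truth_spec$gene_effect_sd)
        g <- g + as.vector(scale(expr_gv[, gi, drop = FALSE]) %*% gamma)
      }
      sc <- sqrt(vc$G) / stats::sd(g)
      gmat[, t_i] <- (g - mean(g)) * sc
      causal_snps[[t_i]] <- data.frame(
        snp_id = colnames(X)[idx], snp_index = idx, effect = beta * sc,
        stringsAsFactors = FALSE)
      causal_genes[[t_i]] <- data.frame(
        gene_id = genes, effect = gamma * sc, stringsAsFactors = FALSE)
    }

    # field/plot layout ------------------------------------------------
    d <- design
    plot_rows <- do.call(rbind, lapply(seq_len(d$n_envs), function(e) {
      blk <- sample(rep(seq_len(d$n_blocks), length.out = n))
      base <- data.frame(
        line_id = lines, env = e, block_id = blk,
        column_id = sample.int(d$n_columns, n, replace = TRUE),
        is_check = FALSE, stringsAsFactors = FALSE)
      if (d$include_check) {
        chk <- data.frame(
          line_id = d$check_id, env = e, block_id = seq_len(d$n_blocks),
          column_id = sample.int(d$n_columns, d$n_blocks, replace = TRUE),
          is_check = TRUE, stringsAsFactors = FALSE)
        base <- rbind(base, chk)
      }
      base
    }))
    np <- nrow(plot_rows)
    plot_rows$instrument_id <- sample.int(d$n_instruments, np, replace = TRUE)
    plot_rows$instrument_column_id <-
      sample.int(d$n_instr_columns, np, replace = TRUE)

    line_of <- match(plot_rows$line_id, lines)  # NA for checks

    # random-effect draws shared across traits differ per trait ---------
    sim_one <- function(gvec, mu, chk_off, sigma, with_instr = TRUE) {
      env_eff <- stats::rnorm(d$n_envs, sd = sqrt(sigma$env))
      blk_eff <- matrix(stats::rnorm(d$n_envs * d$n_blocks,
                                     sd = sqrt(sigma$block)),
                        d$n_envs, d$n_blocks)
      col_eff <- matrix(stats::rnorm(d$n_envs * d$n_columns,
                                     sd = sqrt(sigma$col)),
                        d$n_envs, d$n_columns)
      ge_eff <- matrix(stats::rnorm(d$n_envs * n, sd = sqrt(sigma$GE)),
                       n, d$n_envs)
      y <- mu +
        ifelse(plot_rows$is_check, chk_off, gvec[line_of]) +
        env_eff[plot_rows$env] +
        blk_eff[cbind(plot_rows$env, plot_rows$block_id)] +
        col_eff[cbind(plot_rows$env, plot_rows$column_id)] +
        ifelse(plot_rows$is_check, 0,
               ge_eff[cbind(line_of, plot_rows$env)]) +
        stats::rnorm(np, sd = sqrt(sigma$resid))
      if (with_instr) {
        ins_eff <- stats::rnorm(d$n_instruments, sd = sqrt(sigma$instr))
        icol_eff <- matrix(stats::rnorm(d$n_instruments * d$n_instr_columns,
                                        sd = sqrt(sigma$instr_col)),
                           d$n_instruments, d$n_instr_columns)
        y <- y + ins_eff[plot_rows$instrument_id] +
          icol_eff[cbind(plot_rows$instrument_id,
                         plot_rows$instrument_column_id)]
      }
      y
    }

    vals <- matrix(0, np, n_tr, dimnames = list(NULL, traits$trait_id))
    thresholds <- stats::setNames(numeric(n_tr), traits$trait_id)
    check_off <- stats::rnorm(n_tr, sd = truth_spec$check_effect_sd)
    for (t_i in seq_len(n_tr)) {
      mu <- truth_spec$class_means[[traits$class[t_i]]]
      y <- sim_one(gmat[, t_i], mu, check_off[t_i], vc)
      thr <- max(0, stats::quantile(y, zr[[traits$trait_id[t_i]]], names = FALSE))
      thresholds[t_i] <- thr
      vals[, t_i] <- ifelse(y < thr | y < 0, 0, y)
    }

    # sum traits from censored compound values (never re-censored)
    reg <- trait_registry(class_config)
    sums <- sapply(unique(traits$class), function(cl) {
      rowSums(vals[, traits$trait_id[traits$class == cl], drop = FALSE])
    })
    colnames(sums) <- paste0(unique(traits$class), "_total")
    total <- rowSums(vals)
    all_vals <- cbind(vals, sums, wax_total = total)
    all_vals <- all_vals[, reg$trait_id, drop = FALSE]

    wax <- do.call(rbind, lapply(reg$trait_id, function(tid) {
      cbind(plot_rows, trait_id = tid, value = all_vals[, tid],
            stringsAsFactors = FALSE)
    }))
    rownames(wax) <- NULL
    attr(wax, "trait_meta") <- reg
    class(wax) <- c("plot_table", "data.frame")

    # conductance: weighted trait genetic values + env + noise ----------
    gc_gen <- as.vector(gmat[, names(gcw), drop = FALSE] %*% gcw)
    env_eff <- stats::rnorm(d$n_envs, sd = sqrt(vc$env))
    real <- !plot_rows$is_check
    gc_tab <- data.frame(
      line_id = plot_rows$line_id[real], env = plot_rows$env[real],
      block_id = plot_rows$block_id[real],
      column_id = plot_rows$column_id[real],
      instrument_id = NA_integer_, instrument_column_id = NA_integer_,
      is_check = FALSE, trait_id = "gc",
      value = gc_gen[line_of[real]] + env_eff[plot_rows$env[real]] +
        stats::rnorm(sum(real), sd = truth_spec$gc_noise_sd),
      stringsAsFactors = FALSE)
    class(gc_tab) <- c("plot_table", "data.frame")

    truth <- structure(list(
      causal_snps = causal_snps, causal_genes = causal_genes,
      variance_components = vc, gc_weights = gcw,
      gc_noise_sd = truth_spec$gc_noise_sd,
      genetic_values = gmat, gc_genetic = stats::setNames(gc_gen, lines),
      detection_thresholds = thresholds, seed = seed
    ), class = "truth_record")

    list(wax = wax, gc = gc_tab, truth = truth)
  })
}
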