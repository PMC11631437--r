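# Kinship mixed-model machinery shared by GWAS and TWAS.
#
# Model: y = X b + s beta + u + e, u ~ N(0, K sigma_g^2), e ~ N(0, I sigma_e^2).
# With the eigendecomposition K = U S U' the model rotates to independent
# observations with variances sigma_g^2 (S_ii + lambda), lambda =
# sigma_e^2 / sigma_g^2, so the likelihood profiles to a one-dimensional
# optimization over log(lambda) (the EMMA device).

.mlm_eigen <- function(K) {
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    warning("kinship not positive semidefinite; clipping negative eigenvalues")
  }
  eig$values <- pmax(eig$values, 0)
  eig
}

# Profile log-likelihood at variance ratio lambda; reml toggles the REML
# adjustment. Returns ML and REML log-likelihoods plus GLS ingredients.
.mlm_eval <- function(yr, Xr, s, lambda) {
  n <- length(yr)
  p <- ncol(Xr)
  v <- s + lambda
  w <- 1 / v
  XtWX <- crossprod(Xr * w, Xr)
  XtWy <- crossprod(Xr * w, yr)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 * w)
  ll_ml <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + sum(log(v)) + n)
  ldXX <- 2 * sum(log(diag(chol(crossprod(Xr)))))
  ldXWX <- 2 * sum(log(diag(ch)))
  ll_reml <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(rss / (n - p)) +
                       sum(log(v)) + ldXWX - ldXX + (n - p))
  list(beta = drop(beta), rss = rss, ll_ml = ll_ml, ll_reml = ll_reml,
       XtWX_chol = ch, sigma2_reml = rss / (n - p), sigma2_ml = rss / n)
}

# One-dimensional REML (or ML) optimization over log(lambda).
.mlm_fit <- function(yr, Xr, s, reml = TRUE, interval = c(-14, 14)) {
  obj <- function(loglam) {
    ev <- .mlm_eval(yr, Xr, s, exp(loglam))
    if (is.null(ev)) return(1e10)
    -(if (reml) ev$ll_reml else ev$ll_ml)
  }
  opt <- stats::optimize(obj, interval = interval)
  lambda <- exp(opt$minimum)
  ev <- .mlm_eval(yr, Xr, s, lambda)
  sigma_g2 <- if (reml) ev$sigma2_reml else ev$sigma2_ml
  c(ev, list(lambda = lambda, sigma_g2 = sigma_g2,
             sigma_e2 = lambda * sigma_g2))
}

# Wald test of the last column of Xr at a fitted lambda.
.mlm_wald_last <- function(fit, n, p) {
  ch <- fit$XtWX_chol
  inv_last <- backsolve(ch, forwardsolve(t(ch), c(rep(0, p - 1), 1)))[p]
  se <- sqrt(fit$sigma2_reml * inv_last)
  b <- fit$beta[p]
  tstat <- b / se
  pv <- 2 * stats::pt(-abs(tstat), df = n - p)
  c(effect = b, p = max(pv, .Machine$double.xmin))
}

.align_lines <- function(y, ids) {
  if (!is.null(names(y))) {
    common <- intersect(ids, names(y)[!is.na(y)])
    if (length(common) < 2) stop("fewer than 2 lines shared between trait and genotypes")
    list(y = y[common], ids = common)
  } else {
    if (length(y) != length(ids)) stop("unnamed trait vector must match line count")
    ok <- !is.na(y)
    list(y = stats::setNames(y[ok], ids[ok]), ids = ids[ok])
  }
}

#' Likelihood-ratio R-squared
#'
#' \eqn{R^2_{LR} = 1 - \exp(-\frac{2}{n}(LL_{full} - LL_{null}))}, clamped to
#' `[0, 1)`: the share of phenotypic variation explained by the tested
#' marker, generalizing classical R-squared to the mixed model.
#'
#' @param ll_full,ll_null log-likelihoods of the models with and without the
#'   marker (must satisfy `ll_full >= ll_null` up to rounding).
#' @param n number of observations.
#' @return numeric in `[0, 1)`.
#' @examples
#' r2_likelihood(-98, -100, 300)
#' @export
r2_likelihood <- function(ll_full, ll_null, n) {
  if (n < 2) stop("n must be >= 2")
  if (any(ll_full < ll_null - 1e-9)) {
    stop("ll_full must be >= ll_null")
  }
  r2 <- 1 - exp(-(2 / n) * pmax(0, ll_full - ll_null))
  pmin(pmax(r2, 0), 1 - 1e-15)
}

#' Select the null GWAS model by BIC
#'
#' Fits each candidate null model (kinship plus a covariate set, no SNP) by
#' maximum likelihood and computes \eqn{BIC = -2 LL + q \ln n} with
#' \eqn{q} the number of estimated parameters (fixed effects plus the two
#' variance components). The minimizer is returned; on a tie the smaller
#' model wins.
#'
#' @param trait_values named numeric vector of (transformed) line values.
#' @param candidate_covariate_sets named list; each element a lines x q
#'   covariate matrix (rownames = line ids) or `NULL` for the kinship-only
#'   model. The kinship-only model is added if absent.
#' @param kinship `kinship_matrix` over the same lines.
#' @return object of class `model_spec`: list with `name`, `covariates`,
#'   `bic`, `kinship = TRUE`, and the full `table` of candidate BICs.
#' @export
select_model_bic <- function(trait_values, candidate_covariate_sets, kinship) {
  if (!any(vapply(candidate_covariate_sets, is.null, logical(1)))) {
    candidate_covariate_sets <- c(list(kinship_only = NULL),
                                  candidate_covariate_sets)
  }
  al <- .align_lines(trait_values, rownames(kinship))
  y <- al$y
  ids <- al$ids
  eig <- .mlm_eigen(kinship[ids, ids])
  yr <- drop(crossprod(eig$vectors, y))

  rows <- lapply(seq_along(candidate_covariate_sets), function(i) {
    cv <- candidate_covariate_sets[[i]]
    X <- matrix(1, length(ids), 1)
    if (!is.null(cv)) {
      cv <- as.matrix(cv)
      if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
      X <- cbind(X, cv)
    }
    Xr <- crossprod(eig$vectors, X)
    fit <- .mlm_fit(yr, Xr, eig$values, reml = FALSE)
    q <- ncol(X) + 2
    data.frame(model = names(candidate_covariate_sets)[i], q = q,
               loglik = fit$ll_ml, bic = -2 * fit$ll_ml + q * log(length(y)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- tab[order(tab$bic, tab$q), ][1, ]
  structure(list(name = best$model,
                 covariates = candidate_covariate_sets[[best$model]],
                 bic = best$bic, kinship = TRUE, table = tab),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec: best null model =", x$name,
      sprintf("(BIC %.2f, kinship included)\n", x$bic))
  print(x$table, row.names = FALSE)
  invisible(x)
}

.assoc_table <- function(trait_id, method, feature_id, chrom, pos, p, effect,
                         r2_lr) {
  out <- data.frame(
    trait = trait_id, method = method, feature = feature_id,
    chrom = chrom, pos = pos, p = p, effect = effect, r2_lr = r2_lr,
    stringsAsFactors = FALSE)
  out$rank <- dense_rank(out$p)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Mixed-linear-model GWAS scan
#'
#' Tests every SNP in `y = X b + s beta + u + e`, `u ~ N(0, K sigma_g^2)`,
#' reporting the Wald p-value, the dosage effect estimate, and the
#' likelihood-ratio R-squared of the marker. In `"p3d"` mode the variance
#' components are estimated once on the null model by REML and reused for
#' every SNP; `"exact"` re-optimizes them per SNP. Likelihoods entering
#' \eqn{R^2_{LR}} are maximum-likelihood values evaluated at the fitted
#' variance ratio. SNPs failing the minor-allele-frequency or imputation
#' quality (DR2) filters are excluded up front; constant SNPs report
#' `p = 1`.
#'
#' @param trait_values named numeric vector of line values.
#' @param genotypes a `genotype_matrix` (or dosage matrix with SNP columns).
#' @param kinship optional `kinship_matrix`; computed from `genotypes` when
#'   `NULL`.
#' @param covariates optional lines x q matrix of fixed covariates.
#' @param mode `"p3d"` (default) or `"exact"`.
#' @param maf_min,dr2_min SNP retention filters applied to the genotype
#'   metadata (ignored for plain matrices).
#' @param trait_id label stored in the result.
#' @return an `assoc_table` data frame with columns `trait`, `method`,
#'   `feature`, `chrom`, `pos`, `p`, `effect`, `r2_lr`, `rank`.
#' @export
gwas_scan <- function(trait_values, genotypes, kinship = NULL,
                      covariates = NULL, mode = c("p3d", "exact"),
                      maf_min = 0.05, dr2_min = 0.80,
                      trait_id = "trait") {
  mode <- match.arg(mode)
  is_gm <- inherits(genotypes, "genotype_matrix")
  G <- if (is_gm) genotypes$dosages else as.matrix(genotypes)
  meta <- if (is_gm) genotypes$snp_meta else
    data.frame(snp_id = colnames(G), chrom = NA_character_, pos = NA_integer_,
               maf = pmin(colMeans(G) / 2, 1 - colMeans(G) / 2), dr2 = 1,
               stringsAsFactors = FALSE)
  keep <- meta$maf >= maf_min & meta$dr2 >= dr2_min
  G <- G[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (ncol(G) == 0L) stop("no SNPs pass the MAF/DR2 filters")

  if (is.null(kinship)) kinship <- compute_kinship(G)
  al <- .align_lines(trait_values, rownames(G))
  y <- al$y
  ids <- al$ids
  G <- G[ids, , drop = FALSE]
  K <- kinship[ids, ids]

  X0 <- matrix(1, length(ids), 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
    X0 <- cbind(X0, cv)
  }
  n <- length(y)
  p0 <- ncol(X0)

  eig <- .mlm_eigen(K)
  U <- eig$vectors
  s <- eig$values
  yr <- drop(crossprod(U, y))
  X0r <- crossprod(U, X0)
  null_fit <- .mlm_fit(yr, X0r, s, reml = TRUE)

  const <- apply(G, 2, function(g) stats::sd(g) == 0)
  m <- ncol(G)
  pv <- rep(1, m); eff <- rep(0, m); r2 <- rep(0, m)

  if (mode == "p3d") {
    w <- 1 / (s + null_fit$lambda)
    sw <- sqrt(w)
    Yt <- sw * yr
    Xt <- X0r * sw
    Q <- qr.Q(qr(Xt))
    ry <- Yt - Q %*% crossprod(Q, Yt)
    Gt <- crossprod(U, G) * sw
    RG <- Gt - Q %*% crossprod(Q, Gt)
    ss <- colSums(RG^2)
    cr <- drop(crossprod(RG, ry))
    rss0 <- sum(ry^2)
    ok <- !const & ss > 1e-12
    beta <- ifelse(ok, cr / ss, 0)
    rssj <- pmax(rss0 - beta * cr, .Machine$double.eps)
    df <- n - p0 - 1
    se <- sqrt(rssj / df / ss)
    tstat <- beta / se
    pv[ok] <- pmax(2 * stats::pt(-abs(tstat[ok]), df), .Machine$double.xmin)
    eff[ok] <- beta[ok]
    ll0 <- -0.5 * (n * log(2 * pi) + n * log(rss0 / n) +
                     sum(log(s + null_fit$lambda)) + n)
    llj <- -0.5 * (n * log(2 * pi) + n * log(rssj / n) +
                     sum(log(s + null_fit$lambda)) + n)
    r2[ok] <- r2_likelihood(llj[ok], ll0, n)
  } else {
    ll0 <- .mlm_fit(yr, X0r, s, reml = FALSE)$ll_ml
    for (j in seq_len(m)) {
      if (const[j]) next
      Xr <- cbind(X0r, drop(crossprod(U, G[, j])))
      fit <- .mlm_fit(yr, Xr, s, reml = TRUE)
      wt <- .mlm_wald_last(fit, n, p0 + 1)
      pv[j] <- wt["p"]; eff[j] <- wt["effect"]
      ll_ml_j <- .mlm_eval(yr, Xr, s, fit$lambda)$ll_ml
      r2[j] <- r2_likelihood(max(ll_ml_j, ll0), ll0, n)
    }
  }
  .assoc_table(trait_id, "GWAS", meta$snp_id, meta$chrom, meta$pos,
               pv, eff, r2)
}

#' Mixed-model transcriptome-wide association scan
#'
#' Tests each gene's (residualized) expression as a fixed covariate in the
#' same kinship mixed model as [gwas_scan()]. With `per_gene_reml = TRUE`
#' (the default) the variance components are re-estimated by REML for every
#' gene; otherwise the null-model estimates are reused. Lines with missing
#' expression for a gene are dropped for that gene only. Constant expression
#' reports `p = 1`.
#'
#' @param trait_values named numeric vector of line values.
#' @param expression lines x genes matrix of residualized expression.
#' @param kinship `kinship_matrix` over (at least) the trait lines.
#' @param covariates optional lines x q fixed covariates.
#' @param per_gene_reml re-estimate variance components per gene.
#' @param layout optional `genome_layout` used to attach gene coordinates.
#' @param trait_id label stored in the result.
#' @return an `assoc_table` with one row per gene (method `"TWAS"`).
#' @export
twas_scan <- function(trait_values, expression, kinship, covariates = NULL,
                      per_gene_reml = TRUE, layout = NULL,
                      trait_id = "trait") {
  E <- as.matrix(expression)
  al <- .align_lines(trait_values, rownames(E))
  y <- al$y
  ids <- al$ids
  E <- E[ids, , drop = FALSE]
  K <- kinship[ids, ids]
  X0 <- matrix(1, length(ids), 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
    X0 <- cbind(X0, cv)
  }

  # cache rotations per missingness pattern (screening leaves few NAs)
  cache <- new.env(parent = emptyenv())
  get_rot <- function(miss_idx) {
    key <- paste0("m", paste(miss_idx, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    use <- setdiff(seq_along(ids), miss_idx)
    eig <- .mlm_eigen(K[use, use])
    rot <- list(use = use, U = eig$vectors, s = eig$values,
                yr = drop(crossprod(eig$vectors, y[use])),
                X0r = crossprod(eig$vectors, X0[use, , drop = FALSE]))
    rot$null <- .mlm_fit(rot$yr, rot$X0r, rot$s, reml = TRUE)
    rot$ll0_ml <- .mlm_fit(rot$yr, rot$X0r, rot$s, reml = FALSE)$ll_ml
    cache[[key]] <- rot
    rot
  }

  m <- ncol(E)
  pv <- rep(1, m); eff <- rep(0, m); r2 <- rep(0, m)
  for (j in seq_len(m)) {
    x <- E[, j]
    miss <- which(is.na(x))
    if (length(ids) - length(miss) < ncol(X0) + 3) next
    if (stats::sd(x[setdiff(seq_along(x), miss)]) == 0) next
    rot <- get_rot(miss)
    Xr <- cbind(rot$X0r, drop(crossprod(rot$U, x[rot$use])))
    nn <- length(rot$use)
    if (per_gene_reml) {
      fit <- .mlm_fit(rot$yr, Xr, rot$s, reml = TRUE)
    } else {
      fit <- .mlm_eval(rot$yr, Xr, rot$s, rot$null$lambda)
      fit$lambda <- rot$null$lambda
    }
    wt <- .mlm_wald_last(fit, nn, ncol(Xr))
    pv[j] <- wt["p"]; eff[j] <- wt["effect"]
    ll_ml_j <- .mlm_eval(rot$yr, Xr, rot$s, fit$lambda)$ll_ml
    r2[j] <- r2_likelihood(max(ll_ml_j, rot$ll0_ml), rot$ll0_ml, nn)
  }

  genes <- colnames(E)
  chrom <- rep(NA_character_, m); pos <- rep(NA_integer_, m)
  if (!is.null(layout)) {
    gm <- layout$gene_models
    i <- match(genes, gm$gene_id)
    chrom <- gm$chrom[i]
    pos <- as.integer(round((gm$start[i] + gm$end[i]) / 2))
  }
  .assoc_table(trait_id, "TWAS", genes, chrom, pos, pv, eff, r2)
}
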