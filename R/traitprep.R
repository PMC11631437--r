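#' Drop traits undetected in too many lines
#'
#' A compound not detected (value 0) in a large share of the panel cannot be
#' analysed without bias, so traits whose line-level zero fraction is
#' strictly greater than `max_zero_frac` are excluded. A line counts as zero
#' for a trait when all of its plots are zero; the fraction is computed over
#' lines (check plots excluded), not over plots.
#'
#' @param plot_table long-format plot table (see [simulate_traits_and_gc()]).
#' @param max_zero_frac retention threshold; the default 0.40 keeps traits
#'   detected in at least 60 percent of the panel.
#' @return list with `plot_table` (retained traits) and `report` (data frame
#'   of all traits with `zero_frac` and `dropped`).
#' @export
filter_detectable_traits <- function(plot_table, max_zero_frac = 0.40) {
  if (nrow(plot_table) == 0L) stop("plot_table is empty")
  pt <- plot_table[!plot_table$is_check, , drop = FALSE]
  frac <- vapply(split(pt, pt$trait_id), function(d) {
    line_zero <- tapply(d$value, d$line_id, function(v) all(v == 0))
    mean(line_zero)
  }, numeric(1))
  report <- data.frame(trait_id = names(frac), zero_frac = as.numeric(frac),
                       dropped = as.numeric(frac) > max_zero_frac,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep <- report$trait_id[!report$dropped]
  if (length(keep) == 0L) stop("all traits exceed the zero-fraction threshold")
  out <- plot_table[plot_table$trait_id %in% keep, , drop = FALSE]
  meta <- attr(plot_table, "trait_meta")
  if (!is.null(meta)) {
    attr(out, "trait_meta") <- meta[meta$trait_id %in% keep, , drop = FALSE]
  }
  class(out) <- class(plot_table)
  list(plot_table = out, report = report)
}

#' Impute zero abundances below the detection limit
#'
#' Every zero value of a trait is replaced by a uniform random draw between
#' 0 and the lowest positive value quantified for that trait within the same
#' environment, reflecting that a zero means "below detection", not absence.
#'
#' @param plot_table long-format plot table.
#' @param seed integer seed; identical seeds give identical imputations.
#' @return list with `plot_table` (imputed) and `log` (data frame per
#'   trait/environment: number imputed and the upper bound used).
#' @export
impute_zero_abundances <- function(plot_table, seed = 1) {
  idx_zero <- which(plot_table$value == 0)
  if (length(idx_zero) == 0L) {
    return(list(plot_table = plot_table,
                log = data.frame(trait_id = character(), env = integer(),
                                 n_imputed = integer(), upper = numeric())))
  }
  out <- plot_table
  key <- interaction(plot_table$trait_id, plot_table$env, drop = TRUE)
  logs <- list()
  withr::with_seed(seed, {
    for (k in levels(key)) {
      rows <- which(key == k)
      v <- out$value[rows]
      z <- v == 0
      if (!any(z)) next
      pos <- v[v > 0]
      if (length(pos) == 0L) {
        stop("trait/environment cell entirely zero: ", k,
             " (cannot bound the imputation)")
      }
      m <- min(pos)
      out$value[rows[z]] <- stats::runif(sum(z), 0, m)
      logs[[k]] <- data.frame(trait_id = out$trait_id[rows[1]],
                              env = out$env[rows[1]],
                              n_imputed = sum(z), upper = m,
                              stringsAsFactors = FALSE)
    }
  })
  list(plot_table = out, log = do.call(rbind, c(logs, list(make.row.names = FALSE))))
}

#' Outlier screening with Studentized deleted residuals
#'
#' Fits the working linear design by least squares and computes for every
#' observation the Studentized deleted residual
#' \eqn{t_i = e_i / \sqrt{MSE_{(i)} (1 - h_{ii})}}, the residual scaled by
#' the error variance re-estimated with observation i removed. Observation i
#' is flagged iff \eqn{|t_i|} exceeds the two-sided Bonferroni cutoff
#' \eqn{t_{1-\alpha/(2n),\,n-p-1}}. The screen is a single pass; it is not
#' re-applied to its own output.
#'
#' @param response numeric response vector (may contain `NA`, which are
#'   ignored and never flagged).
#' @param design model matrix; `NULL` means intercept only.
#' @param alpha familywise error rate for the Bonferroni cutoff.
#' @return list with `keep` (logical, `FALSE` for removed), `removed`
#'   (indices), `sdr` (Studentized deleted residuals, `NA` where undefined),
#'   and `cutoff`. Observations with leverage 1 get `sdr = NA` and are
#'   reported in `leverage_one`.
#' @export
screen_outliers_sdr <- function(response, design = NULL, alpha = 0.05) {
  n_all <- length(response)
  ok <- which(!is.na(response))
  y <- response[ok]
  n <- length(y)
  X <- if (is.null(design)) matrix(1, n, 1) else {
    stopifnot(nrow(design) == n_all)
    as.matrix(design)[ok, , drop = FALSE]
  }
  p <- qr(X)$rank
  if (n <= p + 1) stop("need n > p + 1 observations for the deletion residuals")

  fit <- stats::lm.fit(X, y)
  e <- fit$residuals
  h <- stats::hat(X)
  rss <- sum(e^2)
  lev1 <- abs(1 - h) < 1e-10
  sdr <- rep(NA_real_, n)
  denom <- rss * (1 - h[!lev1]) - e[!lev1]^2
  denom[denom < 0] <- 0
  sdr[!lev1] <- e[!lev1] * sqrt((n - p - 1) / pmax(denom, .Machine$double.eps))
  cutoff <- stats::qt(1 - alpha / (2 * n), df = n - p - 1)

  keep <- rep(TRUE, n_all)
  flagged <- ok[which(!is.na(sdr) & abs(sdr) > cutoff)]
  keep[flagged] <- FALSE
  sdr_full <- rep(NA_real_, n_all)
  sdr_full[ok] <- sdr
  list(keep = keep, removed = flagged, sdr = sdr_full, cutoff = cutoff,
       leverage_one = ok[lev1])
}

#' Line-mean heritability from variance components
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/\bar e +
#'   \sigma^2_\epsilon/(\bar e \bar r))}
#'
#' where \eqn{\bar e} is the harmonic mean of the number of environments per
#' line and \eqn{\bar r} the harmonic mean of plots per line within an
#' environment (so \eqn{\bar e \bar r} is the effective total plot count).
#'
#' @param vc variance components: a named list/vector containing `G`, `GE`,
#'   and `resid`, or a `variance_components` object.
#' @param n_envs environments per line (scalar or per-line vector; harmonic
#'   mean is taken).
#' @param plots_per_env plots per line within an environment (scalar or
#'   vector).
#' @return heritability in `[0, 1]`.
#' @examples
#' line_mean_heritability(list(G = 1, GE = 1, resid = 1), 2, 2)  # 0.8
#' @export
line_mean_heritability <- function(vc, n_envs, plots_per_env = 1) {
  if (inherits(vc, "variance_components")) vc <- vc$components
  vc <- as.list(vc)
  for (k in c("G", "GE", "resid")) {
    if (is.null(vc[[k]])) stop("variance component '", k, "' missing")
  }
  e_bar <- harmonic_mean(n_envs)
  r_bar <- harmonic_mean(plots_per_env)
  denom <- vc$G + vc$GE / e_bar + vc$resid / (e_bar * r_bar)
  if (denom <= 0) stop("all variance components are zero; heritability undefined")
  min(1, max(0, vc$G / denom))
}

#' Box-Cox transformation with a convenient lambda
#'
#' Chooses the power-transformation parameter by maximizing the Box-Cox
#' profile log-likelihood of an intercept-only model on the grid -2 to 2 in
#' steps of 0.1, then snaps the optimum to the nearest interpretable value
#' in \{-2, -1, -0.5, 0, 0.5, 1, 2\} provided that value lies inside the 95
#' percent profile-likelihood interval. The transform is
#' \eqn{(y^\lambda - 1)/\lambda}, or \eqn{\log y} at \eqn{\lambda = 0}.
#' Non-positive inputs are shifted by `-min(y) + eps` first (the shift is
#' returned).
#'
#' @param blups strictly positive numeric vector (after the automatic shift);
#'   `NA`s are carried through.
#' @param eps shift margin used when any input is non-positive.
#' @return list with `transformed`, `lambda` (the convenient value used),
#'   `lambda_mle` (grid optimum), `shift`, and `profile` (data frame of the
#'   grid log-likelihood).
#' @export
boxcox_transform <- function(blups, eps = 1e-3) {
  ok <- !is.na(blups)
  y <- blups[ok]
  if (length(y) < 3) stop("need at least 3 values")
  shift <- 0
  if (min(y) <= 0) {
    shift <- -min(y) + eps * max(stats::sd(y), 1)
    y <- y + shift
  }
  if (min(y) <= 0) stop("values non-positive after shift")
  grid <- seq(-2, 2, by = 0.1)
  bc <- MASS::boxcox(v ~ 1, data = data.frame(v = y), lambda = grid,
                     plotit = FALSE)
  ll <- bc$y
  lambda_mle <- bc$x[which.max(ll)]
  in_ci <- ll >= max(ll) - stats::qchisq(0.95, 1) / 2
  convenient <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  # convenient values whose grid point falls inside the 95% interval
  conv_ok <- convenient[vapply(convenient, function(l) {
    i <- which.min(abs(bc$x - l))
    in_ci[i]
  }, logical(1))]
  lambda <- if (length(conv_ok) > 0) {
    conv_ok[which.min(abs(conv_ok - lambda_mle))]
  } else {
    lambda_mle
  }
  tr <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  out <- rep(NA_real_, length(blups))
  out[ok] <- tr
  list(transformed = out, lambda = lambda, lambda_mle = lambda_mle,
       shift = shift, profile = data.frame(lambda = bc$x, loglik = ll))
}

#' Remove latent expression factors
#'
#' Standardizes the lines x genes expression matrix and removes the top
#' `k_factors` principal components (the maximum-likelihood probabilistic-PCA
#' subspace), leaving residual expression free of broad latent confounders.
#' Afterwards each gene is screened for outlying lines with
#' [screen_outliers_sdr()] (intercept-only design); flagged values become
#' `NA`.
#'
#' @param expression_blups lines x genes numeric matrix of combined
#'   expression values.
#' @param k_factors number of latent factors to remove; `<= 0` returns the
#'   column-standardized input unchanged.
#' @param screen apply the per-gene outlier screen.
#' @param alpha screening threshold (Bonferroni-corrected).
#' @return residualized lines x genes matrix (same dimnames).
#' @export
residualize_expression <- function(expression_blups, k_factors = 20,
                                   screen = TRUE, alpha = 0.05) {
  Z <- as.matrix(expression_blups)
  sds <- apply(Z, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(Z, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  if (k_factors > 0) {
    if (k_factors >= min(dim(Z))) stop("k_factors must be < min(n_lines, n_genes)")
    sv <- svd(Z, nu = k_factors, nv = k_factors)
    Z <- Z - sv$u %*% (sv$d[seq_len(k_factors)] * t(sv$v))
  }
  if (screen) {
    for (j in seq_len(ncol(Z))) {
      sc <- screen_outliers_sdr(Z[, j], alpha = alpha)
      if (length(sc$removed) > 0) Z[sc$removed, j] <- NA
    }
  }
  Z
}
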