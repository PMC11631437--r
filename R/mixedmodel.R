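# REML fits of the multi-environment trait model, BLUP extraction, and the
# full trait-preparation pipeline.

.random_term_map <- c(
  line = "line_id",
  env = "env_f",
  "line:env" = "line_env",
  "env:block" = "env_block",
  "env:column" = "env_column",
  instrument = "instrument_f",
  "instrument:column" = "instr_col"
)

.vc_name_map <- c(
  line_id = "G", line_env = "GE", env_f = "env", env_block = "block",
  env_column = "col", instrument_f = "instr", instr_col = "instr_col"
)

#' Fit the multi-environment mixed model for one trait
#'
#' Fits, by REML, the trait model with the grand mean (and a check-line
#' indicator where check plots are present) as fixed effects and genotype,
#' environment, genotype-by-environment, block and column position nested in
#' environment, instrument, and column nested in instrument as random
#' intercepts. Terms absent from the data (all-`NA` or single-level columns)
#' are dropped automatically, as are terms whose estimated variance pins at
#' zero when `drop_zero_terms = TRUE` (the final term set is recorded).
#'
#' @param plot_table long-format plot table.
#' @param trait_id trait to fit.
#' @param random_terms subset of `"line"`, `"env"`, `"line:env"`,
#'   `"env:block"`, `"env:column"`, `"instrument"`, `"instrument:column"`.
#' @param drop_zero_terms refit without random terms estimated at zero
#'   variance (genotype and residual are never dropped).
#' @return list with `vc` (class `variance_components`: named component
#'   vector, log-likelihood, convergence flag, final term set), `blups`
#'   (named per-line genotype BLUPs, deviations from the grand mean; check
#'   line excluded), `grand_mean`, `residuals` (conditional residuals), and
#'   `rows` (row indices of the fitted observations in `plot_table`).
#' @export
fit_trait_mixed_model <- function(plot_table, trait_id,
                                  random_terms = names(.random_term_map),
                                  drop_zero_terms = FALSE) {
  d <- plot_table[plot_table$trait_id == trait_id, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not found: ", trait_id)
  rows <- which(plot_table$trait_id == trait_id)
  keep <- !is.na(d$value)
  d <- d[keep, , drop = FALSE]
  rows <- rows[keep]

  dat <- data.frame(
    value = d$value,
    line_id = factor(d$line_id),
    env_f = factor(d$env),
    line_env = factor(paste(d$line_id, d$env, sep = ":")),
    env_block = factor(paste(d$env, d$block_id, sep = ":")),
    env_column = factor(paste(d$env, d$column_id, sep = ":")),
    instrument_f = factor(d$instrument_id),
    instr_col = factor(paste(d$instrument_id, d$instrument_column_id, sep = ":")),
    is_check = as.numeric(d$is_check)
  )

  usable <- function(v) {
    if (v == "line_env" && nlevels(droplevels(dat$env_f)) < 2) return(FALSE)
    if (v %in% c("instrument_f", "instr_col") &&
        (anyNA(d$instrument_id) || anyNA(d$instrument_column_id))) return(FALSE)
    nlevels(droplevels(dat[[v]])) >= 2
  }
  terms_used <- .random_term_map[intersect(random_terms, names(.random_term_map))]
  terms_used <- terms_used[vapply(terms_used, usable, logical(1))]
  if (!"line_id" %in% terms_used) stop("the genotype term cannot be dropped")

  fixed <- if (any(dat$is_check > 0)) "1 + is_check" else "1"

  fit_with <- function(terms) {
    fml <- stats::as.formula(paste(
      "value ~", fixed, "+",
      paste(sprintf("(1 | %s)", terms), collapse = " + ")))
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    ))
  }
  fit <- fit_with(terms_used)

  get_vc <- function(fit) {
    vc_df <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc_df$vcov, vc_df$grp)
    names(v)[names(v) == "Residual"] <- "resid"
    v
  }
  if (drop_zero_terms) {
    repeat {
      v <- get_vc(fit)
      zero <- names(v)[v < 1e-10 & !names(v) %in% c("line_id", "resid")]
      zero <- intersect(zero, terms_used)
      if (length(zero) == 0L) break
      terms_used <- setdiff(terms_used, zero)
      fit <- fit_with(terms_used)
    }
  }

  v <- get_vc(fit)
  comp <- stats::setNames(numeric(length(.vc_name_map) + 1),
                          c(unname(.vc_name_map), "resid"))
  for (nm in names(v)) {
    key <- if (nm == "resid") "resid" else unname(.vc_name_map[nm])
    if (!is.na(key)) comp[key] <- v[[nm]]
  }
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0

  re <- lme4::ranef(fit)$line_id
  blups <- stats::setNames(re[, 1], rownames(re))
  check_ids <- unique(d$line_id[d$is_check])
  blups <- blups[!names(blups) %in% check_ids]
  grand_mean <- unname(lme4::fixef(fit)["(Intercept)"])

  vc_obj <- structure(list(components = as.list(comp),
                           loglik = as.numeric(stats::logLik(fit)),
                           converged = converged,
                           terms = unname(.vc_name_map[terms_used])),
                      class = "variance_components")
  list(vc = vc_obj, blups = blups, grand_mean = grand_mean,
       residuals = stats::residuals(fit), rows = rows)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (REML):\n")
  print(unlist(x$components))
  cat(sprintf("logLik %.3f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Run the full trait-preparation pipeline
#'
#' Applies, in order: the line-level zero filter, uniform imputation of
#' remaining zeros, a plot-level outlier screen on the conditional residuals
#' of the REML trait model (Studentized deleted residuals, Bonferroni
#' alpha), a refit to estimate variance components, line-mean heritability
#' and BLUPs, the Box-Cox transformation of the abundance-scale BLUPs, and a
#' second, BLUP-level outlier screen on the transformed values. Re-running
#' the pipeline on retained traits is a no-op for the filters.
#'
#' @param plot_table long-format plot table of wax traits.
#' @param max_zero_frac zero-filter threshold (see
#'   [filter_detectable_traits()]).
#' @param alpha outlier-screen familywise error rate.
#' @param drop_zero_terms drop random terms with zero estimated variance.
#' @param seed seed for the imputation draws.
#' @return object of class `trait_panel`: list with `blups` (lines x traits,
#'   abundance scale: grand mean + genotype BLUP), `transformed` (lines x
#'   traits, Box-Cox transformed and outlier-screened, `NA` where removed),
#'   `lambda`, `h2`, `vc` (per-trait `variance_components`), `trait_meta`,
#'   and `qc` (zero filter report, imputation log, outliers removed per
#'   pass).
#' @export
prepare_trait_panel <- function(plot_table, max_zero_frac = 0.40,
                                alpha = 0.05, drop_zero_terms = FALSE,
                                seed = 1) {
  flt <- filter_detectable_traits(plot_table, max_zero_frac)
  imp <- impute_zero_abundances(flt$plot_table, seed = seed)
  pt <- imp$plot_table
  traits <- unique(pt$trait_id)
  meta <- attr(pt, "trait_meta")

  lines_all <- sort(unique(pt$line_id[!pt$is_check]))
  blups <- matrix(NA_real_, length(lines_all), length(traits),
                  dimnames = list(lines_all, traits))
  transformed <- blups
  lambda <- stats::setNames(rep(NA_real_, length(traits)), traits)
  h2 <- lambda
  vc_list <- vector("list", length(traits))
  names(vc_list) <- traits
  out_plot <- list()
  out_blup <- list()

  for (tid in traits) {
    fit1 <- fit_trait_mixed_model(pt, tid, drop_zero_terms = drop_zero_terms)
    scr <- screen_outliers_sdr(fit1$residuals, alpha = alpha)
    work <- pt
    if (length(scr$removed) > 0) {
      work$value[fit1$rows[scr$removed]] <- NA
    }
    out_plot[[tid]] <- data.frame(
      trait_id = tid, n_removed = length(scr$removed),
      sdr_max = if (length(scr$removed)) max(abs(scr$sdr[scr$removed])) else NA_real_)
    fit <- fit_trait_mixed_model(work, tid, drop_zero_terms = drop_zero_terms)

    d <- work[work$trait_id == tid & !work$is_check & !is.na(work$value), ]
    env_per_line <- tapply(d$env, d$line_id, function(e) length(unique(e)))
    plots_per_env <- as.vector(table(d$line_id)) /
      pmax(1, as.vector(env_per_line))
    h2[tid] <- line_mean_heritability(fit$vc, as.vector(env_per_line),
                                      plots_per_env)
    vc_list[[tid]] <- fit$vc
    b <- fit$grand_mean + fit$blups
    blups[names(b), tid] <- b

    bc <- boxcox_transform(blups[, tid])
    lambda[tid] <- bc$lambda
    scr2 <- screen_outliers_sdr(bc$transformed, alpha = alpha)
    tr <- bc$transformed
    if (length(scr2$removed) > 0) tr[scr2$removed] <- NA
    out_blup[[tid]] <- data.frame(
      trait_id = tid, n_removed = length(scr2$removed))
    transformed[, tid] <- tr
  }

  structure(list(
    blups = blups, transformed = transformed, lambda = lambda, h2 = h2,
    vc = vc_list, trait_meta = meta,
    qc = list(zero_filter = flt$report, imputation = imp$log,
              plot_outliers = do.call(rbind, out_plot),
              blup_outliers = do.call(rbind, out_blup))
  ), class = "trait_panel")
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf("trait_panel: %d lines x %d traits\n",
              nrow(x$blups), ncol(x$blups)))
  cat(sprintf("  mean line-mean heritability %.2f (range %.2f-%.2f)\n",
              mean(x$h2, na.rm = TRUE), min(x$h2, na.rm = TRUE),
              max(x$h2, na.rm = TRUE)))
  invisible(x)
}
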