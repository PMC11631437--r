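# Random-forest prediction of cuticular conductance from wax-trait BLUPs.

#' Random-forest configuration
#'
#' Defaults follow the settings that maximize predictive ability for
#' conductance on a ~300-line panel: 1000 trees, 10 predictors sampled per
#' split, 5-fold cross-validation repeated 50 times.
#'
#' @param n_trees,mtry forest size and predictors sampled per split.
#' @param n_folds,n_repeats cross-validation layout.
#' @param seed integer seed controlling fold splits and forests.
#' @return list of settings (class `rf_config`).
#' @export
rf_config <- function(n_trees = 1000, mtry = 10, n_folds = 5,
                      n_repeats = 50, seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_trees = n_trees, mtry = mtry, n_folds = n_folds,
                 n_repeats = n_repeats, seed = seed), class = "rf_config")
}

.rf_align <- function(features, target) {
  X <- as.matrix(features)
  if (!is.null(names(target)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(target)[!is.na(target)])
    X <- X[common, , drop = FALSE]
    y <- target[common]
  } else {
    stopifnot(nrow(X) == length(target))
    y <- target
  }
  cc <- stats::complete.cases(X) & !is.na(y)
  list(X = X[cc, , drop = FALSE], y = y[cc], n_dropped = sum(!cc))
}

#' Repeated cross-validated random-forest prediction
#'
#' For every repeat a fresh fold split is drawn; a forest is grown on each
#' training fold and used to predict the held-out lines, so no observation
#' contributes to any tree used for its own prediction. The predictive
#' ability of a repeat is the Pearson correlation between the pooled
#' out-of-fold predictions and the observed values; the mean over repeats
#' is the headline predictive ability.
#'
#' @param features lines x traits numeric matrix (lines with missing values
#'   are dropped and counted).
#' @param target named numeric vector of observed phenotype values.
#' @param config an [rf_config()].
#' @return object of class `prediction_report`: list with `ability`
#'   (per-repeat predictive abilities), `mean_ability`, `predictions`
#'   (lines x repeats out-of-fold predictions), `n_lines`, `n_dropped`, and
#'   `config`.
#' @export
rf_cross_validate <- function(features, target, config = rf_config()) {
  al <- .rf_align(features, target)
  X <- al$X; y <- al$y
  n <- length(y)
  if (n < config$n_folds) stop("fewer lines than folds")
  mtry <- min(config$mtry, ncol(X))

  withr::with_seed(config$seed, {
    ability <- numeric(config$n_repeats)
    preds <- matrix(NA_real_, n, config$n_repeats,
                    dimnames = list(rownames(X), NULL))
    for (r in seq_len(config$n_repeats)) {
      folds <- sample(rep(seq_len(config$n_folds), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(config$n_folds)) {
        hold <- folds == f
        rf <- randomForest::randomForest(
          X[!hold, , drop = FALSE], y[!hold],
          ntree = config$n_trees, mtry = mtry)
        pred[hold] <- stats::predict(rf, X[hold, , drop = FALSE])
      }
      ability[r] <- stats::cor(pred, y)
      preds[, r] <- pred
    }
    structure(list(ability = ability, mean_ability = mean(ability),
                   predictions = preds, n_lines = n,
                   n_dropped = al$n_dropped, config = config),
              class = "prediction_report")
  })
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "prediction_report: mean predictive ability %.3f over %d repeats (n = %d)\n",
    x$mean_ability, length(x$ability), x$n_lines))
  invisible(x)
}

#' Permutation variable importance
#'
#' Grows one forest on the full data and reports, per feature, the mean
#' increase in out-of-bag squared error when that feature is permuted
#' (unscaled permutation importance). Constant features get importance 0.
#'
#' @param features lines x traits numeric matrix.
#' @param target named numeric vector.
#' @param config an [rf_config()].
#' @return data frame `feature`, `importance`, `rank` (1 = most important),
#'   sorted by decreasing importance.
#' @export
rf_importance <- function(features, target, config = rf_config()) {
  al <- .rf_align(features, target)
  X <- al$X; y <- al$y
  mtry <- min(config$mtry, ncol(X))
  withr::with_seed(config$seed, {
    rf <- randomForest::randomForest(X, y, ntree = config$n_trees,
                                     mtry = mtry, importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  imp[const] <- 0
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen of traits against a phenotype
#'
#' Per feature, the Pearson correlation with the target and its two-sided
#' p-value from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on `n - 2` degrees of
#' freedom (as `cor.test` computes it). Zero-variance features are flagged
#' with `NA`.
#'
#' @param features lines x traits matrix.
#' @param target named numeric vector.
#' @return data frame `feature`, `n`, `r`, `p`, `degenerate`.
#' @export
trait_correlations <- function(features, target) {
  X <- as.matrix(features)
  if (!is.null(names(target)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(target))
    X <- X[common, , drop = FALSE]
    target <- target[common]
  }
  rows <- lapply(colnames(X), function(f) {
    ok <- !is.na(X[, f]) & !is.na(target)
    n <- sum(ok)
    if (n < 3 || stats::sd(X[ok, f]) == 0 || stats::sd(target[ok]) == 0) {
      return(data.frame(feature = f, n = n, r = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(X[ok, f], target[ok])
    data.frame(feature = f, n = n, r = unname(ct$estimate),
               p = ct$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
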