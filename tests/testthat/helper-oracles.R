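# Independent oracles and small fixture builders used across test files.

# Mean silhouette width on a 2-D embedding with known labels (euclidean).
silhouette_score <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Brute-force Studentized deleted residuals: for each observation refit
# without it and scale its prediction error by the deleted-fit variance.
sdr_loo_oracle <- function(y, X) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    fit <- lm.fit(X[-i, , drop = FALSE], y[-i])
    p <- ncol(X)
    mse_i <- sum(fit$residuals^2) / (n - 1 - p)
    xi <- X[i, ]
    XtXi <- solve(crossprod(X[-i, , drop = FALSE]))
    d <- y[i] - sum(xi * fit$coefficients)
    d / sqrt(mse_i * (1 + drop(t(xi) %*% XtXi %*% xi)))
  }, numeric(1))
}

# Long-format plot table with a chosen per-line zero pattern for one trait.
# zero_lines: indices of lines whose plots are all zero.
make_zero_pattern_table <- function(n_lines = 50, zero_lines = integer(0),
                                    trait_id = "WE_01", n_envs = 2,
                                    seed = 1) {
  withr::with_seed(seed, {
    lines <- sprintf("L%03d", seq_len(n_lines))
    rows <- expand.grid(line_id = lines, env = seq_len(n_envs),
                        stringsAsFactors = FALSE)
    rows$block_id <- 1L + (seq_len(nrow(rows)) %% 4L)
    rows$column_id <- 1L + (seq_len(nrow(rows)) %% 6L)
    rows$instrument_id <- 1L + (seq_len(nrow(rows)) %% 2L)
    rows$instrument_column_id <- 1L + (seq_len(nrow(rows)) %% 2L)
    rows$is_check <- FALSE
    rows$trait_id <- trait_id
    rows$value <- abs(rnorm(nrow(rows), mean = 5))
    rows$value[rows$line_id %in% lines[zero_lines]] <- 0
    class(rows) <- c("plot_table", "data.frame")
    rows
  })
}

# Small cached simulated panel shared by several test files.
.fixture_env <- new.env(parent = emptyenv())
fixture_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    geno <- simulate_population(120, 600, c(chr1 = 2e7, chr2 = 2e7),
                                n_subpops = 3, fst = 0.12, seed = 11)
    lay <- simulate_gene_models(80, c(chr1 = 2e7, chr2 = 2e7), seed = 12)
    .fixture_env$panel <- list(geno = geno, lay = lay,
                               K = compute_kinship(geno))
  }
  .fixture_env$panel
}
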