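# Internal helpers shared across modules.

#' Dense ranks of p-values
#'
#' Ties share a rank and the next distinct value gets the next integer, so
#' ranks are dense over the non-missing entries. `NA`s stay `NA`.
#' @param p numeric vector of p-values.
#' @return integer vector of ranks (1 = smallest p).
#' @keywords internal
dense_rank <- function(p) {
  r <- rep(NA_integer_, length(p))
  ok <- !is.na(p)
  r[ok] <- match(p[ok], sort(unique(p[ok])))
  r
}

#' @keywords internal
harmonic_mean <- function(x) {
  x <- x[!is.na(x)]
  if (any(x <= 0)) stop("harmonic mean requires positive values")
  length(x) / sum(1 / x)
}

# Normalise chromosome lengths to a named numeric vector.
#' @keywords internal
as_chrom_lengths <- function(chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    out <- as.numeric(chrom_lengths[[2]])
    names(out) <- as.character(chrom_lengths[[1]])
    return(out)
  }
  out <- as.numeric(chrom_lengths)
  if (is.null(names(chrom_lengths))) {
    names(out) <- paste0("chr", seq_along(out))
  } else {
    names(out) <- names(chrom_lengths)
  }
  if (any(!is.finite(out)) || any(out < 1)) {
    stop("chromosome lengths must be positive")
  }
  out
}

# Largest-remainder apportionment of n items across weights.
#' @keywords internal
apportion <- function(n, weights) {
  share <- n * weights / sum(weights)
  base <- floor(share)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# max(1, round(frac * n)) -- the top-fraction rounding rule used everywhere.
#' @keywords internal
top_k <- function(frac, n) {
  max(1L, as.integer(round(frac * n)))
}
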