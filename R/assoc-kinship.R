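#' Genomic kinship matrix
#'
#' VanRaden's centered cross-product: with dosage matrix \eqn{M} and allele
#' frequencies \eqn{p_j}, \eqn{K = W W' / (2 \sum_j p_j (1 - p_j))} where
#' \eqn{W = M - 2p}. Monomorphic SNPs carry no relatedness information and
#' are excluded with a warning. The result is symmetric and positive
#' semidefinite by construction; under this scaling the diagonal averages
#' \eqn{1 + f} for inbreeding coefficient \eqn{f} (about 2 for a fully
#' inbred panel).
#'
#' @param genotypes a `genotype_matrix`, or a lines x SNPs dosage matrix.
#' @param method currently only `"vanraden"`.
#' @return object of class `kinship_matrix`: the matrix with attributes
#'   `method` and row/column names set to the line ids.
#' @export
compute_kinship <- function(genotypes, method = "vanraden") {
  method <- match.arg(method)
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  p <- colMeans(M) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from kinship")
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(M) == 0L) stop("no polymorphic SNPs for kinship")
  W <- sweep(M, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  structure(K, method = method, class = c("kinship_matrix", "matrix", "array"))
}

#' Principal components of the genotype matrix
#'
#' Scores of the top-`k` eigenvectors of the column-centered dosage matrix,
#' used to control for population stratification. The sign of each component
#' is fixed so that its largest-magnitude SNP loading is positive.
#'
#' @param genotypes a `genotype_matrix` or dosage matrix.
#' @param k number of components; `k <= 0` returns a zero-column matrix.
#' @return lines x k score matrix (columns `PC1`..`PCk`).
#' @export
compute_pcs <- function(genotypes, k) {
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  if (k <= 0) {
    return(matrix(0, nrow(M), 0, dimnames = list(rownames(M), NULL)))
  }
  if (k >= nrow(M)) stop("k must be < n_lines")
  C <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(C, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  dimnames(scores) <- list(rownames(M), paste0("PC", seq_len(k)))
  scores
}
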