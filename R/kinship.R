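#' Genomic relationship matrix (VanRaden normalization)
#'
#' Mean-imputes missing codes per marker, centers each marker by its column
#' mean, and returns `G = W W' / c` with `c = sum_j 2 p_j (1 - p_j)`, where
#' `p_j` is the allele frequency of marker j computed from the -1/+1 codes.
#' This matches the default of the additive-relationship routines used for
#' genomic prediction in inbred panels. A small ridge is added if finite
#' precision leaves eigenvalues below -1e-8.
#'
#' @param geno a `geno_matrix` or a plain m x p matrix of codes in
#'   `{-1, +1, NA}`.
#' @return an object of class `kinship_matrix`: list with `values`
#'   (m x m symmetric matrix, dimnames = varieties) and `varieties`.
#' @export
compute_grm <- function(geno) {
  X <- geno_codes(geno)
  p_freq <- (colMeans(X, na.rm = TRUE) + 1) / 2
  poly <- p_freq > 0 & p_freq < 1 & !is.na(p_freq)
  if (!any(poly))
    stop("compute_grm: all markers monomorphic; kinship undefined",
         call. = FALSE)
  W <- impute_center(X)
  c_norm <- sum(2 * p_freq[poly] * (1 - p_freq[poly]))
  G <- tcrossprod(W) / c_norm
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) G <- G + diag(-ev_min + 1e-8, nrow(G))
  structure(list(values = G, varieties = rownames(X)),
            class = "kinship_matrix")
}

geno_codes <- function(geno) {
  if (inherits(geno, "geno_matrix")) geno$codes
  else if (is.matrix(geno)) geno
  else stop("expected a geno_matrix or a matrix of codes", call. = FALSE)
}

# per-marker mean imputation then column centering (monomorphic -> all 0)
impute_center <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- mu[j]
  sweep(X, 2L, colMeans(X), "-")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d x %d, mean diagonal %.3f\n",
              nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Principal-component covariates for population structure
#'
#' Computes the leading eigenvectors of the imputed, column-centered
#' genotype matrix — the same matrix underlying [compute_grm()], so the
#' covariates and the kinship are mutually consistent. Eigenvector signs are
#' fixed deterministically: the loading of largest magnitude in each
#' component is made positive.
#'
#' @param geno a `geno_matrix` or code matrix.
#' @param n_pc number of components (default 5).
#' @return m x `n_pc` score matrix (rows = varieties, columns `PC1`...),
#'   ordered by decreasing explained variance.
#' @export
pca_covariates <- function(geno, n_pc = 5L) {
  X <- geno_codes(geno)
  if (n_pc >= nrow(X))
    stop("pca_covariates: n_pc must be smaller than the number of varieties",
         call. = FALSE)
  if (n_pc == 0L)
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L,
                  dimnames = list(rownames(X), NULL)))
  W <- impute_center(X)
  sv <- svd(W, nu = n_pc, nv = n_pc)
  flip <- vapply(seq_len(n_pc), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)] * flip, n_pc)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_pc)))
  scores
}

#' Write a kinship matrix as TSV
#'
#' @param K a `kinship_matrix`.
#' @param path output path (square matrix with a header row of IDs).
#' @export
write_kinship_tsv <- function(K, path) {
  utils::write.table(K$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
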