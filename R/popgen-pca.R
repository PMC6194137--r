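#' Genotype principal components analysis
#'
#' EIGENSOFT-style PCA of the haploid genotype matrix: each variant column
#' is mean-imputed (missing and artifact calls), mean-centered and scaled
#' by `sqrt(p(1-p))` with `p` the sample alt frequency (frequency scaling;
#' `normalization = "unscaled"` skips the scaling). Monomorphic variants are
#' dropped. Sample coordinates are the projections onto the top eigenvectors
#' of the sample covariance.
#'
#' @param gm A [genotype_matrix()] (outgroup excluded).
#' @param n_components Number of components to return (clipped with a
#'   warning when larger than the available rank).
#' @param normalization `"frequency-scaled"` (default) or `"unscaled"`.
#' @return List of class `pca_result`: `eigenvalues` (descending),
#'   `sample_coordinates` (samples x components, rownames = sample ids),
#'   `normalization`, `n_snps_used`.
#' @export
genotype_pca <- function(gm, n_components = 10L,
                         normalization = c("frequency-scaled", "unscaled")) {
  normalization <- match.arg(normalization)
  ing <- ingroup(gm)
  d <- t(as_dosage(ing, impute = "mean"))   # samples x variants
  p <- colMeans(d)
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(d, 2L, p, "-")
  if (normalization == "frequency-scaled")
    x <- sweep(x, 2L, sqrt(p * (1 - p)), "/")
  m <- ncol(x)
  if (m == 0L) stop("no polymorphic variants for PCA")
  K <- tcrossprod(x) / m
  eig <- eigen(K, symmetric = TRUE)
  rank <- sum(eig$values > 1e-10)
  if (n_components > min(dim(x), rank)) {
    warning("n_components clipped to ", min(dim(x), rank))
    n_components <- min(dim(x), rank)
  }
  vals <- pmax(eig$values[seq_len(n_components)], 0)
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals), n_components)
  rownames(coords) <- ing$samples$sample_id
  colnames(coords) <- paste0("PC", seq_len(n_components))
  res <- list(
    eigenvalues = vals,
    sample_coordinates = coords,
    normalization = normalization,
    n_snps_used = m
  )
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("genotype PCA on %d variants (%s): top eigenvalue shares %s\n",
              x$n_snps_used, x$normalization,
              paste0(sprintf("%.1f%%", head(pct, 3)), collapse = ", ")))
  invisible(x)
}
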