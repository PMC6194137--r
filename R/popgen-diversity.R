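#' Per-site nucleotide diversity (pi) from haploid calls
#'
#' For each segregating site, the unbiased average pairwise difference is
#' `(n/(n-1)) * 2 p (1-p)` with `n` the number of called haploid genotypes
#' and `p` the alt frequency at that site; per-site diversity is the sum
#' over sites divided by the genome length `L`.
#'
#' @param gm A [genotype_matrix()] (outgroup samples are excluded).
#' @param L Genome length in bp the variants were called against.
#' @return List of class `diversity_result` with `pi_per_site`,
#'   `watterson_theta_per_site`, `S` (segregating sites), `L`, `n`
#'   (ingroup sample count) and `a_n` (harmonic sum).
#' @export
nucleotide_diversity <- function(gm, L) {
  stopifnot(L >= 1)
  ing <- ingroup(gm)
  d <- as_dosage(ing)
  n_called <- rowSums(!is.na(d))
  skipped <- n_called < 2L
  if (any(skipped))
    message(sum(skipped), " site(s) with < 2 called genotypes skipped")
  p <- rowMeans(d, na.rm = TRUE)
  pi_site <- ifelse(skipped, 0,
                    n_called / (n_called - 1) * 2 * p * (1 - p))
  S <- sum(!skipped & p > 0 & p < 1)
  n <- ncol(ing$calls)
  res <- list(
    pi_per_site = sum(pi_site) / L,
    watterson_theta_per_site = if (n >= 2) watterson_theta(S, n, L)
                               else NA_real_,
    S = S, L = L, n = n,
    a_n = if (n >= 2) sum(1 / seq_len(n - 1L)) else NA_real_
  )
  class(res) <- "diversity_result"
  res
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(
    "diversity: pi/site = %.6g, Watterson theta/site = %.6g (S = %d, n = %d, L = %d)\n",
    x$pi_per_site, x$watterson_theta_per_site, x$S, x$n, x$L))
  invisible(x)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled haploid genomes (>= 2).
#' @param L Genome length in bp.
#' @return Watterson's estimator per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("Watterson's theta requires n >= 2")
  stopifnot(S >= 0, L >= 1)
  S / (sum(1 / seq_len(n - 1L)) * L)
}
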