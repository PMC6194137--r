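#' Upper-tail hypergeometric enrichment test
#'
#' With `k` hits among a selection of size `n`, `K` hits in a background of
#' size `N`, the p-value is the probability of drawing at least `k` hits:
#' `p = sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`.
#'
#' @param k Hits in the selection.
#' @param K Hits in the background.
#' @param n Selection size.
#' @param N Background size.
#' @return List of class `enrichment_result`: `k`, `K`, `n`, `N`,
#'   `expected` (`n K / N`) and `p_value`.
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  stopifnot(N >= 1, n >= 1, n <= N, K >= 0, K <= N, k >= 0,
            k <= min(K, n))
  res <- list(k = k, K = K, n = n, N = N,
              expected = n * K / N,
              p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "hypergeometric enrichment: %d/%d in selection vs %d/%d background (expected %.2f); p = %.4g\n",
    x$k, x$n, x$K, x$N, x$expected, x$p_value))
  invisible(x)
}

#' Positional-class enrichment among significant SNPs
#'
#' Tests whether significant SNPs are over-represented in a positional
#' class (e.g., the 5 kb upstream regulatory window) relative to the tested
#' background of all post-QC SNPs.
#'
#' @param hit_ids Variant ids of the significant set.
#' @param annotations [annotate_snps()] output covering the background.
#' @param class One of the positional classes, or a vector (a SNP in any of
#'   them counts).
#' @return An `enrichment_result` (see [hypergeom_enrichment()]).
#' @export
positional_enrichment <- function(hit_ids, annotations, class) {
  stopifnot(all(class %in% POSITIONAL_CLASSES))
  if (length(hit_ids) == 0L) stop("empty selection: enrichment undefined")
  if (!all(hit_ids %in% annotations$id))
    stop("hit ids absent from the annotated background")
  in_class <- annotations$positional_class %in% class
  hit <- annotations$id %in% hit_ids
  hypergeom_enrichment(
    k = sum(in_class & hit), K = sum(in_class),
    n = sum(hit), N = nrow(annotations)
  )
}

#' Gene-set overlap enrichment
#'
#' Hypergeometric over-representation of an external gene set (e.g., ASD
#' ortholog ids) among candidate genes, against a gene universe.
#'
#' @param candidate_genes Candidate gene ids (e.g., genes within 10 kb of
#'   significant SNPs).
#' @param gene_set External gene-set ids.
#' @param universe All tested gene ids; candidates and set must be subsets.
#' @return An `enrichment_result` (see [hypergeom_enrichment()]).
#' @export
gene_set_enrichment <- function(candidate_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  candidate_genes <- unique(candidate_genes)
  gene_set <- unique(gene_set)
  if (!all(candidate_genes %in% universe))
    stop("candidate genes must be a subset of the universe")
  if (!all(gene_set %in% universe))
    stop("gene set must be a subset of the universe")
  if (length(candidate_genes) == 0L)
    stop("empty candidate list: enrichment undefined")
  hypergeom_enrichment(
    k = length(intersect(candidate_genes, gene_set)),
    K = length(gene_set),
    n = length(candidate_genes),
    N = length(universe)
  )
}

#' Read a plain-text gene-set file
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
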