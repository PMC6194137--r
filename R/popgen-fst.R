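# Weir-Cockerham variance components for haploid data. Each haploid
# individual contributes a single allele, so the within-individual
# (heterozygosity) component of the diploid estimator does not exist and is
# dropped; only the among-group component a and the within-group component b
# remain:
#
#   n_bar = mean group size, n_c = (r n_bar - sum n_i^2 / (r n_bar)) / (r-1)
#   p_bar = weighted mean frequency, s2 = sum n_i (p_i - p_bar)^2 / ((r-1) n_bar)
#   b = n_bar/(n_bar - 1) * (p_bar (1 - p_bar) - s2 (r-1)/r)
#   a = n_bar/n_c * (s2 - b / n_bar)    [equivalently s2 - (1/(n_bar-1)) (...)]
#
# Per-site F_ST = a / (a + b); the multi-locus estimate is the
# ratio-of-sums sum(a) / sum(a + b).

group_indicator <- function(g) {
  vapply(levels(g), function(l) as.numeric(g == l), numeric(length(g)))
}

# vectorized components from per-site per-group counts and frequencies
wc_components <- function(p, n) {
  r <- ncol(p)
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  b <- nbar / (nbar - 1) * inner
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  cbind(a = a, b = b)
}

#' Weir-Cockerham F_ST for haploid genotypes
#'
#' Per-site variance-components estimator adapted to haploid samples (no
#' within-individual component), with the genome-wide value computed as the
#' ratio of summed among-group components over summed totals
#' (ratio-of-sums), not as the mean of per-site ratios.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Character/factor of length `n_samples`; `NA` samples are
#'   excluded (e.g., outgroup). If missing, the sample `population` is used
#'   (outgroup samples excluded).
#' @param genome_wide_method `"ratio_of_sums"` (default) or
#'   `"mean_of_ratios"` for sensitivity analyses.
#' @return List of class `fst_result`: `per_site` (`data.frame` id,
#'   scaffold, pos, a, denom, fst), `genome_wide`, `groups`, `n_sites_used`.
#'   Sites where any group has fewer than 2 called genotypes, or with zero
#'   total variance (`a + b = 0`), are excluded from the genome-wide sums
#'   (their per-site fst is `NA`).
#' @export
weir_cockerham_fst <- function(gm, grouping = NULL,
                               genome_wide_method = c("ratio_of_sums",
                                                      "mean_of_ratios")) {
  genome_wide_method <- match.arg(genome_wide_method)
  if (is.null(grouping)) {
    grouping <- ifelse(gm$samples$is_outgroup, NA_character_,
                       gm$samples$population)
  }
  grouping <- as.character(grouping)
  keep <- !is.na(grouping)
  d <- as_dosage(gm)[, keep, drop = FALSE]
  g <- factor(grouping[keep])
  if (nlevels(g) < 2) stop("need at least two groups")
  ind <- group_indicator(g)
  called <- !is.na(d)
  d0 <- d; d0[!called] <- 0
  cnt <- called %*% ind               # per-site per-group called count
  alt <- d0 %*% ind                   # per-site per-group alt count
  ok <- rowSums(cnt < 2) == 0L
  p <- alt / pmax(cnt, 1)
  ab <- wc_components(p, cnt)
  a <- ab[, "a"]; denom <- ab[, "a"] + ab[, "b"]
  usable <- ok & is.finite(denom) & denom != 0
  fst <- ifelse(usable, a / denom, NA_real_)
  gw <- if (genome_wide_method == "ratio_of_sums")
    sum(a[usable]) / sum(denom[usable])
  else mean(fst[usable])
  res <- list(
    per_site = data.frame(
      id = gm$variants$id, scaffold = gm$variants$scaffold,
      pos = gm$variants$pos,
      a = ifelse(ok, a, NA_real_),
      denom = ifelse(ok, denom, NA_real_),
      fst = fst, stringsAsFactors = FALSE),
    genome_wide = gw,
    groups = levels(g),
    n_sites_used = sum(usable)
  )
  class(res) <- "fst_result"
  res
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST (%s): genome-wide = %.4g over %d sites\n",
              paste(x$groups, collapse = " vs "), x$genome_wide,
              x$n_sites_used))
  invisible(x)
}

#' Permutation test for behavior-group differentiation
#'
#' The observed genome-wide F_ST between the two behavior groups is compared
#' with a null built by shuffling behavior labels across individuals. For
#' each permutation a fresh random subset of `subset_size` SNPs (without
#' replacement; all SNPs when fewer are available) is drawn and the
#' genome-wide ratio-of-sums F_ST recomputed. The p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, never exactly zero.
#'
#' @param gm A [genotype_matrix()].
#' @param behavior Optional label vector (two groups; `NA` excluded). By
#'   default the sample table's `behavior` is used with `"unknown"`/outgroup
#'   samples excluded.
#' @param n_perm Number of permutations (default 1000).
#' @param subset_size SNP subset size per permutation (default 100000).
#' @param seed Integer seed.
#' @param fixed_subset If `TRUE`, one subset is drawn and reused for all
#'   permutations instead of resampling per permutation.
#' @return List of class `permutation_result`: `observed_fst`,
#'   `null_values`, `null_mean`, `null_sd`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(gm, behavior = NULL, n_perm = 1000L,
                                 subset_size = 100000L, seed = 1L,
                                 fixed_subset = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(behavior)) {
    behavior <- gm$samples$behavior
    behavior[behavior == "unknown" | gm$samples$is_outgroup] <- NA
  }
  behavior <- as.character(behavior)
  keep <- which(!is.na(behavior))
  labs <- factor(behavior[keep])
  if (nlevels(labs) != 2) stop("behavior permutation test needs two groups")
  d <- as_dosage(gm)[, keep, drop = FALSE]
  m <- nrow(d)
  subset_size <- min(subset_size, m)
  if (subset_size < m)
    message("using random subsets of ", subset_size, " of ", m, " SNPs")

  called <- !is.na(d)
  d0 <- d; d0[!called] <- 0

  gw_fst <- function(rows, lab) {
    ind <- group_indicator(lab)
    cnt <- called[rows, , drop = FALSE] %*% ind
    alt <- d0[rows, , drop = FALSE] %*% ind
    ok <- rowSums(cnt < 2) == 0L
    p <- alt / pmax(cnt, 1)
    ab <- wc_components(p, cnt)
    denom <- ab[, "a"] + ab[, "b"]
    usable <- ok & is.finite(denom) & denom != 0
    sum(ab[usable, "a"]) / sum(denom[usable])
  }

  set.seed(seed)
  observed <- gw_fst(seq_len(m), labs)
  sub_fixed <- if (fixed_subset) sample.int(m, subset_size) else NULL
  null_values <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(labs)
    rows <- if (fixed_subset) sub_fixed else sample.int(m, subset_size)
    gw_fst(rows, perm)
  }, numeric(1))
  res <- list(
    observed_fst = observed,
    null_values = null_values,
    null_mean = mean(null_values),
    null_sd = sd(null_values),
    p_value = (1 + sum(null_values >= observed)) / (1 + n_perm),
    n_perm = n_perm
  )
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "observed F_ST = %.4g; permuted null = %.2g +/- %.2g (%d perms); p = %.4g\n",
    x$observed_fst, x$null_mean, x$null_sd, x$n_perm, x$p_value))
  invisible(x)
}
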