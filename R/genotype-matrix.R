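# Call codes for haploid individuals. H marks a heterozygous-style call in a
# haploid male -- a genotyping artifact, never a half-dose genotype.
GT_REF  <- 0L
GT_ALT  <- 1L
GT_HET  <- 2L
GT_MISS <- 3L

#' Construct a haploid genotype matrix
#'
#' The central container of the pipeline: an integer matrix of haploid calls
#' (variants in rows, samples in columns) over the alphabet ref (0), alt (1),
#' heterozygous artifact (H, coded 2) and missing (M, coded 3), together with
#' the variant table and the sample metadata table.
#'
#' @param calls Integer matrix `n_variants x n_samples` with values in
#'   `0:3` (ref, alt, het artifact, missing).
#' @param variants `data.frame` with columns `id`, `scaffold`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated for multiallelic sites), `qual`,
#'   `class` (`"snp"`, `"indel"` or `"other"`).
#' @param samples `data.frame` with columns `sample_id`, `population`,
#'   `behavior` (`"social"`, `"solitary"` or `"unknown"`) and `is_outgroup`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(
    nrow(calls) == nrow(variants),
    ncol(calls) == nrow(samples),
    all(calls %in% c(GT_REF, GT_ALT, GT_HET, GT_MISS))
  )
  req_v <- c("id", "scaffold", "pos", "ref", "alt", "qual", "class")
  req_s <- c("sample_id", "population", "behavior", "is_outgroup")
  if (!all(req_v %in% names(variants)))
    stop("variant table must have columns: ", paste(req_v, collapse = ", "))
  if (!all(req_s %in% names(samples)))
    stop("sample table must have columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (any(variants$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
  bad <- !samples$behavior %in% c("social", "solitary", "unknown")
  if (any(bad)) stop("invalid behavior label(s): ",
                     paste(unique(samples$behavior[bad]), collapse = ", "))
  if (any(samples$is_outgroup & samples$behavior != "unknown"))
    stop("outgroup samples must have behavior 'unknown'")
  rownames(calls) <- variants$id
  colnames(calls) <- samples$sample_id
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d variants x %d samples (%d outgroup)\n",
    nrow(x$calls), ncol(x$calls), sum(x$samples$is_outgroup)
  ))
  tab <- table(factor(x$calls, levels = 0:3,
                      labels = c("ref", "alt", "H", "M")))
  cat("  calls:", paste(names(tab), format(as.integer(tab)), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Variant index (integer, logical or variant id).
#' @param j Sample index (integer, logical or sample id).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected variants/samples.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$variants$id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  genotype_matrix(
    x$calls[i, j, drop = FALSE],
    x$variants[i, , drop = FALSE],
    x$samples[j, , drop = FALSE]
  )
}

#' Numeric allele dosage of haploid calls
#'
#' Converts the call matrix to a numeric 0/1 matrix. Heterozygous-artifact and
#' missing calls become `NA`: in a haploid, H carries no dose information.
#'
#' @param gm A [genotype_matrix()].
#' @param impute `"none"` keeps `NA`s; `"mean"` replaces them with the variant
#'   mean over called samples (variants with no calls become 0).
#' @return Numeric matrix, variants x samples.
#' @export
as_dosage <- function(gm, impute = c("none", "mean")) {
  impute <- match.arg(impute)
  d <- gm$calls
  storage.mode(d) <- "double"
  d[d >= GT_HET] <- NA_real_
  if (impute == "mean") {
    mu <- rowMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    if (nrow(idx)) d[idx] <- mu[idx[, 1L]]
  }
  d
}

#' Restrict to ingroup (non-outgroup) samples
#'
#' @param gm A [genotype_matrix()].
#' @return A `genotype_matrix` without outgroup samples.
#' @export
ingroup <- function(gm) gm[, !gm$samples$is_outgroup]

#' Alternate-allele frequency per variant
#'
#' Computed over called haploid genotypes only (H and M excluded from the
#' denominator: the artifact carries no allelic information).
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector of alt frequencies (`NaN` where no sample is called).
#' @export
alt_freq <- function(gm) {
  d <- as_dosage(gm)
  rowMeans(d, na.rm = TRUE)
}

#' Minor-allele frequency per variant
#'
#' @inheritParams alt_freq
#' @return Numeric vector: `pmin(p, 1 - p)` of the alt frequency.
#' @export
minor_allele_freq <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}

# classify a site from its ref/alt allele strings
variant_class <- function(ref, alt_list) {
  vapply(seq_along(ref), function(i) {
    alts <- alt_list[[i]]
    if (length(alts) == 0L) return("other")
    if (any(nchar(alts) != nchar(ref[i]))) "indel"
    else if (nchar(ref[i]) == 1L) "snp"
    else "other"
  }, character(1))
}
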