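#' QC thresholds for the post-calling filter cascade
#'
#' Defaults are the filter values of the originating study: site quality
#' >= 30, heterozygous-artifact calls in fewer than 15 individuals,
#' individual heterozygosity <= 30%, uncalled in fewer than 16 individuals,
#' MAF >= 0.05, biallelic SNPs only.
#'
#' @param min_qual Minimum phred-scaled site quality (sites with
#'   `qual < min_qual` are removed).
#' @param max_het_individuals Sites with H calls in this many or more
#'   ingroup individuals are removed.
#' @param max_individual_het_fraction Individuals whose H fraction among
#'   called sites exceeds this are removed.
#' @param max_uncalled Sites missing in this many or more ingroup
#'   individuals are removed.
#' @param min_maf Minimum minor-allele frequency (computed over called
#'   ingroup haploid genotypes of retained individuals).
#' @param require_biallelic Drop sites with more than one alt allele.
#' @param drop_indels Drop sites whose class is not `"snp"`.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_qual = 30,
                          max_het_individuals = 15L,
                          max_individual_het_fraction = 0.30,
                          max_uncalled = 16L,
                          min_maf = 0.05,
                          require_biallelic = TRUE,
                          drop_indels = TRUE) {
  stopifnot(min_qual >= 0, max_het_individuals >= 0,
            max_individual_het_fraction >= 0, max_uncalled >= 0,
            min_maf >= 0, min_maf < 0.5)
  structure(list(
    min_qual = min_qual,
    max_het_individuals = as.integer(max_het_individuals),
    max_individual_het_fraction = max_individual_het_fraction,
    max_uncalled = as.integer(max_uncalled),
    min_maf = min_maf,
    require_biallelic = isTRUE(require_biallelic),
    drop_indels = isTRUE(drop_indels)
  ), class = "qc_thresholds")
}

#' Remove individuals with excess heterozygous-artifact calls
#'
#' In a haploid male, heterozygous calls are genotyping artifacts; an
#' individual with a high artifact fraction is unreliable. An individual is
#' removed iff `H / (H + called)` over its non-missing calls exceeds
#' `max_individual_het_fraction`. Outgroup samples face the same criterion.
#'
#' @param gm A [genotype_matrix()].
#' @param th A [qc_thresholds()].
#' @return List with `gm` (filtered matrix), `removed_samples` (ids) and
#'   `het_fraction` (named vector over input samples).
#' @export
filter_individuals <- function(gm, th = qc_thresholds()) {
  h <- colSums(gm$calls == GT_HET)
  nonmiss <- colSums(gm$calls != GT_MISS)
  frac <- ifelse(nonmiss > 0, h / nonmiss, NA_real_)
  drop <- is.na(frac) | frac > th$max_individual_het_fraction
  if (any(is.na(frac)))
    warning("individual(s) with zero non-missing calls removed: ",
            paste(gm$samples$sample_id[is.na(frac)], collapse = ", "))
  list(
    gm = gm[, !drop],
    removed_samples = gm$samples$sample_id[drop],
    het_fraction = setNames(frac, gm$samples$sample_id)
  )
}

#' Apply the site-level filter cascade
#'
#' A variant is removed iff it fails any of: non-SNP class (when
#' `drop_indels`), `qual < min_qual`, H calls in `>= max_het_individuals`
#' ingroup individuals, missing in `>= max_uncalled` ingroup individuals,
#' more than one alt allele (when `require_biallelic`), or minor-allele
#' frequency below `min_maf` over called ingroup genotypes. Filters are
#' evaluated independently on the input, so the report tallies a site under
#' every filter it fails. Outgroup genotypes never count toward site
#' filters. Individual filtering ([filter_individuals()]) is expected to
#' have been applied first so frequencies reflect the final cohort.
#'
#' @param gm A [genotype_matrix()].
#' @param th A [qc_thresholds()].
#' @return List with `gm` (retained sites), `report` (per-filter removal
#'   counts) and `failed` (logical matrix site x filter).
#' @export
filter_variants <- function(gm, th = qc_thresholds()) {
  ing <- gm$calls[, !gm$samples$is_outgroup, drop = FALSE]
  n_alt_alleles <- vapply(strsplit(gm$variants$alt, ",", fixed = TRUE),
                          length, integer(1))
  maf <- minor_allele_freq(ingroup(gm))
  failed <- cbind(
    not_snp = if (th$drop_indels) gm$variants$class != "snp"
              else rep(FALSE, nrow(gm$calls)),
    low_qual = gm$variants$qual < th$min_qual,
    het_excess = rowSums(ing == GT_HET) >= th$max_het_individuals,
    uncalled = rowSums(ing == GT_MISS) >= th$max_uncalled,
    multiallelic = if (th$require_biallelic) n_alt_alleles > 1L
                   else rep(FALSE, nrow(gm$calls)),
    low_maf = is.nan(maf) | maf < th$min_maf
  )
  drop <- rowSums(failed) > 0L
  report <- list(
    n_input = nrow(gm$calls),
    n_retained = sum(!drop),
    n_removed = sum(drop),
    per_filter = vapply(colnames(failed), function(f)
      sum(failed[, f]), integer(1))
  )
  class(report) <- "qc_report"
  list(gm = gm[!drop, ], report = report, failed = failed)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d sites in, %d removed, %d retained\n",
              x$n_input, x$n_removed, x$n_retained))
  for (f in names(x$per_filter))
    cat(sprintf("  %-12s %d\n", f, x$per_filter[[f]]))
  invisible(x)
}

#' Run the full QC cascade (individuals, then sites)
#'
#' @param gm A [genotype_matrix()].
#' @param th A [qc_thresholds()].
#' @return List with `gm`, `report`, `removed_samples`.
#' @export
run_qc <- function(gm, th = qc_thresholds()) {
  ind <- filter_individuals(gm, th)
  var <- filter_variants(ind$gm, th)
  message(sprintf(
    "QC: %d/%d individuals retained; %d/%d sites retained",
    ncol(ind$gm$calls), ncol(gm$calls),
    var$report$n_retained, var$report$n_input))
  list(gm = var$gm, report = var$report,
       removed_samples = ind$removed_samples)
}
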