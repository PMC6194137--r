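#' Read a multi-sample VCF into a haploid genotype matrix
#'
#' Parses a VCF v4.2 file (via `VariantAnnotation`) and applies the haploid
#' genotype coding: for a diploid-style call `a/b` (or `a|b`), `0/0` maps to
#' ref, `1/1` to the first alt, `a != b` to the heterozygous-artifact code H,
#' and any missing allele to M. Single-allele haploid calls (`0`, `1`) are
#' accepted as the same alphabet. Homozygous calls for a second or later alt
#' allele cannot be expressed in the biallelic 0/1 alphabet and are coded M;
#' such sites keep their multiallelic annotation and are removed by QC.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param metadata Sample metadata `data.frame` or path to a metadata TSV
#'   (see [read_sample_metadata()]). Every VCF sample must be present.
#' @return A [genotype_matrix()], samples in VCF column order.
#' @export
read_vcf <- function(path, metadata) {
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path,
      param = VariantAnnotation::ScanVcfParam(info = NA, geno = "GT")),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  vcf_samples <- colnames(gt)
  missing_md <- setdiff(vcf_samples, metadata$sample_id)
  if (length(missing_md))
    stop("sample(s) missing from metadata: ",
         paste(missing_md, collapse = ", "))
  samples <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref_al <- as.character(VariantAnnotation::ref(vcf))
  alt_al <- as(VariantAnnotation::alt(vcf), "CharacterList")
  alt_list <- as.list(alt_al)
  variants <- data.frame(
    id = make.unique(names(rr), sep = "_"),
    scaffold = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref_al,
    alt = vapply(alt_list, paste, character(1), collapse = ","),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    class = variant_class(ref_al, alt_list),
    stringsAsFactors = FALSE
  )
  variants$qual[is.na(variants$qual)] <- 0

  calls <- matrix(decode_gt(as.vector(gt)), nrow = nrow(gt))
  genotype_matrix(calls, variants, samples)
}

# Vectorized GT string -> {0,1,H,M} decoder. "/" and "|" are equivalent
# (phase is meaningless for haploids); both haploid ("0") and
# homozygous-diploid ("0/0") dialects are accepted.
decode_gt <- function(gt) {
  u <- unique(gt)
  codes <- vapply(u, decode_gt1, integer(1), USE.NAMES = FALSE)
  codes[match(gt, u)]
}

decode_gt1 <- function(g) {
  if (is.na(g)) return(GT_MISS)
  al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
  if (length(al) < 1L || length(al) > 2L)
    stop("unsupported genotype string: '", g, "'")
  if (any(al == "." | al == "")) return(GT_MISS)
  if (length(al) == 2L && al[1] != al[2]) return(GT_HET)
  a <- suppressWarnings(as.integer(al[1]))
  if (is.na(a)) stop("unsupported genotype string: '", g, "'")
  if (a == 0L) GT_REF else if (a == 1L) GT_ALT else GT_MISS
}

#' Write a haploid genotype matrix as VCF v4.2
#'
#' Emits one sample column per individual with haploid-style GT strings:
#' ref `0`, alt `1`, heterozygous artifact `0/1`, missing `.`. Reading the
#' file back with [read_vcf()] reproduces the call matrix exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contigs Optional `data.frame` with columns `scaffold`, `length`
#'   written as `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contigs = NULL) {
  v <- gm$variants
  gt_str <- c("0", "1", "0/1", ".")[gm$calls + 1L]
  gt <- matrix(gt_str, nrow = nrow(gm$calls))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haplopop",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$scaffold,
              as.integer(contigs$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    v$scaffold, v$pos, v$id, v$ref, v$alt,
    format(v$qual, trim = TRUE, scientific = FALSE), ".", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
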