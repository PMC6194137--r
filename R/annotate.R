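# Positional class priority when a SNP falls in windows of several genes or
# several windows of one gene: coding > intron > downstream_1kb >
# upstream_5kb > gene_proximal_10kb > intergenic; within a class the
# nearest gene wins.
POSITIONAL_CLASSES <- c("exon_nonsynonymous", "exon_synonymous",
                        "exon_other", "intron", "downstream_1kb",
                        "upstream_5kb", "gene_proximal_10kb", "intergenic")
CLASS_PRIORITY <- c(exon_nonsynonymous = 1, exon_synonymous = 1,
                    exon_other = 1, intron = 2, downstream_1kb = 3,
                    upstream_5kb = 4, gene_proximal_10kb = 5,
                    intergenic = 6)

#' Classify the effect of a single-base change within a codon
#'
#' @param ref_codon Three-letter reference codon (read in transcription
#'   direction, i.e. coding-strand sense).
#' @param codon_pos Position of the substituted base within the codon (1-3).
#' @param alt_base Substituted base (coding-strand sense).
#' @return `"exon_synonymous"` or `"exon_nonsynonymous"` by the standard
#'   nuclear genetic code (`"exon_other"` if a codon is untranslatable).
#' @export
codon_effect <- function(ref_codon, codon_pos, alt_base) {
  ref_codon <- toupper(ref_codon)
  alt_base <- toupper(alt_base)
  stopifnot(nchar(ref_codon) == 3L, codon_pos %in% 1:3,
            nchar(alt_base) == 1L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[ref_codon]
  aa_alt <- Biostrings::GENETIC_CODE[alt_codon]
  if (is.na(aa_ref) || is.na(aa_alt)) return("exon_other")
  if (aa_ref == aa_alt) "exon_synonymous" else "exon_nonsynonymous"
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# coding-strand codon context of a CDS position; NULL when the reference
# sequence is unavailable. refseq: named list/DNAStringSet-like of scaffold
# sequences as plain character strings.
codon_context <- function(snp_pos, gene, refseq) {
  cdm <- gene$cds[[1]]
  if (is.null(cdm) || nrow(cdm) == 0L) return(NULL)
  # genomic positions of CDS bases in transcription order
  coding_pos <- unlist(lapply(seq_len(nrow(cdm)), function(k) {
    s <- cdm[k, "start"]; e <- cdm[k, "end"]
    if (gene$strand == "+") s:e else e:s
  }))
  offset <- match(snp_pos, coding_pos)
  if (is.na(offset)) return(NULL)
  codon_idx <- (offset - 1L) %/% 3L
  codon_genomic <- coding_pos[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  if (anyNA(codon_genomic)) return(NULL)  # truncated trailing codon
  if (is.null(refseq) || is.null(refseq[[gene$scaffold]])) return(NULL)
  seq <- refseq[[gene$scaffold]]
  bases <- toupper(substring(seq, codon_genomic, codon_genomic))
  if (gene$strand == "-") bases <- COMPLEMENT[bases]
  list(codon = paste(bases, collapse = ""),
       codon_pos = (offset - 1L) %% 3L + 1L)
}

# class of one SNP relative to one gene; list(class, dist) or NULL
classify_vs_gene <- function(pos, ref, alt, gene, windows, refseq) {
  lo <- gene$span_start; hi <- gene$span_end
  dist <- if (pos < lo) lo - pos else if (pos > hi) pos - hi else 0L
  plus <- gene$strand == "+"
  inside <- pos >= lo & pos <= hi
  if (inside) {
    exm <- gene$exons[[1]]
    in_exon <- any(pos >= exm[, "start"] & pos <= exm[, "end"])
    if (!in_exon) return(list(class = "intron", dist = 0L))
    cdm <- gene$cds[[1]]
    in_cds <- nrow(cdm) > 0L &&
      any(pos >= cdm[, "start"] & pos <= cdm[, "end"])
    if (!in_cds) return(list(class = "exon_other", dist = 0L))
    ctx <- codon_context(pos, gene, refseq)
    if (is.null(ctx) || nchar(ref) != 1L || nchar(alt) != 1L)
      return(list(class = "exon_other", dist = 0L))
    alt_sense <- if (plus) alt else unname(COMPLEMENT[toupper(alt)])
    return(list(class = codon_effect(ctx$codon, ctx$codon_pos, alt_sense),
                dist = 0L))
  }
  # downstream window: beyond the last codon in transcription direction
  if (!is.na(gene$last_codon_end)) {
    dn <- if (plus) pos > gene$last_codon_end &
                    pos <= gene$last_codon_end + windows$downstream
          else pos < gene$last_codon_end &
               pos >= gene$last_codon_end - windows$downstream
    if (dn) return(list(class = "downstream_1kb", dist = dist))
  }
  # upstream window: against transcription direction from the TSS
  up <- if (plus) pos < gene$tss & pos >= gene$tss - windows$upstream
        else pos > gene$tss & pos <= gene$tss + windows$upstream
  if (up) return(list(class = "upstream_5kb", dist = dist))
  if (dist <= windows$proximal)
    return(list(class = "gene_proximal_10kb", dist = dist))
  NULL
}

#' Annotate SNPs with positional classes relative to gene models
#'
#' Strand-aware window annotation: `upstream_5kb` extends `windows$upstream`
#' bp against transcription direction from the TSS; `downstream_1kb`
#' extends `windows$downstream` bp beyond the last codon in transcription
#' direction; SNPs inside the gene body are exonic (synonymous /
#' non-synonymous by codon substitution when a reference sequence is
#' supplied, otherwise `exon_other` for coding and non-coding exon bases
#' alike) or intronic; remaining SNPs within `windows$proximal` bp of a
#' gene span are `gene_proximal_10kb`, everything else `intergenic`.
#' Overlaps resolve by class priority (coding > intron > downstream >
#' upstream > proximal), then by distance to the nearest gene.
#'
#' @param variants `data.frame` with columns `id`, `scaffold`, `pos`,
#'   `ref`, `alt` (a [genotype_matrix()]'s `$variants` works directly).
#' @param genes A `gene_models` table ([read_gene_models()] /
#'   [simulate_gene_models()]).
#' @param windows Named list with `upstream`, `downstream`, `proximal`
#'   window sizes in bp (defaults 5000 / 1000 / 10000).
#' @param refseq Optional named list (or `Biostrings::DNAStringSet`) of
#'   scaffold sequences for synonymous/non-synonymous calls.
#' @return `data.frame`: id, scaffold, pos, positional_class, gene_id
#'   (`NA` for intergenic), distance_to_gene.
#' @export
annotate_snps <- function(variants, genes,
                          windows = list(upstream = 5000, downstream = 1000,
                                         proximal = 10000),
                          refseq = NULL) {
  if (!is.null(refseq) && !is.list(refseq))
    refseq <- as.list(as.character(refseq))
  n <- nrow(variants)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  dst <- rep(NA_integer_, n)
  if (nrow(genes)) {
    # candidate gene pairs within the widest window
    pad <- max(unlist(windows))
    ggr <- GenomicRanges::GRanges(
      genes$scaffold,
      IRanges::IRanges(pmax(genes$span_start - pad, 1L),
                       genes$span_end + pad))
    sgr <- GenomicRanges::GRanges(variants$scaffold,
                                  IRanges::IRanges(variants$pos,
                                                   variants$pos))
    hits <- GenomicRanges::findOverlaps(sgr, ggr)
    hs <- S4Vectors::queryHits(hits); hg <- S4Vectors::subjectHits(hits)
    for (i in unique(hs)) {
      best <- NULL
      for (g in hg[hs == i]) {
        res <- classify_vs_gene(variants$pos[i], variants$ref[i],
                                strsplit(variants$alt[i], ",")[[1]][1],
                                genes[g, ], windows, refseq)
        if (is.null(res)) next
        if (is.null(best) ||
            CLASS_PRIORITY[res$class] < CLASS_PRIORITY[best$class] ||
            (CLASS_PRIORITY[res$class] == CLASS_PRIORITY[best$class] &&
             res$dist < best$dist)) {
          best <- res
          best$gene <- genes$gene_id[g]
        }
      }
      if (!is.null(best)) {
        cls[i] <- best$class
        gid[i] <- best$gene
        dst[i] <- best$dist
      }
    }
  }
  data.frame(
    id = variants$id, scaffold = variants$scaffold, pos = variants$pos,
    positional_class = cls, gene_id = gid, distance_to_gene = dst,
    stringsAsFactors = FALSE
  )
}

#' Polarize alleles against outgroup haplotypes
#'
#' If every called outgroup haplotype at a site carries the same ingroup
#' allele, that allele is ancestral and the other is derived; discordant or
#' entirely missing outgroup calls leave the site unpolarized.
#'
#' @param gm A [genotype_matrix()] containing outgroup samples.
#' @return `data.frame`: id, derived_allele (`"ref"`, `"alt"`,
#'   `"unpolarized"`), ancestral_allele.
#' @export
polarize_alleles <- function(gm) {
  og <- gm$calls[, gm$samples$is_outgroup, drop = FALSE]
  if (ncol(og) == 0L) stop("no outgroup samples present")
  n_ref <- rowSums(og == GT_REF)
  n_alt <- rowSums(og == GT_ALT)
  derived <- rep("unpolarized", nrow(og))
  derived[n_ref > 0 & n_alt == 0] <- "alt"
  derived[n_alt > 0 & n_ref == 0] <- "ref"
  ancestral <- c(alt = "ref", ref = "alt",
                 unpolarized = "unpolarized")[derived]
  data.frame(id = gm$variants$id, derived_allele = derived,
             ancestral_allele = unname(ancestral),
             stringsAsFactors = FALSE)
}
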