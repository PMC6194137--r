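#' Read gene models from a GFF3 file
#'
#' Builds one gene model per gene from `gene`/`mRNA`/`exon`/`CDS` features
#' (via `rtracklayer`). When a gene has several mRNAs the one with the
#' longest total CDS is used. Segments are stored 1-based inclusive and
#' sorted in transcription order (descending coordinates on the minus
#' strand); the TSS is the transcription-direction-first transcript
#' coordinate and `last_codon_end` the transcription-direction-most CDS base.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` of class `gene_models`, one row per gene, with
#'   columns `gene_id`, `scaffold`, `strand`, `tss`, `last_codon_end`,
#'   `span_start`, `span_end` and list-columns `exons` and `cds` (each a
#'   matrix with columns `start`, `end` and, for `cds`, `phase`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  ids <- as.character(m$ID)
  parent <- vapply(as.list(m$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  exons <- which(type == "exon")
  cdss  <- which(type == "CDS")

  rows <- lapply(genes, function(gi) {
    gid <- ids[gi]
    tx <- mrnas[parent[mrnas] == gid]
    if (length(tx) == 0L) return(NULL)
    # longest-CDS transcript represents the gene
    cds_len <- vapply(tx, function(ti) {
      ci <- cdss[parent[cdss] == ids[ti]]
      sum(GenomicRanges::end(gr)[ci] - GenomicRanges::start(gr)[ci] + 1L)
    }, numeric(1))
    ti <- tx[which.max(cds_len)]
    tid <- ids[ti]
    strand <- as.character(GenomicRanges::strand(gr))[ti]
    if (!strand %in% c("+", "-"))
      stop("gene ", gid, ": transcript has no strand")
    ei <- exons[parent[exons] == tid]
    ci <- cdss[parent[cdss] == tid]
    if (length(ei) == 0L) ei <- ci
    ord <- if (strand == "+") order(GenomicRanges::start(gr)[ei])
           else order(-GenomicRanges::start(gr)[ei])
    exm <- cbind(start = GenomicRanges::start(gr)[ei][ord],
                 end = GenomicRanges::end(gr)[ei][ord])
    ordc <- if (strand == "+") order(GenomicRanges::start(gr)[ci])
            else order(-GenomicRanges::start(gr)[ci])
    phase <- suppressWarnings(as.integer(as.character(m$phase[ci])))
    if (all(is.na(phase))) phase <- cds_phases(
      GenomicRanges::end(gr)[ci][ordc] - GenomicRanges::start(gr)[ci][ordc] + 1L)
    else phase <- phase[ordc]
    cdm <- cbind(start = GenomicRanges::start(gr)[ci][ordc],
                 end = GenomicRanges::end(gr)[ci][ordc],
                 phase = phase)
    tx_start <- GenomicRanges::start(gr)[ti]
    tx_end <- GenomicRanges::end(gr)[ti]
    data.frame(
      gene_id = gid,
      scaffold = as.character(GenomicRanges::seqnames(gr))[ti],
      strand = strand,
      tss = if (strand == "+") tx_start else tx_end,
      last_codon_end = if (length(ci) == 0L) NA_integer_
        else if (strand == "+") max(GenomicRanges::end(gr)[ci])
        else min(GenomicRanges::start(gr)[ci]),
      span_start = tx_start,
      span_end = tx_end,
      exons = I(list(exm)),
      cds = I(list(cdm)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), scaffold = character(),
                      strand = character(), tss = integer(),
                      last_codon_end = integer(), span_start = integer(),
                      span_end = integer(), exons = I(list()),
                      cds = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_models", class(out))
  out
}

# phase of each CDS segment given transcription-order segment lengths
cds_phases <- function(lens) {
  if (length(lens) == 0L) return(integer())
  c(0L, (3L - cumsum(lens)[-length(lens)] %% 3L) %% 3L)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows with `ID`/`Parent` links, one
#' transcript per gene, suitable for round-tripping with
#' [read_gene_models()].
#'
#' @param genes A `gene_models` table (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    exm <- g$exons[[1]]
    cdm <- g$cds[[1]]
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    row9 <- function(type, start, end, phase, attrs)
      paste(g$scaffold, "haplopop", type, start, end, ".", g$strand,
            phase, attrs, sep = "\t")
    lines <- c(
      lines,
      row9("gene", g$span_start, g$span_end, ".", paste0("ID=", gid)),
      row9("mRNA", g$span_start, g$span_end, ".",
           paste0("ID=", tid, ";Parent=", gid)),
      vapply(seq_len(nrow(exm)), function(k)
        row9("exon", min(exm[k, 1:2]), max(exm[k, 1:2]), ".",
             paste0("ID=", tid, ".exon", k, ";Parent=", tid)), character(1)),
      if (nrow(cdm))
        vapply(seq_len(nrow(cdm)), function(k)
          row9("CDS", min(cdm[k, 1:2]), max(cdm[k, 1:2]), cdm[k, "phase"],
               paste0("ID=", tid, ".cds;Parent=", tid)), character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}
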