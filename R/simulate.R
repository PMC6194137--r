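#' Configuration for the haplodiploid population simulator
#'
#' Defaults mirror the resequencing design the pipeline was built around:
#' six populations of 25 haploid males in two behavior groups (3 social,
#' 3 solitary), island-model differentiation at genome-wide F_ST 0.06,
#' rare heterozygous miscalls in haploids, light missingness and two
#' outgroup haplotypes. The default scaffold layout places one variant per
#' ~130 bp (the empirical SNP density of the study system, which also puts
#' per-site diversity on the ~0.002 scale), split over `n_scaffolds`
#' equal-length scaffolds.
#'
#' @param n_populations Number of populations.
#' @param samples_per_population Haploid individuals per population.
#' @param behavior_assignment Named character vector population -> behavior;
#'   default assigns the first half `"social"`, the rest `"solitary"`.
#' @param n_snps Number of variant sites.
#' @param scaffold_layout `data.frame(scaffold, length)`; default derived
#'   from `n_snps` at 130 bp/SNP density.
#' @param n_scaffolds Scaffold count for the default layout.
#' @param fst_target Balding-Nichols F (expected genome-wide F_ST).
#' @param ancestral_maf_law `"uniform"`: ancestral minor-allele frequency
#'   uniform on \[0.05, 0.5\]; `"neutral_sfs"`: derived-allele counts drawn
#'   from the standard neutral site-frequency spectrum (P(k) proportional
#'   to 1/k), no population structure -- used for diversity calibration.
#' @param n_causal Number of planted behavior-associated SNPs.
#' @param causal_shift Between-behavior-group allele-frequency displacement
#'   at causal SNPs (split +/- shift/2 around the ancestral frequency).
#'   Causal sites are seeded at intermediate ancestral frequency
#'   (uniform on \[shift/2, 1 - shift/2\]) so the displacement survives
#'   clipping to \[0, 1\].
#' @param het_artifact_rate Per-call probability of a heterozygous miscall.
#' @param missing_rate Per-call probability of a missing call.
#' @param n_outgroup Outgroup haplotypes carrying the ancestral major allele.
#' @param recomb_block_bp Linkage-block size in bp; calls within a block are
#'   copied from a shared local template, so r-squared is elevated within
#'   blocks and vanishes across them (the study system loses half its
#'   r-squared within ~250 bp).
#' @param n_genes Genes to place in the synthetic GFF3; the default scales
#'   with the layout (one gene per ~60 kb, at most 50) so placement always
#'   leaves deep intergenic space.
#' @param seed Integer seed; identical configs are bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 6L,
                       samples_per_population = 25L,
                       behavior_assignment = NULL,
                       n_snps = 10000L,
                       scaffold_layout = NULL,
                       n_scaffolds = 10L,
                       fst_target = 0.06,
                       ancestral_maf_law = c("uniform", "neutral_sfs"),
                       n_causal = 0L,
                       causal_shift = 0.5,
                       het_artifact_rate = 0.002,
                       missing_rate = 0.01,
                       n_outgroup = 2L,
                       recomb_block_bp = 250L,
                       n_genes = NULL,
                       seed = 1L) {
  ancestral_maf_law <- match.arg(ancestral_maf_law)
  if (is.null(behavior_assignment)) {
    pops <- paste0("pop", seq_len(n_populations))
    behavior_assignment <- setNames(
      rep(c("social", "solitary"), c(ceiling(n_populations / 2),
                                     floor(n_populations / 2))), pops)
  }
  if (is.null(scaffold_layout)) {
    total <- max(n_snps, 1L) * 130
    n_scaffolds <- max(1L, min(as.integer(n_scaffolds),
                               total %/% 250000L))
    len <- ceiling(total / n_scaffolds)
    scaffold_layout <- data.frame(
      scaffold = sprintf("scf%02d", seq_len(n_scaffolds)),
      length = rep(len, n_scaffolds), stringsAsFactors = FALSE)
  }
  if (is.null(n_genes))
    n_genes <- min(50L, sum(scaffold_layout$length %/% 35000L))
  cfg <- list(
    n_populations = as.integer(n_populations),
    samples_per_population = as.integer(samples_per_population),
    behavior_assignment = behavior_assignment,
    n_snps = as.integer(n_snps),
    scaffold_layout = scaffold_layout,
    fst_target = fst_target,
    ancestral_maf_law = ancestral_maf_law,
    n_causal = as.integer(n_causal),
    causal_shift = causal_shift,
    het_artifact_rate = het_artifact_rate,
    missing_rate = missing_rate,
    n_outgroup = as.integer(n_outgroup),
    recomb_block_bp = as.integer(recomb_block_bp),
    n_genes = as.integer(n_genes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_populations >= 1L, samples_per_population >= 1L, n_snps >= 0L,
      fst_target >= 0, fst_target < 1,
      n_causal <= n_snps, n_causal >= 0L,
      causal_shift >= 0, causal_shift <= 1,
      het_artifact_rate >= 0, het_artifact_rate <= 1,
      missing_rate >= 0, missing_rate <= 1,
      n_outgroup >= 0L, recomb_block_bp >= 1L, n_genes >= 0L
    )
    if (length(behavior_assignment) != n_populations)
      stop("behavior_assignment must name every population")
    if (!all(behavior_assignment %in% c("social", "solitary")))
      stop("behavior_assignment values must be social/solitary")
    if (sum(scaffold_layout$length) < n_snps)
      stop("scaffold layout too short to place n_snps variants")
  })
  invisible(cfg)
}

#' Simulate per-population allele frequencies
#'
#' Ancestral alt-allele frequencies are drawn from the configured law; each
#' population's frequency is then drawn from the Balding-Nichols
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_target`
#' (`F = 0` degenerates to copying the ancestral frequency). The first
#' `n_causal` randomly chosen SNPs get `+causal_shift/2` added in social
#' populations and `-causal_shift/2` in solitary ones, clipped to \[0, 1\].
#'
#' @param cfg A [sim_config()].
#' @return List with `freq` (matrix SNPs x populations), `ancestral`
#'   (numeric vector), `causal_idx` (integer vector), `positions`
#'   (`data.frame` scaffold/pos, coordinate-sorted).
#' @export
simulate_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_snps
  pops <- names(cfg$behavior_assignment)

  positions <- sim_positions(cfg)

  if (cfg$ancestral_maf_law == "neutral_sfs") {
    n_tot <- cfg$n_populations * cfg$samples_per_population
    k <- sample(seq_len(n_tot - 1L), m, replace = TRUE,
                prob = 1 / seq_len(n_tot - 1L))
    anc <- k / n_tot
  } else {
    maf <- runif(m, 0.05, 0.5)
    flip <- runif(m) < 0.5
    anc <- ifelse(flip, 1 - maf, maf)
  }

  causal_idx <- if (cfg$n_causal > 0L) sort(sample.int(m, cfg$n_causal))
                else integer()
  if (cfg$n_causal > 0L && cfg$ancestral_maf_law == "uniform") {
    # intermediate ancestral frequency so the shift survives clipping
    lo <- cfg$causal_shift / 2
    anc[causal_idx] <- runif(cfg$n_causal, lo, 1 - lo)
  }

  F <- cfg$fst_target
  if (F <= 0 || cfg$ancestral_maf_law == "neutral_sfs") {
    freq <- matrix(anc, nrow = m, ncol = length(pops))
  } else {
    freq <- vapply(pops, function(p)
      rbeta(m, anc * (1 - F) / F, (1 - anc) * (1 - F) / F), numeric(m))
    # Beta draws can hit 0/1 exactly at extreme shapes; keep them valid
    freq[!is.finite(freq)] <- anc[row(freq)[!is.finite(freq)]]
  }
  colnames(freq) <- pops

  if (length(causal_idx)) {
    soc <- cfg$behavior_assignment == "social"
    freq[causal_idx, soc] <- freq[causal_idx, soc, drop = FALSE] +
      cfg$causal_shift / 2
    freq[causal_idx, !soc] <- freq[causal_idx, !soc, drop = FALSE] -
      cfg$causal_shift / 2
    freq <- pmin(pmax(freq, 0), 1)
  }
  list(freq = freq, ancestral = anc, causal_idx = causal_idx,
       positions = positions)
}

# coordinate-sorted unique SNP positions across the scaffold layout,
# allocated proportionally to scaffold length
sim_positions <- function(cfg) {
  lay <- cfg$scaffold_layout
  m <- cfg$n_snps
  n_per <- floor(m * lay$length / sum(lay$length))
  rem <- m - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  out <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    if (n_per[i] == 0L) return(NULL)
    data.frame(scaffold = lay$scaffold[i],
               pos = sort(sample.int(lay$length[i], n_per[i])),
               stringsAsFactors = FALSE)
  }))
  out[order(out$scaffold, out$pos), , drop = FALSE]
}

#' Simulate haploid genotypes from population frequencies
#'
#' Calls are Bernoulli(population frequency) with block-wise linkage: within
#' every `recomb_block_bp` window each individual copies all its calls from a
#' single local haplotype template (one latent uniform per individual per
#' block thresholded against the per-SNP frequencies), which elevates
#' within-block r-squared while keeping marginal frequencies exact and
#' blocks independent. True calls are then independently replaced by the
#' heterozygous-artifact code H at `het_artifact_rate` and by missing M at
#' `missing_rate`. Outgroup haplotypes deterministically carry the ancestral
#' major allele (ancestral frequency rounded), before the same noise.
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param cfg The same [sim_config()].
#' @return List with `gm` (a [genotype_matrix()]) and `truth`
#'   (`data.frame`: variant id, causal flag, ancestral allele and ancestral
#'   frequency, plus per-population simulated frequencies).
#' @export
simulate_genotypes <- function(freqs, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  pops <- names(cfg$behavior_assignment)
  npp <- cfg$samples_per_population
  pos <- freqs$positions

  block <- as.integer(
    interaction(pos$scaffold, pos$pos %/% cfg$recomb_block_bp, drop = TRUE))

  calls <- matrix(GT_REF, nrow = m,
                  ncol = cfg$n_populations * npp + cfg$n_outgroup)
  col <- 0L
  for (p in seq_along(pops)) {
    fp <- freqs$freq[, p]
    for (ind in seq_len(npp)) {
      col <- col + 1L
      u <- runif(max(block))[block]   # one latent uniform per block
      calls[, col] <- as.integer(u < fp)
    }
  }
  # outgroup: ancestral major allele, no polymorphism
  anc_allele <- as.integer(freqs$ancestral > 0.5)
  for (o in seq_len(cfg$n_outgroup)) {
    col <- col + 1L
    calls[, col] <- anc_allele
  }

  n_cells <- length(calls)
  noise <- runif(n_cells)
  calls[noise < cfg$het_artifact_rate] <- GT_HET
  calls[noise >= cfg$het_artifact_rate &
          noise < cfg$het_artifact_rate + cfg$missing_rate] <- GT_MISS

  ids <- sprintf("%s_%d", pos$scaffold, pos$pos)
  variants <- data.frame(
    id = ids, scaffold = pos$scaffold, pos = pos$pos,
    ref = "A", alt = "T",
    qual = round(30 + rexp(m, 1 / 300), 1),
    class = "snp", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c(paste0(rep(pops, each = npp), "_",
                         sprintf("m%02d", sequence(rep(npp, length(pops))))),
                  if (cfg$n_outgroup > 0)
                    sprintf("outgroup_%02d", seq_len(cfg$n_outgroup))),
    population = c(rep(pops, each = npp),
                   rep("outgroup", cfg$n_outgroup)),
    behavior = c(rep(unname(cfg$behavior_assignment), each = npp),
                 rep("unknown", cfg$n_outgroup)),
    is_outgroup = c(rep(FALSE, cfg$n_populations * npp),
                    rep(TRUE, cfg$n_outgroup)),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, variants, samples)
  truth <- data.frame(
    id = ids,
    causal = seq_len(m) %in% freqs$causal_idx,
    ancestral_allele = c("ref", "alt")[anc_allele + 1L],
    ancestral_freq = freqs$ancestral,
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(freqs$freq))
  list(gm = gm, truth = truth)
}

#' Simulate a synthetic gene set as gene models
#'
#' Places `n_genes` non-overlapping stranded genes across the scaffold
#' layout, each with 2-4 exons and a CDS whose total length is divisible by
#' three; inter-gene gaps exceed 20 kb so some variants stay intergenic
#' beyond the 10 kb proximity window.
#'
#' @param cfg A [sim_config()].
#' @return A `gene_models` table (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  lay <- cfg$scaffold_layout
  n <- cfg$n_genes
  if (n == 0L) {
    out <- data.frame(gene_id = character(), scaffold = character(),
                      strand = character(), tss = integer(),
                      last_codon_end = integer(), span_start = integer(),
                      span_end = integer(), exons = I(list()),
                      cds = I(list()), stringsAsFactors = FALSE)
    class(out) <- c("gene_models", class(out))
    return(out)
  }
  # sequential placement with > 20 kb gaps keeps deep intergenic space;
  # one gene fits per ~33 kb (gap 21-26 kb + gene body up to ~6 kb)
  capacity <- lay$length %/% 33000L
  if (n > sum(capacity))
    stop("insufficient scaffold space for ", n, " genes (capacity ",
         sum(capacity), ")")
  n_per <- integer(nrow(lay))
  left <- n
  for (s in order(-capacity)) {
    n_per[s] <- min(capacity[s], left)
    left <- left - n_per[s]
  }
  gi <- 0L
  rows <- list()
  for (s in seq_len(nrow(lay))) {
    if (n_per[s] == 0L) next
    cursor <- 1L
    for (k in seq_len(n_per[s])) {
      gi <- gi + 1L
      cursor <- cursor + 21000L + sample.int(5000L, 1L)
      g <- sim_one_gene(lay$scaffold[s], cursor, paste0("gene", gi))
      rows[[gi]] <- g
      cursor <- g$span_end
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_models", class(out))
  out
}

sim_one_gene <- function(scaffold, start, gene_id) {
  n_ex <- sample(2:4, 1L)
  exon_len <- sample(120:600, n_ex, replace = TRUE)
  intron_len <- sample(80:800, n_ex - 1L, replace = TRUE)
  ex_start <- start + c(0L, cumsum(exon_len[-n_ex] + intron_len))
  ex_end <- ex_start + exon_len - 1L
  # CDS: trim UTR off the first and last exon, force total length % 3 == 0
  utr5 <- sample(20:60, 1L)
  utr3 <- sample(20:60, 1L)
  cds_start <- ex_start
  cds_end <- ex_end
  cds_start[1] <- cds_start[1] + utr5
  cds_end[n_ex] <- cds_end[n_ex] - utr3
  total <- sum(cds_end - cds_start + 1L)
  cds_end[n_ex] <- cds_end[n_ex] - (total %% 3L)
  strand <- sample(c("+", "-"), 1L)
  ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  exm <- cbind(start = ex_start[ord], end = ex_end[ord])
  lens <- (cds_end - cds_start + 1L)[ord]
  cdm <- cbind(start = cds_start[ord], end = cds_end[ord],
               phase = cds_phases(lens))
  data.frame(
    gene_id = gene_id, scaffold = scaffold, strand = strand,
    tss = if (strand == "+") ex_start[1] else ex_end[n_ex],
    last_codon_end = if (strand == "+") cds_end[n_ex] else cds_start[1],
    span_start = ex_start[1], span_end = ex_end[n_ex],
    exons = I(list(exm)), cds = I(list(cdm)), stringsAsFactors = FALSE
  )
}

#' Simulate a complete haplodiploid dataset
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()] and
#' [simulate_gene_models()] under one seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `gm`, `truth`, `genes`, `freqs` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  freqs <- simulate_frequencies(cfg)
  gt <- simulate_genotypes(freqs, cfg)
  genes <- simulate_gene_models(cfg)
  list(gm = gt$gm, truth = gt$truth, genes = genes, freqs = freqs,
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits VCF v4.2, GFF3, the 4-column sample metadata TSV and a truth table
#' TSV (causal ids, ancestral alleles, simulated frequencies).
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    gff = file.path(dir, "genes.gff3"),
    metadata = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(ds$gm, paths["vcf"], contigs = ds$config$scaffold_layout)
  write_gff3(ds$genes, paths["gff"])
  write_sample_metadata(ds$gm$samples, paths["metadata"])
  write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
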