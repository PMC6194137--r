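test_that("positional classes on a two-strand toy gene set are exact", {
  genes <- toy_genes()
  mk <- function(pos) data.frame(
    id = paste0("s", seq_along(pos)), scaffold = "scf01", pos = pos,
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  # plus-strand gene: span 10000-13000, tss 10000, last codon 12950
  # minus-strand gene: span 57000-60000, tss 60000, last codon 57050
  cases <- list(
    list(pos = 6600L,  class = "upstream_5kb", gene = "gplus"),   # 3400 bp 5'
    list(pos = 9999L,  class = "upstream_5kb", gene = "gplus"),
    list(pos = 4999L,  class = "gene_proximal_10kb", gene = "gplus"),
    list(pos = 10050L, class = "exon_other", gene = "gplus"),     # 5' UTR
    list(pos = 11000L, class = "intron", gene = "gplus"),
    list(pos = 13500L, class = "downstream_1kb", gene = "gplus"),
    list(pos = 14500L, class = "gene_proximal_10kb", gene = "gplus"),
    list(pos = 30000L, class = "intergenic", gene = NA_character_),
    # minus-strand arithmetic mirrors everything
    list(pos = 60500L, class = "upstream_5kb", gene = "gminus"),
    list(pos = 56850L, class = "downstream_1kb", gene = "gminus"), # 200 bp past
    list(pos = 58500L, class = "intron", gene = "gminus"),
    list(pos = 55000L, class = "gene_proximal_10kb", gene = "gminus")
  )
  ann <- annotate_snps(mk(vapply(cases, `[[`, integer(1), "pos")), genes)
  for (i in seq_along(cases)) {
    expect_identical(ann$positional_class[i], cases[[i]]$class,
                     label = paste("pos", cases[[i]]$pos))
    expect_identical(ann$gene_id[i], cases[[i]]$gene,
                     label = paste("gene at", cases[[i]]$pos))
  }
})

test_that("every SNP gets exactly one class and counts sum to the total", {
  cfg <- sim_config(n_snps = 2000L, seed = 41L)
  ds <- simulate_dataset(cfg)
  ann <- annotate_snps(ds$gm$variants, ds$genes)
  expect_identical(nrow(ann), nrow(ds$gm$variants))
  expect_true(all(ann$positional_class %in% haplopop:::POSITIONAL_CLASSES))
  expect_identical(sum(table(ann$positional_class)), nrow(ann))
  # gene placement leaves deep intergenic space
  expect_gt(sum(ann$positional_class == "intergenic"), 0L)
})

test_that("reflecting coordinates and flipping strands preserves classes", {
  genes <- toy_genes()
  L <- 100000L
  flip_genes <- genes
  flip_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  flip_genes$tss <- L - genes$tss + 1L
  flip_genes$last_codon_end <- L - genes$last_codon_end + 1L
  flip_genes$span_start <- L - genes$span_end + 1L
  flip_genes$span_end <- L - genes$span_start + 1L
  flip_genes$exons <- I(lapply(genes$exons, function(m)
    cbind(start = L - m[, "end"] + 1L, end = L - m[, "start"] + 1L)))
  flip_genes$cds <- I(lapply(genes$cds, function(m)
    cbind(start = L - m[, "end"] + 1L, end = L - m[, "start"] + 1L,
          phase = m[, "phase"])))
  set.seed(6)
  pos <- sample.int(70000L, 300)
  vv <- data.frame(id = paste0("s", seq_along(pos)), scaffold = "scf01",
                   pos = pos, ref = "A", alt = "T", stringsAsFactors = FALSE)
  fv <- vv; fv$pos <- L - pos + 1L
  a1 <- annotate_snps(vv, genes)
  a2 <- annotate_snps(fv, flip_genes)
  expect_identical(a2$positional_class, a1$positional_class)
})

test_that("codon_effect agrees with translation brute force", {
  expect_identical(codon_effect("GCT", 3, "C"), "exon_synonymous")   # Ala>Ala
  expect_identical(codon_effect("GCT", 2, "A"), "exon_nonsynonymous") # Ala>Asp
  set.seed(10)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    codon <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      tr <- function(s) as.character(Biostrings::translate(
        Biostrings::DNAString(s), no.init.codon = TRUE))
      oracle <- if (tr(codon) == tr(mut))
        "exon_synonymous" else "exon_nonsynonymous"
      expect_identical(codon_effect(codon, pos, b), oracle,
                       label = paste(codon, pos, b))
    }
  }
})

test_that("CDS SNPs are classified syn/nonsyn from the reference sequence", {
  genes <- toy_genes()
  refseq <- toy_refseq()
  # every CDS base of the plus-strand gene, brute-forced via codon lookup
  cdm <- genes$cds[[1]]
  cds_pos <- c(cdm[1, "start"]:cdm[1, "end"], cdm[2, "start"]:cdm[2, "end"])
  seq <- refseq$scf01
  base_at <- function(p) substr(seq, p, p)
  set.seed(12)
  take <- sample(seq_along(cds_pos), 40)
  vv <- data.frame(
    id = paste0("c", seq_along(take)), scaffold = "scf01",
    pos = cds_pos[take], ref = vapply(cds_pos[take], base_at, character(1)),
    alt = "A", stringsAsFactors = FALSE)
  vv$alt <- ifelse(vv$ref == "A", "G", "A")
  ann <- annotate_snps(vv, genes, refseq = refseq)
  for (i in seq_along(take)) {
    off <- take[i]
    codon_idx <- (off - 1) %/% 3
    codon <- paste(vapply(cds_pos[codon_idx * 3 + 1:3], base_at,
                          character(1)), collapse = "")
    oracle <- codon_effect(codon, (off - 1) %% 3 + 1, vv$alt[i])
    expect_identical(ann$positional_class[i], oracle,
                     label = paste("cds offset", off))
  }
  # without a reference sequence CDS SNPs degrade to exon_other
  ann0 <- annotate_snps(vv, genes)
  expect_true(all(ann0$positional_class == "exon_other"))
})

test_that("polarization follows outgroup consensus", {
  calls <- rbind(c(0L, 1L, 0L, 0L),   # outgroup ref/ref -> derived alt
                 c(0L, 1L, 1L, 1L),   # outgroup alt/alt -> derived ref
                 c(0L, 1L, 0L, 1L),   # discordant -> unpolarized
                 c(0L, 1L, 3L, 3L),   # uncalled -> unpolarized
                 c(0L, 1L, 3L, 0L))   # single called outgroup suffices
  gm <- toy_gm(calls, population = c("p1", "p1", "out", "out"),
               is_outgroup = c(FALSE, FALSE, TRUE, TRUE))
  pol <- polarize_alleles(gm)
  expect_identical(pol$derived_allele,
                   c("alt", "ref", "unpolarized", "unpolarized", "alt"))
  expect_identical(pol$ancestral_allele,
                   c("ref", "alt", "unpolarized", "unpolarized", "ref"))
})

test_that("hypergeometric p matches combinatorial enumeration to 1e-12", {
  e <- hypergeom_enrichment(5, 5, 5, 10)
  expect_equal(e$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(0, 3, 4, 10)$p_value, 1,
               tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:20) {
    N <- sample(5:60, 1)
    n <- sample(1:N, 1)
    K <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(hypergeom_enrichment(k, K, n, N)$p_value,
                 hyper_oracle(k, K, n, N), tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
})

test_that("positional and gene-set enrichment wire counts correctly", {
  ann <- data.frame(
    id = paste0("v", 1:10), scaffold = "s", pos = 1:10,
    positional_class = c(rep("upstream_5kb", 4), rep("intergenic", 6)),
    gene_id = NA, distance_to_gene = NA, stringsAsFactors = FALSE)
  e <- positional_enrichment(paste0("v", 1:3), ann, "upstream_5kb")
  expect_identical(c(e$k, e$K, e$n, e$N), c(3L, 4L, 3L, 10L))
  expect_equal(e$p_value, hyper_oracle(3, 4, 3, 10), tolerance = 1e-12)
  expect_error(positional_enrichment(character(), ann, "upstream_5kb"),
               "empty")
  expect_error(positional_enrichment("vX", ann, "upstream_5kb"), "absent")

  u <- paste0("g", 1:20)
  e2 <- gene_set_enrichment(u[1:5], u[c(1, 2, 10, 11)], u)
  expect_identical(c(e2$k, e2$K, e2$n, e2$N), c(2L, 4L, 5L, 20L))
  expect_equal(e2$p_value, hyper_oracle(2, 4, 5, 20), tolerance = 1e-12)
  # degenerate identities
  expect_equal(gene_set_enrichment(u, u, u)$p_value, 1)
  expect_equal(gene_set_enrichment(u[1:3], u[10:12], u)$p_value, 1)
  expect_error(gene_set_enrichment("gX", u[1:2], u), "subset")
})

test_that("polarization recovers simulated ancestral alleles", {
  cfg <- sim_config(n_snps = 2000L, seed = 43L)
  ds <- simulate_dataset(cfg)
  pol <- polarize_alleles(ds$gm)
  polarizable <- pol$derived_allele != "unpolarized"
  agree <- pol$ancestral_allele[polarizable] ==
    ds$truth$ancestral_allele[polarizable]
  expect_gt(mean(agree), 0.95)
  expect_gt(mean(polarizable), 0.9)
})
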