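# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures live in the repository.

# minimal variant/sample tables around a raw call matrix
toy_gm <- function(calls, pos = NULL, scaffold = "scf01",
                   qual = 100, class = "snp", ref = "A", alt = "T",
                   population = NULL, behavior = NULL,
                   is_outgroup = NULL) {
  calls <- as.matrix(calls)
  m <- nrow(calls); n <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(population)) population <- rep("popA", n)
  if (is.null(behavior)) behavior <- rep("unknown", n)
  if (is.null(is_outgroup)) is_outgroup <- rep(FALSE, n)
  genotype_matrix(
    calls,
    variants = data.frame(
      id = paste0("v", seq_len(m)), scaffold = rep(scaffold, length.out = m),
      pos = pos, ref = rep(ref, length.out = m),
      alt = rep(alt, length.out = m), qual = rep(qual, length.out = m),
      class = rep(class, length.out = m), stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = paste0("s", seq_len(n)), population = population,
      behavior = behavior, is_outgroup = is_outgroup,
      stringsAsFactors = FALSE)
  )
}

# two-group haploid matrix from per-group allele counts at one site
two_pop_site <- function(alt1, n1, alt2, n2) {
  calls <- matrix(c(rep(1L, alt1), rep(0L, n1 - alt1),
                    rep(1L, alt2), rep(0L, n2 - alt2)), nrow = 1)
  toy_gm(calls, population = rep(c("p1", "p2"), c(n1, n2)))
}

# independently coded direct-formula Weir-Cockerham oracle (haploid):
# scalar arithmetic straight from the variance-component definitions
wc_oracle <- function(p, n) {
  r <- length(p)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  list(a = a, b = b, fst = a / (a + b))
}

# brute-force upper-tail hypergeometric by combinatorial enumeration
hyper_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# QC fixture: 50 sites with hand-planted violations; returns the matrix
# and the ids that must survive the default cascade
qc_fixture <- function() {
  set.seed(42)
  n <- 40L   # ingroup haploids
  m <- 50L
  calls <- matrix(rep(c(0L, 1L), length.out = n * m), nrow = m,
                  byrow = TRUE)  # alternating alleles within a row: MAF 0.5
  variants <- data.frame(
    id = sprintf("v%02d", 1:m), scaffold = "scf01", pos = (1:m) * 1000L,
    ref = "A", alt = "T", qual = 100, class = "snp",
    stringsAsFactors = FALSE)
  # planted violations (disjoint sites so the expected set is a hand count)
  variants$class[1:3] <- "indel"
  variants$ref[1:3] <- "A"; variants$alt[1:3] <- "AT"
  variants$qual[4:6] <- 29.9
  calls[7, 1:15] <- 2L                    # H in exactly 15 individuals
  calls[8, 1:14] <- 2L                    # H in 14 -> retained
  calls[9, 1:16] <- 3L                    # missing in 16
  calls[10, 1:15] <- 3L                   # missing in 15 -> retained
  variants$alt[11:12] <- "T,G"            # multiallelic
  calls[13, ] <- c(rep(1L, 1), rep(0L, n - 1))   # MAF 1/40 = 0.025
  calls[14, ] <- c(rep(1L, 2), rep(0L, n - 2))   # MAF 0.05 -> retained
  gm <- toy_gm(calls)
  gm$variants <- variants
  rownames(gm$calls) <- variants$id
  removed <- c(sprintf("v%02d", c(1:7, 9, 11:13)))
  list(gm = gm, expect_removed = removed,
       expect_retained = setdiff(variants$id, removed))
}

# tiny two-strand gene set for annotation tests, built directly
toy_genes <- function() {
  plus <- data.frame(
    gene_id = "gplus", scaffold = "scf01", strand = "+",
    tss = 10000L, last_codon_end = 12950L,
    span_start = 10000L, span_end = 13000L,
    exons = I(list(cbind(start = c(10000L, 12000L),
                         end = c(10500L, 13000L)))),
    cds = I(list(cbind(start = c(10100L, 12000L),
                       end = c(10500L, 12950L),
                       phase = c(0L, 2L)))),
    stringsAsFactors = FALSE)
  minus <- data.frame(
    gene_id = "gminus", scaffold = "scf01", strand = "-",
    tss = 60000L, last_codon_end = 57050L,
    span_start = 57000L, span_end = 60000L,
    exons = I(list(cbind(start = c(59000L, 57000L),
                         end = c(60000L, 58000L)))),
    cds = I(list(cbind(start = c(59000L, 57050L),
                       end = c(59900L, 58000L),
                       phase = c(0L, 2L)))),
    stringsAsFactors = FALSE)
  g <- rbind(plus, minus)
  class(g) <- c("gene_models", class(g))
  g
}

# deterministic scaffold sequence so codon lookups are reproducible
toy_refseq <- function(len = 70000L) {
  set.seed(99)
  list(scf01 = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
}
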