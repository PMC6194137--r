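test_that("pi matches the brute-force pairwise count and trivial cases", {
  # 4 haplotypes {0,0,1,1} at one site, L = 1: 4 of the 6 pairs differ
  gm <- toy_gm(matrix(c(0L, 0L, 1L, 1L), nrow = 1))
  div <- nucleotide_diversity(gm, L = 1)
  # brute-force oracle: mean pairwise difference over all C(4,2) pairs
  h <- c(0, 0, 1, 1)
  pairs <- combn(4, 2)
  oracle <- mean(h[pairs[1, ]] != h[pairs[2, ]])
  expect_equal(oracle, 2 / 3)
  expect_equal(div$pi_per_site, oracle, tolerance = 1e-12)

  mono <- toy_gm(matrix(0L, nrow = 5, ncol = 6))
  expect_equal(nucleotide_diversity(mono, L = 100)$pi_per_site, 0)
})

test_that("Watterson's theta follows the harmonic-sum formula", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 4, 100), 3 / ((1 + 1/2 + 1/3) * 100),
               tolerance = 1e-12)
  expect_equal(watterson_theta(7, 2, 50), 7 / 50)   # a_2 = 1
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
})

test_that("pi and theta agree on theta-calibrated neutral simulations", {
  # neutral-SFS generator with the layout chosen so theta_W targets 0.002
  n <- 150L
  a_n <- sum(1 / seq_len(n - 1L))
  S <- 2000L
  L <- round(S / (a_n * 0.002))
  res <- sapply(1:5, function(s) {
    cfg <- sim_config(
      n_snps = S, ancestral_maf_law = "neutral_sfs",
      het_artifact_rate = 0, missing_rate = 0,
      scaffold_layout = data.frame(scaffold = "scf01", length = L),
      seed = 600L + s)
    d <- nucleotide_diversity(ingroup(simulate_dataset(cfg)$gm), L = L)
    c(pi = d$pi_per_site, theta = d$watterson_theta_per_site)
  })
  pi_hat <- mean(res["pi", ])
  expect_gt(pi_hat, 0.002 * 0.8)
  expect_lt(pi_hat, 0.002 * 1.2)
  ratio <- pi_hat / mean(res["theta", ])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("Weir-Cockerham F_ST matches the direct-formula oracle to 1e-12", {
  # printed example: p = (0.8, 0.2), 10 haploids per group
  gm <- two_pop_site(8L, 10L, 2L, 10L)
  res <- weir_cockerham_fst(gm, grouping = gm$samples$population)
  orc <- wc_oracle(c(0.8, 0.2), c(10, 10))
  expect_equal(res$per_site$fst[1], orc$fst, tolerance = 1e-12)
  expect_equal(res$per_site$a[1], orc$a, tolerance = 1e-12)

  # 100 random configurations, 2-5 groups, unequal sizes
  set.seed(7)
  for (rep in 1:100) {
    r <- sample(2:5, 1)
    n <- sample(3:30, r, replace = TRUE)
    alt <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
    calls <- matrix(unlist(mapply(function(a, ni)
      c(rep(1L, a), rep(0L, ni - a)), alt, n, SIMPLIFY = FALSE)),
      nrow = 1)
    gm <- toy_gm(calls, population = rep(paste0("g", seq_len(r)), n))
    res <- weir_cockerham_fst(gm, grouping = gm$samples$population)
    orc <- wc_oracle(alt / n, n)
    if (orc$a + orc$b == 0) {
      expect_true(is.na(res$per_site$fst[1]))
    } else {
      expect_equal(res$per_site$fst[1], orc$fst, tolerance = 1e-12)
    }
  }
})

test_that("F_ST limits: fixed difference gives 1, no differentiation ~ 0", {
  fixed <- two_pop_site(10L, 10L, 0L, 10L)
  expect_equal(
    weir_cockerham_fst(fixed, fixed$samples$population)$per_site$fst[1], 1)

  # identical frequencies, equal sizes -> per-site estimate <= 0
  same <- two_pop_site(5L, 10L, 5L, 10L)
  expect_lte(
    weir_cockerham_fst(same, same$samples$population)$per_site$fst[1], 0)

  # many such sites -> genome-wide near zero
  set.seed(11)
  m <- 500L
  p <- runif(m, 0.2, 0.8)
  calls <- t(vapply(p, function(pi) c(rbinom(15, 1, pi), rbinom(15, 1, pi)),
                    integer(30)))
  gm <- toy_gm(calls, population = rep(c("a", "b"), each = 15))
  gw <- weir_cockerham_fst(gm, gm$samples$population)$genome_wide
  expect_lt(abs(gw), 0.02)
})

test_that("genome-wide F_ST is ratio-of-sums, not mean of ratios", {
  gm <- toy_gm(rbind(
    c(1L, 1L, 1L, 0L, 0L, 0L),
    c(1L, 0L, 1L, 0L, 1L, 0L)),
    population = rep(c("a", "b"), each = 3))
  res <- weir_cockerham_fst(gm, gm$samples$population)
  ps <- res$per_site
  expect_equal(res$genome_wide, sum(ps$a) / sum(ps$denom), tolerance = 1e-12)
  mor <- weir_cockerham_fst(gm, gm$samples$population,
                            genome_wide_method = "mean_of_ratios")
  expect_equal(mor$genome_wide, mean(ps$fst), tolerance = 1e-12)
})

test_that("sites with an under-called group are skipped", {
  calls <- rbind(c(1L, 0L, 3L, 3L, 3L, 0L),
                 c(1L, 0L, 1L, 0L, 1L, 0L))
  gm <- toy_gm(calls, population = rep(c("a", "b"), each = 3))
  res <- weir_cockerham_fst(gm, gm$samples$population)
  expect_true(is.na(res$per_site$fst[1]))
  expect_identical(res$n_sites_used, 1L)
})

test_that("permutation p-value agrees with exhaustive enumeration on 3v3", {
  set.seed(3)
  m <- 60L
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + runif(m, -0.4, 0.4), 0), 1)
  calls <- t(vapply(seq_len(m), function(i)
    c(rbinom(3, 1, p1[i]), rbinom(3, 1, p2[i])), integer(6)))
  gm <- toy_gm(calls, population = rep(c("a", "b"), each = 3),
               behavior = rep(c("social", "solitary"), each = 3))
  res <- fst_permutation_test(gm, n_perm = 2000L, seed = 9L)

  # oracle: enumerate all 20 label arrangements directly
  d <- as_dosage(gm)
  gw <- function(lab) {
    f <- weir_cockerham_fst(gm, lab)$genome_wide
    f
  }
  obs <- gw(gm$samples$behavior)
  combos <- combn(6, 3)
  null <- apply(combos, 2, function(idx) {
    lab <- rep("solitary", 6); lab[idx] <- "social"
    gw(lab)
  })
  p_exh <- mean(null >= obs)
  expect_lt(abs(res$p_value - p_exh), 0.05)
  expect_equal(res$observed_fst, obs, tolerance = 1e-12)
})

test_that("perfect differentiation attains the minimum p = 1/(n_perm+1)", {
  calls <- matrix(rep(c(rep(1L, 10), rep(0L, 10)), 40), nrow = 40,
                  byrow = TRUE)
  gm <- toy_gm(calls, population = rep(c("a", "b"), each = 10),
               behavior = rep(c("social", "solitary"), each = 10))
  res <- fst_permutation_test(gm, n_perm = 1000L, seed = 1L)
  expect_equal(res$p_value, 1 / 1001)
  expect_equal(res$observed_fst, 1)
})

test_that("r2 matches hand-computed toy columns", {
  gm <- toy_gm(rbind(c(0L, 0L, 1L, 1L),
                     c(0L, 0L, 1L, 1L),
                     c(0L, 1L, 0L, 1L),
                     c(0L, 0L, 1L, 0L)), pos = c(100L, 150L, 200L, 250L))
  ld <- ld_r2(gm, window_bp = 1000L)
  get <- function(pa, pb)
    ld$pairs$r2[ld$pairs$pos1 == pa & ld$pairs$pos2 == pb]
  expect_equal(get(100, 150), 1, tolerance = 1e-12)   # identical columns
  expect_equal(get(100, 200), 0, tolerance = 1e-12)   # D = 0
  expect_equal(get(100, 250), 1 / 3, tolerance = 1e-12)
})

test_that("zero-variance pairs are skipped and window respected", {
  gm <- toy_gm(rbind(c(0L, 0L, 0L, 0L),
                     c(0L, 1L, 0L, 1L),
                     c(0L, 1L, 1L, 0L)), pos = c(100L, 200L, 40000L))
  ld <- ld_r2(gm, window_bp = 50000L)
  # the monomorphic first site contributes nothing, leaving the single
  # informative pair
  expect_identical(nrow(ld$pairs), 1L)
  expect_identical(ld$pairs$pos1, 200L)
})

test_that("VIF pruning removes correlated variants and nothing else", {
  set.seed(5)
  n <- 60L
  # orthogonal variants (Hadamard columns): nothing pruned
  H2 <- matrix(c(1, 1, 1, -1), 2)
  H16 <- H2 %x% H2 %x% H2 %x% H2
  indep <- t((H16[, 2:13] + 1L) / 2L)
  gm <- toy_gm(indep)
  expect_identical(length(ld_prune(gm)), 12L)

  # two identical adjacent variants: exactly one (the later) removed
  x <- rbinom(n, 1, 0.5)
  dup <- rbind(matrix(rbinom(5 * n, 1, 0.5), nrow = 5), x, x)
  gm2 <- toy_gm(dup, pos = c(1:5, 100, 200) * 10L)
  kept <- ld_prune(gm2)
  expect_identical(length(kept), 6L)
  expect_true("v6" %in% kept)
  expect_false("v7" %in% kept)

  # a perfectly correlated 3-variant block in a 10-variant window -> 8 kept
  y <- rbinom(n, 1, 0.5)
  blk <- rbind(matrix(rbinom(7 * n, 1, 0.5), nrow = 7), y, y, y)
  gm3 <- toy_gm(blk)
  kept3 <- ld_prune(gm3)
  expect_identical(length(kept3), 8L)

  # brute-force recomputation: replay the pruning windows (original
  # coordinate grid) and verify every retained variant's VIF < 2
  cfg <- sim_config(n_snps = 600L, seed = 37L)
  ds <- simulate_dataset(cfg)
  gm4 <- ingroup(ds$gm)
  kept4 <- ld_prune(gm4)
  d <- t(as_dosage(gm4, impute = "mean"))
  v <- gm4$variants
  retained <- v$id %in% kept4
  worst <- 0
  for (scf in unique(v$scaffold)) {
    idx <- which(v$scaffold == scf)
    for (s in seq(1L, length(idx), by = 5L)) {
      win <- idx[s:min(s + 49L, length(idx))]
      win <- win[retained[win]]
      win <- win[apply(d[, win, drop = FALSE], 2, var) > 0]
      if (length(win) < 2) next
      vifs <- diag(solve(cor(d[, win])))
      worst <- max(worst, vifs)
    }
  }
  expect_lt(worst, 2)
})

test_that("PCA separates fixed populations and is sample-order equivariant", {
  calls <- cbind(matrix(0L, 30, 8), matrix(1L, 30, 8))
  gm <- toy_gm(calls, population = rep(c("a", "b"), each = 8))
  pca <- suppressWarnings(genotype_pca(gm, n_components = 2))
  pc1 <- pca$sample_coordinates[, 1]
  expect_lt(max(tapply(pc1, gm$samples$population, var)), 1e-20)
  expect_gt(abs(diff(tapply(pc1, gm$samples$population, mean))), 1)

  set.seed(8)
  calls2 <- matrix(rbinom(40 * 12, 1, 0.4), nrow = 40)
  gm2 <- toy_gm(calls2)
  perm <- sample(12)
  p_orig <- genotype_pca(gm2, n_components = 3)
  p_perm <- genotype_pca(gm2[, perm], n_components = 3)
  # same subspace: coordinates agree up to per-component sign
  for (k in 1:3)
    expect_equal(abs(p_perm$sample_coordinates[, k]),
                 abs(p_orig$sample_coordinates[perm, k]), tolerance = 1e-8)
  expect_equal(p_perm$eigenvalues, p_orig$eigenvalues, tolerance = 1e-10)

  # eigenvalues non-increasing, coordinates column-orthogonal
  expect_true(all(diff(p_orig$eigenvalues) <= 1e-12))
  cp <- crossprod(p_orig$sample_coordinates)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
})
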