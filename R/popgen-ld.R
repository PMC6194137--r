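#' Pairwise linkage disequilibrium (r-squared) within windows
#'
#' For every same-scaffold variant pair within `window_bp`, r-squared is the
#' squared Pearson correlation of the two haploid 0/1 vectors over jointly
#' called samples. Pairs involving a zero-variance site are skipped. A
#' binned decay curve is attached (default edges: 0-50 bp, then log-spaced
#' up to the window).
#'
#' @param gm A [genotype_matrix()] (outgroup excluded).
#' @param window_bp Maximum pair distance in bp (default 50000).
#' @param bin_edges Optional numeric vector of distance-bin edges.
#' @return List of class `ld_result`: `pairs` (`data.frame` scaffold,
#'   pos1, pos2, dist, r2), `decay` (`data.frame` bin_lo, bin_hi, mean_r2,
#'   n_pairs) and `window_bp`.
#' @export
ld_r2 <- function(gm, window_bp = 50000L, bin_edges = NULL) {
  ing <- ingroup(gm)
  ord <- order(ing$variants$scaffold, ing$variants$pos)
  ing <- ing[ord, ]
  d <- as_dosage(ing)
  v <- ing$variants
  out <- vector("list", 0L)
  for (scf in unique(v$scaffold)) {
    idx <- which(v$scaffold == scf)
    pos <- v$pos[idx]
    m <- length(idx)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      jmax <- findInterval(pos[i] + window_bp, pos)
      if (jmax <= i) next
      js <- (i + 1L):jmax
      r <- suppressWarnings(
        cor(d[idx[i], ], t(d[idx[js], , drop = FALSE]),
            use = "pairwise.complete.obs"))
      out[[length(out) + 1L]] <- data.frame(
        scaffold = scf, pos1 = pos[i], pos2 = pos[js],
        dist = pos[js] - pos[i], r2 = as.numeric(r)^2,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out)
           else data.frame(scaffold = character(), pos1 = integer(),
                           pos2 = integer(), dist = integer(),
                           r2 = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  if (is.null(bin_edges)) {
    hi <- max(window_bp, 100)
    bin_edges <- unique(c(0, 50, round(exp(seq(log(50), log(hi),
                                               length.out = 10)))[-1]))
  }
  bin <- cut(pairs$dist, bin_edges, include.lowest = TRUE, right = TRUE)
  decay <- data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    mean_r2 = as.numeric(tapply(pairs$r2, bin, mean)),
    n_pairs = as.integer(table(bin))
  )
  res <- list(pairs = pairs, decay = decay, window_bp = window_bp)
  class(res) <- "ld_result"
  res
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD: %d pairs within %d bp; mean r2 = %.3f\n",
              nrow(x$pairs), x$window_bp, mean(x$pairs$r2)))
  invisible(x)
}

#' Variance-inflation-factor LD pruning
#'
#' PLINK-style `--indep`-type pruning: a sliding window of `window_snps`
#' variants advancing by `step_snps` per scaffold; within each window the
#' variant with the highest VIF (`1/(1-R^2)` from regressing it on the other
#' retained window variants, i.e. the diagonal of the inverted correlation
#' matrix) is removed iteratively until all VIFs fall below
#' `vif_threshold`. Removal is global: a variant removed in one window stays
#' removed. Exactly collinear (duplicate) variants are resolved by removing
#' the later-coordinate member first. Missing/artifact calls are
#' mean-imputed for the correlations. The defaults mirror
#' `--indep 50 5 2`.
#'
#' @param gm A [genotype_matrix()] (outgroup excluded), coordinate-sorted.
#' @param window_snps Window size in variants.
#' @param step_snps Step size in variants.
#' @param vif_threshold VIF threshold (2 corresponds to R^2 = 0.5).
#' @return Character vector of retained variant ids (coordinate order).
#' @export
ld_prune <- function(gm, window_snps = 50L, step_snps = 5L,
                     vif_threshold = 2) {
  stopifnot(window_snps >= 2L, step_snps >= 1L, vif_threshold > 1)
  ing <- ingroup(gm)
  ord <- order(ing$variants$scaffold, ing$variants$pos)
  ing <- ing[ord, ]
  d <- t(as_dosage(ing, impute = "mean"))   # samples x variants
  v <- ing$variants
  removed <- logical(nrow(v))
  # monomorphic columns carry no information and cannot enter a regression
  mono <- apply(d, 2L, function(x) var(x) == 0)
  for (scf in unique(v$scaffold)) {
    idx <- which(v$scaffold == scf)
    starts <- seq(1L, max(1L, length(idx)), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      repeat {
        act <- win[!removed[win] & !mono[win]]
        if (length(act) < 2L) break
        cc <- cor(d[, act, drop = FALSE])
        worst <- worst_vif(cc)
        if (is.null(worst)) break
        if (worst$vif < vif_threshold) break
        removed[act[worst$which]] <- TRUE
      }
    }
  }
  v$id[!removed]
}

# highest-VIF column of a correlation matrix; exact collinearity is
# resolved by flagging the later column of the most correlated pair
worst_vif <- function(cc) {
  k <- ncol(cc)
  off <- abs(cc); diag(off) <- 0
  if (max(off) >= 1 - 1e-10) {
    w <- which(off == max(off), arr.ind = TRUE)[1L, ]
    return(list(which = max(w), vif = Inf))
  }
  inv <- tryCatch(solve(cc), error = function(e) NULL)
  if (is.null(inv)) {
    w <- which(off == max(off), arr.ind = TRUE)[1L, ]
    return(list(which = max(w), vif = Inf))
  }
  vifs <- diag(inv)
  # ties broken toward the later coordinate
  top <- which(vifs == max(vifs))
  list(which = max(top), vif = max(vifs))
}
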