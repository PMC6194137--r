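#' Centered genomic relatedness matrix
#'
#' `K = G G' / m` over `m` variants, where `G` is the samples x variants
#' dosage matrix with missing/artifact calls mean-imputed per variant and
#' each variant column mean-centered. Symmetric positive semi-definite by
#' construction.
#'
#' @param gm A [genotype_matrix()] (typically ingroup, post-QC).
#' @return List of class `grm`: `K` (samples x samples), `n_snps_used`.
#' @export
compute_grm <- function(gm) {
  d <- t(as_dosage(gm, impute = "mean"))
  m <- ncol(d)
  if (m == 0L) stop("cannot build a relatedness matrix from zero variants")
  x <- sweep(d, 2L, colMeans(d), "-")
  K <- tcrossprod(x) / m
  dimnames(K) <- list(gm$samples$sample_id, gm$samples$sample_id)
  structure(list(K = K, n_snps_used = m, construction = "centered"),
            class = "grm")
}

# Profile restricted log-likelihood of the single-variance-ratio LMM
# y = X b + u + e,  u ~ N(0, sg2 K), e ~ N(0, se2 I), lambda = sg2/se2,
# evaluated in the eigenbasis of K (yt = U'y, Xt = U'X, d = eigenvalues).
reml_loglik <- function(loglam, d, yt, Xt) {
  v <- exp(loglam) * d + 1
  w <- 1 / v
  XtW <- Xt * w
  A <- crossprod(Xt, XtW)
  rhs <- crossprod(XtW, yt)
  beta <- solve(A, rhs)
  resid <- yt - Xt %*% beta
  rss <- sum(w * resid^2)
  nc <- length(yt) - ncol(Xt)
  -0.5 * (nc * log(2 * pi * rss / nc) + nc + sum(log(v)) +
            determinant(A, logarithm = TRUE)$modulus[1])
}

# Vectorized restricted log-likelihood over a log-lambda grid for every
# variant simultaneously (closed-form 2x2 GLS per variant per grid point).
reml_grid_loglik <- function(grid, d, yt, onet, Gt) {
  n <- length(yt)
  nc <- n - 2L
  Gt2 <- Gt^2
  out <- matrix(NA_real_, nrow = nrow(Gt), ncol = length(grid))
  for (g in seq_along(grid)) {
    w <- 1 / (exp(grid[g]) * d + 1)
    s11 <- sum(w * onet^2)
    s1y <- sum(w * onet * yt)
    syy <- sum(w * yt^2)
    slogv <- -sum(log(w))
    s1x <- drop(Gt %*% (w * onet))
    sxx <- drop(Gt2 %*% w)
    sxy <- drop(Gt %*% (w * yt))
    det <- s11 * sxx - s1x^2
    b1 <- (sxx * s1y - s1x * sxy) / det
    b2 <- (s11 * sxy - s1x * s1y) / det
    rss <- syy - 2 * (b1 * s1y + b2 * sxy) +
      b1^2 * s11 + 2 * b1 * b2 * s1x + b2^2 * sxx
    ok <- is.finite(det) & det > 0 & is.finite(rss) & rss > 0
    out[, g] <- ifelse(ok,
      -0.5 * (nc * log(2 * pi * pmax(rss, .Machine$double.xmin) / nc) +
                nc + slogv + log(pmax(det, .Machine$double.xmin))),
      -Inf)
  }
  out
}

#' Univariate linear mixed model association scan
#'
#' Fits `y = mu + x beta + u + e` per variant, with `u ~ N(0, sg2 K)`
#' absorbing relatedness/structure and `e ~ N(0, se2 I)`. `K` is
#' eigendecomposed once; for each variant the restricted likelihood is
#' profiled over `lambda = sg2/se2` by scalar optimization of `log(lambda)`
#' on `[1e-5, 1e5]` (`lambda_mode = "per_snp"`, the default) or using a
#' single null-model `lambda` for all variants (`"shared"`, faster). The
#' Wald statistic `(beta/se)^2` is referred to chi-square with 1 df, and
#' Benjamini-Hochberg q-values are attached.
#'
#' @param y Numeric phenotype vector (binary traits coded social = 1,
#'   solitary = 0 are treated as quantitative). No missing values.
#' @param gm A [genotype_matrix()] restricted to the phenotyped samples, in
#'   the same order as `y`.
#' @param K A [compute_grm()] result (or a bare symmetric matrix).
#' @param lambda_mode `"per_snp"` or `"shared"`.
#' @return `data.frame` of class `assoc_result`: id, scaffold, pos, beta,
#'   se, lambda, wald_p, fdr_q (coordinate-sorted as input). Zero-variance
#'   variants are reported with `NA` statistics; a non-finite fit yields
#'   `p = 1` and `flag = "nonfinite"`.
#' @export
lmm_scan <- function(y, gm, K = compute_grm(gm),
                     lambda_mode = c("per_snp", "shared")) {
  lambda_mode <- match.arg(lambda_mode)
  if (inherits(K, "grm")) K <- K$K
  n <- length(y)
  stopifnot(!anyNA(y), ncol(gm$calls) == n, nrow(K) == n)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  onet <- drop(crossprod(U, rep(1, n)))
  G <- as_dosage(gm, impute = "mean")       # variants x samples
  Gt <- tcrossprod(G, t(U))                 # variants x samples, rotated
  zero_var <- apply(G, 1L, function(x) var(x) == 0)
  bounds <- log(c(1e-5, 1e5))

  shared_lam <- NULL
  if (lambda_mode == "shared") {
    X0 <- matrix(onet, ncol = 1)
    opt <- optimize(reml_loglik, bounds, d = d, yt = yt, Xt = X0,
                    maximum = TRUE, tol = 1e-6)
    shared_lam <- exp(opt$maximum)
  }

  m <- nrow(gm$calls)
  # coarse vectorized profile over a log-lambda grid brackets the optimum
  # for every variant at once; each is then refined by scalar optimization
  # within its bracketing grid cell
  best_cell <- NULL
  grid <- seq(bounds[1], bounds[2], length.out = 41L)
  if (lambda_mode == "per_snp" && m > 0L) {
    ll_grid <- reml_grid_loglik(grid, d, yt, onet, Gt)
    best_cell <- max.col(ll_grid, ties.method = "first")
  }

  beta <- se <- lam <- p <- rep(NA_real_, m)
  flag <- rep("", m)
  for (j in seq_len(m)) {
    if (zero_var[j]) { flag[j] <- "zero_variance"; next }
    Xt <- cbind(onet, Gt[j, ])
    lj <- if (is.null(shared_lam)) {
      k <- best_cell[j]
      iv <- grid[c(max(1L, k - 1L), min(length(grid), k + 1L))]
      opt <- tryCatch(
        optimize(reml_loglik, iv, d = d, yt = yt, Xt = Xt,
                 maximum = TRUE, tol = 1e-4),
        error = function(e) NULL)
      if (is.null(opt)) NA_real_ else exp(opt$maximum)
    } else shared_lam
    if (!is.finite(lj)) { p[j] <- 1; flag[j] <- "nonfinite"; next }
    w <- 1 / (lj * d + 1)
    A <- crossprod(Xt, Xt * w)
    fit <- tryCatch({
      bh <- solve(A, crossprod(Xt * w, yt))
      resid <- yt - Xt %*% bh
      rss <- sum(w * resid^2)
      s2 <- rss / (n - 2L)
      sej <- sqrt(s2 * solve(A)[2L, 2L])
      list(beta = bh[2L], se = sej)
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$se) || fit$se <= 0) {
      p[j] <- 1; flag[j] <- "nonfinite"; next
    }
    beta[j] <- fit$beta
    se[j] <- fit$se
    lam[j] <- lj
    p[j] <- pchisq((fit$beta / fit$se)^2, df = 1, lower.tail = FALSE)
    p[j] <- max(p[j], .Machine$double.xmin)   # keep p in (0, 1]
  }
  res <- data.frame(
    id = gm$variants$id, scaffold = gm$variants$scaffold,
    pos = gm$variants$pos, beta = beta, se = se, lambda = lam,
    wald_p = p, flag = flag, stringsAsFactors = FALSE
  )
  res$fdr_q <- rep(NA_real_, m)
  tested <- !is.na(res$wald_p)
  res$fdr_q[tested] <- fdr_correct(res$wald_p[tested])
  class(res) <- c("assoc_result", class(res))
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up rule: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @return q-value vector in input order (empty input gives empty output).
#' @export
fdr_correct <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric())
  ord <- order(pvals)
  q <- pmin(rev(cummin(rev(pvals[ord] * m / seq_len(m)))), 1)
  q[order(ord)]
}

#' Variants passing the FDR significance threshold
#'
#' @param res An [lmm_scan()] result.
#' @param q_threshold FDR threshold (default `5e-5`, the genome-wide level
#'   used in the originating study).
#' @return Subset of `res` with `fdr_q < q_threshold`, sorted by q then by
#'   scaffold and position.
#' @export
significant_hits <- function(res, q_threshold = 5e-5) {
  hit <- !is.na(res$fdr_q) & res$fdr_q < q_threshold
  out <- res[hit, , drop = FALSE]
  out[order(out$fdr_q, out$scaffold, out$pos), , drop = FALSE]
}
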