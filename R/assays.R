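#' qPCR delta-CT normalization, fold change and group test
#'
#' Technical replicates are collapsed to their mean per sample and gene
#' (the biological replicate is the unit of analysis). Per sample,
#' `dCT = mean(CT_target) - mean(CT_reference)`; relative expression is
#' `fold = 2^-(dCT - mean dCT of the baseline group)`, so the baseline
#' group's fold changes have geometric mean 1. Group differences in dCT are
#' tested with a two-sided two-sample t-test (pooled variance by default).
#'
#' @param tbl Long-format `data.frame` with columns `sample`, `group`,
#'   `gene`, `ct` (one row per technical replicate).
#' @param target Target gene name in `tbl$gene`.
#' @param reference Reference (housekeeping) gene name.
#' @param baseline_group Group whose mean dCT anchors the fold change
#'   (default `"solitary"`).
#' @param var_equal Pooled-variance t-test (default); `FALSE` gives Welch.
#' @return List of class `qpcr_result`: `per_sample` (`data.frame` sample,
#'   group, dct, fold), `t`, `df`, `p_value`, `group_means` (mean dCT).
#' @export
qpcr_fold_change <- function(tbl, target, reference,
                             baseline_group = "solitary",
                             var_equal = TRUE) {
  req <- c("sample", "group", "gene", "ct")
  if (!all(req %in% names(tbl)))
    stop("qPCR table must have columns: ", paste(req, collapse = ", "))
  stopifnot(all(tbl$ct > 0))
  if (!baseline_group %in% tbl$group)
    stop("baseline group '", baseline_group, "' not present")
  if (!all(c(target, reference) %in% tbl$gene))
    stop("target/reference gene missing from table")
  mean_ct <- function(gene) {
    sub <- tbl[tbl$gene == gene, ]
    agg <- aggregate(ct ~ sample + group, data = sub, FUN = mean)
    agg
  }
  tg <- mean_ct(target)
  rf <- mean_ct(reference)
  per <- merge(tg, rf, by = c("sample", "group"),
               suffixes = c("_target", "_reference"))
  if (nrow(per) == 0L) stop("no sample has both target and reference CTs")
  per$dct <- per$ct_target - per$ct_reference
  base_mean <- mean(per$dct[per$group == baseline_group])
  per$fold <- 2^-(per$dct - base_mean)
  groups <- unique(per$group)
  if (length(groups) != 2L) stop("exactly two groups required")
  x <- per$dct[per$group == groups[1]]
  y <- per$dct[per$group == groups[2]]
  tt <- stats::t.test(x, y, var.equal = var_equal)
  res <- list(
    per_sample = per[order(per$group, per$sample),
                     c("sample", "group", "dct", "fold")],
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    group_means = setNames(c(mean(x), mean(y)), groups),
    baseline_group = baseline_group
  )
  class(res) <- "qpcr_result"
  res
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qPCR dCT test: t = %.4g (df = %.4g), p = %.4g\n",
              x$t, x$df, x$p_value))
  cat("mean fold change by group:\n")
  print(tapply(x$per_sample$fold, x$per_sample$group, mean))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA on replicate measurements per construct /
#' group, followed by all-pairs Tukey HSD using the studentized range
#' distribution; unbalanced pairs use the harmonic mean of the two group
#' sizes (Tukey-Kramer). Groups with a single replicate are excluded from
#' the post-hoc table with a warning.
#'
#' @param values Numeric measurements (luminescence or fold change).
#' @param group Group label per measurement (>= 2 groups, >= 2 replicates
#'   per group for the ANOVA).
#' @return List of class `anova_tukey_result`: `F`, `df` (c(between,
#'   within)), `p_value`, `group_means`, `ms_within` and `tukey`
#'   (`data.frame` comparison, diff, p_adj).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2L)
  ni <- tabulate(group)
  if (any(ni < 2L))
    warning("group(s) with a single replicate: ",
            paste(levels(group)[ni < 2L], collapse = ", "))
  k <- nlevels(group)
  n <- length(values)
  gm <- tapply(values, group, mean)
  grand <- mean(values)
  ss_between <- sum(ni * (gm - grand)^2)
  ss_within <- sum((values - gm[group])^2)
  df1 <- k - 1L
  df2 <- n - k
  msb <- ss_between / df1
  msw <- ss_within / df2
  Fstat <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  pval <- if (is.infinite(Fstat)) 0
          else if (msw == 0 && msb == 0) 1
          else pf(Fstat, df1, df2, lower.tail = FALSE)

  lv <- levels(group)[ni >= 2L]
  pairs <- if (length(lv) >= 2L) t(utils::combn(lv, 2L)) else
    matrix(character(), ncol = 2)
  tukey <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    g1 <- pairs[r, 1]; g2 <- pairs[r, 2]
    n1 <- sum(group == g1); n2 <- sum(group == g2)
    nh <- 2 / (1 / n1 + 1 / n2)       # harmonic mean pair size
    diff <- gm[g2] - gm[g1]
    se <- sqrt(msw / nh)
    q <- if (se == 0) { if (diff == 0) 0 else Inf } else abs(diff) / se
    p <- if (is.infinite(q)) 0
         else ptukey(q, nmeans = length(lv), df = df2, lower.tail = FALSE)
    data.frame(comparison = paste(g2, "-", g1), diff = unname(diff),
               p_adj = p, stringsAsFactors = FALSE)
  }))
  if (is.null(tukey))
    tukey <- data.frame(comparison = character(), diff = numeric(),
                        p_adj = numeric(), stringsAsFactors = FALSE)
  res <- list(F = Fstat, df = c(df1, df2), p_value = pval,
              group_means = gm, ms_within = msw, tukey = tukey)
  class(res) <- "anova_tukey_result"
  res
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
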