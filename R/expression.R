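#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - mean(Ct(references))` (arithmetic mean of
#' the reference Cts, the standard dual-reference-gene practice);
#' `ddCt = mean dCt(test) - mean dCt(calibrator)`; fold change =
#' `2^(-ddCt)`. The standard deviation of the fold is propagated from the
#' replicate dCt spread of the test group.
#'
#' @param ct `data.frame` with columns `sample`, `group`, `gene`, `ct`
#'   (technical replicates allowed as extra rows).
#' @param target_gene Target gene name.
#' @param reference_genes Reference (housekeeping) genes, present in every
#'   sample (default `groEL` and `gyrA`).
#' @param calibrator_group Group used as calibrator (e.g. `"WT"`).
#' @param test_group Group whose fold change is reported; defaults to the
#'   single non-calibrator group.
#' @return List: `fold_change`, `sd_fold` (from test-group dCt spread),
#'   `ddct`, per-sample `dct` table.
#' @export
ddct_fold_change <- function(ct, target_gene,
                             reference_genes = c("groEL", "gyrA"),
                             calibrator_group, test_group = NULL) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive")
  groups <- unique(ct$group)
  if (!calibrator_group %in% groups)
    stop("no samples in calibrator group '", calibrator_group, "'")
  if (is.null(test_group)) {
    test_group <- setdiff(groups, calibrator_group)
    if (length(test_group) != 1L)
      stop("test_group must be given when more than two groups are present")
  }
  if (!test_group %in% groups)
    stop("no samples in test group '", test_group, "'")
  dct <- lapply(split(ct, ct$sample), function(s) {
    tgt <- s$ct[s$gene == target_gene]
    refs <- vapply(reference_genes, function(g) {
      v <- s$ct[s$gene == g]
      if (length(v) == 0L)
        stop("reference gene ", g, " missing in sample ", s$sample[1L])
      mean(v)
    }, numeric(1))
    if (length(tgt) == 0L)
      stop("target gene ", target_gene, " missing in sample ", s$sample[1L])
    data.frame(sample = s$sample[1L], group = s$group[1L],
               dct = mean(tgt) - mean(refs), stringsAsFactors = FALSE)
  })
  dct <- do.call(rbind, dct)
  rownames(dct) <- NULL
  d_test <- dct$dct[dct$group == test_group]
  d_cal <- dct$dct[dct$group == calibrator_group]
  ddct <- mean(d_test) - mean(d_cal)
  fold <- 2^(-ddct)
  sd_dct <- if (length(d_test) > 1L) sd(d_test) else 0
  # delta-method SD of 2^-dCt around the mean
  sd_fold <- fold * log(2) * sd_dct
  list(fold_change = fold, sd_fold = sd_fold, ddct = ddct, dct = dct)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of the gene's count
#' to its geometric mean across samples, computed over genes with strictly
#' positive counts everywhere. When no such gene exists, falls back to
#' library-size ratios with a warning.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using library-size ratios")
    ls <- colSums(counts)
    return(ls / exp(mean(log(pmax(ls, 1)))))
  }
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(col) median(col / geo))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Explicit step-up procedure: sort p ascending, multiply by `n / rank`,
#' enforce monotonicity from the largest rank down, cap at 1, and return in
#' the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test. When both groups have zero variance:
#' equal means give p = 1 by convention, different means give p = 0 (the
#' groups are perfectly separated).
#'
#' @param group_a,group_b Numeric vectors with >= 2 values each.
#' @return List: `statistic`, `p_value`, `df`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 values per group")
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    return(list(statistic = Inf * sign(mean(group_a) - mean(group_b)),
                p_value = 0, df = NA_real_))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Differential expression on a count matrix
#'
#' A transparent negative-binomial Wald test. Counts are normalized by
#' median-of-ratios [size_factors()]; all-zero genes are discarded before
#' testing. Per gene, the log2 fold change of group means uses a 0.5
#' pseudocount. The per-gene NB dispersion is estimated by the method of
#' moments from within-group variances and stabilized by flooring at the
#' across-gene median (with only a few replicates per group the per-gene
#' moment estimate is extremely noisy; the floor pools information across
#' genes, conservatively widening the standard error of quiet genes). The
#' Wald statistic is the log2 fold change over its delta-method standard
#' error `sqrt(sum_g (1/mu_g + alpha) / n_g) / ln 2`; p-values are normal
#' two-sided and BH-adjusted. A gene is called significant when
#' `FDR < fdr` and `log2FC > min_log2fc` (one-sided "upregulated" rule;
#' set `two_sided_fc = TRUE` for `|log2FC| > min_log2fc`).
#'
#' @param counts Gene-by-sample count matrix with column names.
#' @param groups Character/factor vector over samples with exactly two
#'   levels (e.g. `"WT"` / `"mutant"`); fold changes are `test` over
#'   `reference`.
#' @param reference Group treated as baseline (default `"WT"` when
#'   present, else the first level).
#' @param fdr FDR cut-off (default 0.05).
#' @param min_log2fc log2 fold-change cut-off (default 3).
#' @param two_sided_fc Apply the fold cut-off to `|log2FC|` (default
#'   FALSE).
#' @return `data.frame`: `gene`, `base_mean_ref`, `base_mean_test`,
#'   `log2fc`, `dispersion`, `pvalue`, `fdr`, `significant`.
#' @export
dge_test <- function(counts, groups, reference = NULL, fdr = 0.05,
                     min_log2fc = 3, two_sided_fc = FALSE) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one entry per sample column")
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (is.null(reference)) reference <- if ("WT" %in% lv) "WT" else lv[1L]
  test <- setdiff(lv, reference)
  for (g in lv) if (sum(groups == g) < 2L)
    stop("group '", g, "' has fewer than 2 samples")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no gene with nonzero counts")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, groups == reference, drop = FALSE]
  b <- norm[, groups == test, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  # method-of-moments NB dispersion from within-group variance
  pooled_var <- (apply(a, 1, var) * (na - 1) +
                   apply(b, 1, var) * (nb - 1)) / (na + nb - 2)
  pooled_mean <- (mean_a * na + mean_b * nb) / (na + nb)
  disp_raw <- pmax((pooled_var - pooled_mean) / pooled_mean^2, 0)
  disp0 <- median(disp_raw)
  disp <- pmax(disp_raw, disp0)
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  se <- sqrt((1 / pmax(mean_a, 0.5) + disp) / na +
               (1 / pmax(mean_b, 0.5) + disp) / nb) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  q <- bh_adjust(p)
  fc_ok <- if (two_sided_fc) abs(log2fc) > min_log2fc else log2fc > min_log2fc
  data.frame(gene = rownames(counts), base_mean_ref = mean_a,
             base_mean_test = mean_b, log2fc = log2fc, dispersion = disp,
             pvalue = p, fdr = q, significant = q < fdr & fc_ok,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a differential-expression result table
#'
#' @param res Result of [dge_test()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dge_table <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
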