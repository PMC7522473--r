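make_ct <- function(dct_wt, dct_mut, ref_ct = c(groEL = 16, gyrA = 17)) {
  rows <- list()
  for (g in seq_along(dct_wt)) {
    smp <- paste0("WT_", g)
    rows[[smp]] <- data.frame(sample = smp, group = "WT",
                              gene = c("ribD", names(ref_ct)),
                              ct = c(mean(ref_ct) + dct_wt[g], ref_ct))
  }
  for (g in seq_along(dct_mut)) {
    smp <- paste0("M_", g)
    rows[[smp]] <- data.frame(sample = smp, group = "mutant",
                              gene = c("ribD", names(ref_ct)),
                              ct = c(mean(ref_ct) + dct_mut[g], ref_ct))
  }
  do.call(rbind, rows)
}

test_that("equal dCt across groups gives fold 1 and a one-cycle shift gives fold 2", {
  ct <- make_ct(c(3, 3, 3), c(3, 3, 3))
  expect_equal(ddct_fold_change(ct, "ribD",
                                calibrator_group = "WT")$fold_change, 1)
  ct2 <- make_ct(c(3, 3, 3), c(2, 2, 2))
  expect_equal(ddct_fold_change(ct2, "ribD",
                                calibrator_group = "WT")$fold_change, 2)
})

test_that("swapping test and calibrator inverts the fold change", {
  set.seed(61)
  ct <- make_ct(rnorm(3, 4, 0.3), rnorm(3, 1, 0.3))
  a <- ddct_fold_change(ct, "ribD", calibrator_group = "WT",
                        test_group = "mutant")$fold_change
  b <- ddct_fold_change(ct, "ribD", calibrator_group = "mutant",
                        test_group = "WT")$fold_change
  expect_equal(a, 1 / b)
})

test_that("a noise-free table encoding the reported ribD ratio returns fold 15", {
  ct <- make_ct_table(seed = 1, target_fold = 15, noise_sd = 0)
  fold <- ddct_fold_change(ct, "ribD",
                           calibrator_group = "WT")$fold_change
  expect_equal(fold, 15, tolerance = 0.01)
})

test_that("missing references and empty groups are input errors", {
  ct <- make_ct(c(3, 3), c(2, 2))
  expect_error(ddct_fold_change(ct[ct$gene != "gyrA", ], "ribD",
                                calibrator_group = "WT"), "gyrA")
  expect_error(ddct_fold_change(ct, "ribD", calibrator_group = "none"),
               "calibrator")
})

test_that("size factors are exact on identical, scaled and toy matrices", {
  m <- matrix(rep(c(10, 40, 100, 7, 3), 3), ncol = 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))
  m2 <- m; m2[, 2] <- m[, 2] * 2
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # 5x3 toy matrix against a hand-computed median-of-ratios
  toy <- matrix(c(2, 4, 8,
                  10, 10, 10,
                  6, 3, 12,
                  100, 50, 200,
                  1, 2, 4), 5, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  geo <- apply(toy, 1, function(r) exp(mean(log(r))))
  hand <- apply(sweep(toy, 1, geo, "/"), 2, median)
  expect_equal(size_factors(toy), hand)
  zero <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_warning(size_factors(zero), "library-size")
})

test_that("BH adjustment equals the hand step-up trace and stats::p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), bh_oracle(p))
  set.seed(62)
  for (k in 1:5) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("Welch test matches the textbook formula and degenerate conventions", {
  a <- c(1.1, 2.3, 3.1); b <- c(4.0, 5.2, 4.8)
  got <- welch_t_test(a, b)
  ref <- welch_oracle(a, b)
  expect_equal(got$statistic, ref$statistic)
  expect_equal(got$p_value, ref$p_value)
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_lt(welch_t_test(c(0, 0, 0), c(10, 10, 10.0001))$p_value, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("identical groups produce no significant genes and near-zero fold changes", {
  cm <- make_count_matrix(seed = 8, fold = 1, n_genes = 100)
  res <- dge_test(cm$counts, cm$groups)
  expect_false(any(res$significant))
  expect_lt(median(abs(res$log2fc)), 1)
})

test_that("a planted 18-fold cluster is recovered and called significant", {
  cm <- make_count_matrix(seed = 42, n_genes = 200, fold = 18,
                          dispersion = 0.05)
  res <- dge_test(cm$counts, cm$groups)
  rib <- res[res$gene %in% c("ribD", "ribE", "ribAB", "ribH"), ]
  est <- mean(2^rib$log2fc)
  expect_equal(est, 18, tolerance = 0.2)
  expect_true(all(rib$significant))
  expect_true(all(rib$fdr < 0.05 & rib$log2fc > 3))
})

test_that("the fold-change rule excludes strong but small effects", {
  set.seed(63)
  n <- 60
  counts <- matrix(rnbinom(n * 4, mu = 200, size = 50), n, 4,
                   dimnames = list(paste0("g", 1:n),
                                   c("WT_1", "WT_2", "mut_1", "mut_2")))
  counts["g1", 3:4] <- rnbinom(2, mu = 200 * 2^2.5, size = 1000)
  res <- dge_test(counts, c("WT", "WT", "mutant", "mutant"))
  g1 <- res[res$gene == "g1", ]
  expect_lt(g1$fdr, 0.05)
  expect_false(g1$significant)  # log2FC below 3
})

test_that("fold-change estimates are invariant to rescaling a sample column", {
  cm <- make_count_matrix(seed = 9, n_genes = 80, fold = 6)
  res1 <- dge_test(cm$counts, cm$groups)
  scaled <- cm$counts
  scaled[, 2] <- scaled[, 2] * 5
  res2 <- dge_test(scaled, cm$groups)
  expect_equal(res2$log2fc, res1$log2fc, tolerance = 0.02)
})

test_that("group sizes below two are rejected by name", {
  cm <- make_count_matrix(seed = 10, n_genes = 20)
  expect_error(dge_test(cm$counts[, c(1, 3, 4)],
                        cm$groups[c(1, 3, 4)]), "WT")
})
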