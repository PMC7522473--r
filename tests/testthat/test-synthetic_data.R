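queries <- rib_query_proteins()
operon <- c("ribD", "ribE", "ribAB", "ribH")

test_that("generators are pure functions of their seed", {
  p1 <- make_pangenome(seed = 3, n_genomes = 5, n_carriers = 2,
                       n_background = 4)
  p2 <- make_pangenome(seed = 3, n_genomes = 5, n_carriers = 2,
                       n_background = 4)
  expect_identical(p1, p2)
  expect_identical(make_ct_table(seed = 4), make_ct_table(seed = 4))
  expect_identical(make_count_matrix(seed = 4), make_count_matrix(seed = 4))
  expect_identical(make_fecal_table(seed = 4), make_fecal_table(seed = 4))
  expect_identical(make_riboswitch_set(seed = 4), make_riboswitch_set(seed = 4))
})

test_that("carrier fraction zero plants nothing and divergence zero keeps identity 100", {
  p <- make_pangenome(seed = 5, n_genomes = 6, n_carriers = 0,
                      n_background = 4)
  expect_false(any(p$truth$rib_present))
  mat <- build_distribution_matrix(p$panel, queries[operon])
  expect_true(all(mat == 0))

  p100 <- make_pangenome(seed = 5, n_genomes = 4, n_carriers = 2,
                         carrier_identity = c(100, 100), n_background = 4)
  mat100 <- build_distribution_matrix(p100$panel, queries[operon])
  expect_true(all(mat100[p100$truth$rib_present, ] == 100))
  expect_error(make_pangenome(n_genomes = 4, n_carriers = 6), "fraction")
})

test_that("the truth table covers every genome and flags layouts", {
  p <- make_pangenome(seed = 6, n_genomes = 7, n_carriers = 3,
                      n_background = 4, layout = "scattered")
  expect_equal(nrow(p$truth), 7L)
  expect_setequal(p$truth$genome_id,
                  vapply(p$panel, function(g) g$genome_id, character(1)))
  expect_false(any(p$truth$rib_present))  # scattered layout breaks presence
  expect_true(all(p$truth$layout[1:3] == "scattered"))
})

test_that("the synthetic riboswitch set reproduces the tabulated mutations", {
  rs <- make_riboswitch_set(seed = 1)
  tab <- rs$table[!rs$table$below_detection, ]
  expect_equal(nchar(rs$wt), 500L)
  expect_length(rs$variants, 7L)
  wt_chars <- strsplit(rs$wt, "")[[1]]
  expect_equal(nrow(map_mutations(rs$wt, rs$wt)), 0L)
  for (k in seq_len(nrow(tab))) {
    id <- tab$mutant_id[k]
    muts <- map_mutations(rs$wt, rs$variants[[id]])
    expect_equal(nrow(muts), 1L)  # exactly one difference per variant
    expect_equal(muts$position, tab$position[k])
    expect_equal(muts$wt_base, tab$wt_base[k])
    expect_equal(muts$mut_base, tab$mut_base[k])
  }
  # ROS25's position lies inside an anti-antiterminator span
  spans <- rs$regions[grepl("anti_antiterminator", rs$regions$motif), ]
  expect_true(any(spans$start <= 105 & spans$end >= 105))
  # the wild type carries each motif exactly once at the recorded position
  hits <- scan_motifs(rs$wt, riboswitch_model(mismatch_tolerance = 0L))
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$start[match(rs$regions$motif, hits$motif)],
               rs$regions$start)
})

test_that("noise-free Ct tables encode the requested fold exactly", {
  for (f in c(1, 8)) {
    ct <- make_ct_table(seed = 2, target_fold = f, noise_sd = 0)
    expect_equal(ddct_fold_change(ct, "ribD",
                                  calibrator_group = "WT")$fold_change, f)
  }
  expect_error(make_ct_table(target_fold = 0), "target_fold")
  expect_error(make_ct_table(n_replicates = 0), "n_replicates")
})

test_that("noisy Ct tables recover the fold on average over many seeds", {
  f <- 15
  est <- vapply(1:300, function(s)
    ddct_fold_change(make_ct_table(seed = s, target_fold = f,
                                   noise_sd = 0.1),
                     "ribD", calibrator_group = "WT")$fold_change,
    numeric(1))
  expect_equal(mean(est), f, tolerance = 0.02)
})

test_that("count matrices with no planted effect yield no significant calls", {
  cm <- make_count_matrix(seed = 1, fold = 1)
  res <- dge_test(cm$counts, cm$groups)
  expect_false(any(res$significant))
})

test_that("zero dispersion approaches the Poisson limit", {
  cm <- make_count_matrix(seed = 7, n_genes = 150, n_per_group = 40,
                          fold = 1, dispersion = 0,
                          mean_log10_range = c(2, 3),
                          size_factor_sd = 0)
  ratio <- apply(cm$counts, 1, var) / rowMeans(cm$counts)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
  expect_error(make_count_matrix(dispersion = -1), "dispersion")
})

test_that("noise-free fermentation curves are monotone and mass-balanced", {
  tc <- make_timecourse()
  expect_true(all(diff(tc$od) >= 0))
  expect_true(all(diff(tc$substrate) <= 0))
  expect_true(all(tc$substrate >= 0))
  # substrate is exhausted before the end when yield limits growth
  tc2 <- make_timecourse(substrate0 = 5, yield = 0.2, t_end = 30)
  expect_lt(min(tc2$substrate), 1e-9)
  expect_equal(max(tc2$od), 0.05 + 5 * 0.2)
  expect_error(make_timecourse(yield = 0), "yield")
})

test_that("rate estimators recover the generator parameters", {
  tc <- make_timecourse(model = "exponential", t_end = 6, dt = 0.05)
  g <- specific_growth_rate(tc$time, tc$od)
  expect_equal(g$mu_max, 0.31, tolerance = 0.01)
  tcl <- make_timecourse(dt = 0.05)
  p <- production_rate(tcl$time, tcl$riboflavin)
  expect_equal(p$rate_max, 13.9, tolerance = 0.01)
})

test_that("fecal tables respect the configured range and approach its bounds", {
  tab <- make_fecal_table(seed = 9, n_donors = 10)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$riboflavin_ng_per_g >= 80.7 &
                    tab$riboflavin_ng_per_g <= 728.2))
  big <- make_fecal_table(seed = 10, n_donors = 4000)
  s <- summary_stats(big$riboflavin_ng_per_g)
  expect_equal(s$min, 80.7, tolerance = 0.02)
  expect_equal(s$max, 728.2, tolerance = 0.02)
  expect_error(make_fecal_table(n_donors = 0), "n_donors")
})
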