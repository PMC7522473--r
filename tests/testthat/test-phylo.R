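test_that("p-distance handles identity, differences and pairwise deletion", {
  al <- c(s1 = "ACGT", s2 = "ACGT")
  expect_equal(p_distance(al)["s1", "s2"], 0)
  al <- c(s1 = "ACGT", s2 = "ACGA")
  expect_equal(p_distance(al)["s1", "s2"], 0.25)
  al <- c(s1 = "AC-T", s2 = "ACGT")
  expect_equal(p_distance(al)["s1", "s2"], 0)  # 3 comparable sites
  expect_error(p_distance(c(a = "ACG", b = "AC")), "equal length")
  expect_error(p_distance(c(a = "--A", b = "A--")), "comparable")
})

test_that("p-distance agrees with the ape reference implementation", {
  set.seed(41)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("a", "c", "g", "t"), 60, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", 1:5)
  mine <- p_distance(seqs)
  bin <- ape::as.DNAbin(strsplit(seqs, ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # x_A = (d_AB + d_AC - d_BC) / 2 = 1, x_B = 2, x_C = 3
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers trees from additive distance matrices", {
  set.seed(42)
  for (n in c(5, 6, 8)) {
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(rec$edge.length),
                 sort(ape::unroot(tr)$edge.length), tolerance = 1e-8)
  }
})

test_that("NJ agrees with the ape reference on random matrices", {
  set.seed(43)
  for (k in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n, 1, 10), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    mine <- nj_tree(d)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equidistant taxa resolve deterministically via the tie-break", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("bootstrap support is 100 for a universally supported split", {
  al <- c(a = "AAAAACCCCC", b = "AAAAACCCCG",
          c = "CCCCCAAAAA", d = "CCCCCAAAAT")
  bs <- bootstrap_support(al, n_replicates = 50, seed = 7)
  expect_equal(nrow(bs$support), 1L)
  expect_equal(bs$support$support, 100)
})

test_that("bootstrap supports are reproducible under a fixed seed and in range", {
  set.seed(44)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", 1:6)
  b1 <- bootstrap_support(seqs, n_replicates = 30, seed = 99)
  b2 <- bootstrap_support(seqs, n_replicates = 30, seed = 99)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 100))
})

test_that("identical trees have zero entanglement", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(entanglement(tr, tr)$score, 0)
})

test_that("exact entanglement equals the exhaustive rotation oracle", {
  set.seed(45)
  for (k in 1:6) {
    t1 <- ape::rtree(5, tip.label = LETTERS[1:5])
    t2 <- ape::rtree(5, tip.label = LETTERS[1:5])
    mine <- entanglement(t1, t2, method = "exact")$score
    expect_equal(mine, entanglement_oracle(t1, t2), tolerance = 1e-12)
  }
})

test_that("greedy entanglement is symmetric and bounded below by exact", {
  set.seed(46)
  for (k in 1:6) {
    t1 <- ape::rtree(6, tip.label = letters[1:6])
    t2 <- ape::rtree(6, tip.label = letters[1:6])
    g12 <- entanglement(t1, t2)$score
    g21 <- entanglement(t2, t1)$score
    expect_equal(g12, g21)
    expect_gte(g12 + 1e-12, entanglement(t1, t2, method = "exact")$score)
    expect_true(g12 >= 0 && g12 <= 1)
  }
  expect_error(entanglement(ape::rtree(4), ape::rtree(5)), "leaf sets")
})

test_that("entanglement is invariant under joint relabeling", {
  set.seed(47)
  t1 <- ape::rtree(6, tip.label = letters[1:6])
  t2 <- ape::rtree(6, tip.label = letters[1:6])
  s0 <- entanglement(t1, t2)$score
  perm <- setNames(LETTERS[1:6], letters[1:6])
  r1 <- t1; r1$tip.label <- unname(perm[t1$tip.label])
  r2 <- t2; r2$tip.label <- unname(perm[t2$tip.label])
  expect_equal(entanglement(r1, r2)$score, s0)
})

test_that("planted horizontal transfer raises rib-tree entanglement above the housekeeping baseline", {
  # housekeeping history: clean caterpillar; rib history: one subclade's
  # rib genes exchanged between distant taxa (planted discordance)
  set.seed(48)
  n <- 8
  taxa <- paste0("t", 1:n)
  hk_tree <- ape::read.tree(
    text = "(((((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4):1,t6:5):1,t7:6):1,t8:7);")
  hk_d <- ape::cophenetic.phylo(hk_tree)[taxa, taxa]
  jitter1 <- matrix(runif(n * n, 0, 0.02), n, n)
  jitter1 <- (jitter1 + t(jitter1)) / 2; diag(jitter1) <- 0
  # resampled housekeeping: same history, small noise
  hk2_d <- hk_d + jitter1
  # rib distances: swap t1 and t7 (transfer into a distant subclade)
  swap <- taxa; swap[c(1, 7)] <- taxa[c(7, 1)]
  rib_d <- hk_d[swap, swap]
  dimnames(rib_d) <- list(taxa, taxa)
  hk <- nj_tree(hk_d)
  ent_null <- entanglement(hk, nj_tree(hk2_d))$score
  ent_rib <- entanglement(hk, nj_tree(rib_d))$score
  expect_gt(ent_rib, ent_null)
})
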