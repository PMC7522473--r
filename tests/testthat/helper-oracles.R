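# Independent oracles used across tests. Each re-derives a quantity by a
# route deliberately different from the package implementation.

# brute-force affine-gap local alignment score: O(n^3) recurrence that
# maximizes over every possible gap length explicitly
sw_score_oracle <- function(q, s, mat, gap_open, gap_extend) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa); n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    best <- 0
    best <- max(best, H[i, j] + mat[qa[i], sa[j]])
    for (k in seq_len(j))
      best <- max(best, H[i + 1, j + 1 - k] - gap_open - k * gap_extend)
    for (k in seq_len(i))
      best <- max(best, H[i + 1 - k, j + 1] - gap_open - k * gap_extend)
    H[i + 1, j + 1] <- best
  }
  max(H)
}

# hand step-up Benjamini-Hochberg trace
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    val <- min(prev, p[o[r]] * n / r)
    q[o[r]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# textbook Welch statistic and two-sided p-value
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, p_value = 2 * pt(-abs(tstat), df))
}

# exhaustive tanglegram displacement minimum over every rotation of both
# trees, driven by ape::rotate on the phylo objects themselves
entanglement_oracle <- function(t1, t2) {
  tip_order <- function(phy) {
    phy <- ape::reorder.phylo(phy, "cladewise")
    e <- phy$edge[, 2]
    phy$tip.label[e[e <= ape::Ntip(phy)]]
  }
  all_orders <- function(phy) {
    nodes <- ape::Ntip(phy) + seq_len(phy$Nnode)
    orders <- list()
    for (mask in 0:(2^length(nodes) - 1)) {
      p <- phy
      for (k in seq_along(nodes))
        if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0)
          p <- ape::rotate(p, nodes[k])
      orders[[length(orders) + 1L]] <- tip_order(p)
    }
    unique(orders)
  }
  denom <- floor(length(t1$tip.label)^2 / 2) / length(t1$tip.label)
  best <- Inf
  for (o1 in all_orders(t1)) for (o2 in all_orders(t2)) {
    r2 <- setNames(seq_along(o2), o2)
    best <- min(best, mean(abs(seq_along(o1) - r2[o1])) / denom)
  }
  best
}

# a small genome whose genes are supplied directly
toy_genome <- function(genome_id, proteins, contig = "c1", niche = "human",
                       contigs = NULL, spacing = 100L) {
  if (length(contig) == 1L) contig <- rep(contig, length(proteins))
  genes <- NULL
  pos <- setNames(rep(1L, length(unique(contig))), unique(contig))
  for (k in seq_along(proteins)) {
    ct <- contig[k]
    len_nt <- 3L * nchar(proteins[k]) + 3L
    genes <- rbind(genes, gene(names(proteins)[k], ct, pos[ct],
                               pos[ct] + len_nt - 1L, "+", proteins[k]))
    pos[ct] <- pos[ct] + len_nt + spacing
  }
  genome_record(genome_id, paste("sp", genome_id), niche, genes,
                contigs = contigs)
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                 len, replace = TRUE), collapse = ""), character(1))
}
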