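#' Pairwise distance matrix from an alignment
#'
#' p-distance with pairwise deletion: for each pair, the fraction of
#' differing sites over the sites where neither sequence has a gap (`-`).
#' A Jukes-Cantor correction is available behind `model = "jc"`.
#'
#' @param alignment Named character vector of equal-length (aligned)
#'   sequences, >= 2 entries.
#' @param model `"p"` (default, uncorrected) or `"jc"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment, model = c("p", "jc")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length (aligned input)")
  labs <- names(alignment)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  chars <- lapply(alignment, function(s) strsplit(toupper(s), "")[[1]])
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "-" & b != "-"
    if (!any(ok))
      stop("no comparable sites between ", labs[i], " and ", labs[j])
    p <- sum(a[ok] != b[ok]) / sum(ok)
    if (model == "jc") {
      if (p >= 0.75) stop("p-distance >= 0.75: Jukes-Cantor undefined for ",
                          labs[i], " vs ", labs[j])
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion with the standard NJ branch
#' length formulas. When several pairs minimize Q the pair whose sorted
#' (smallest-descendant-tip) label pair is lexicographically lowest is
#' joined, making the result deterministic. Negative branch length
#' estimates are clamped to 0 with a warning.
#'
#' @param d Symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted `ape` "phylo" tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  clamped <- FALSE
  fmt_len <- function(v) {
    if (v < 0) { clamped <<- TRUE; v <- 0 }
    sprintf("%.12g", v)
  }
  # each active node: newick fragment + min descendant tip label (tie-break)
  nwk <- labs
  key <- labs
  while (nrow(d) > 3L) {
    r <- nrow(d)
    u <- rowSums(d)
    q <- (r - 2) * d - outer(u, u, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- d[i, j] / 2 + (u[i] - u[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    new_nwk <- paste0("(", nwk[i], ":", fmt_len(vi), ",",
                      nwk[j], ":", fmt_len(vj), ")")
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    d <- d2
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ord <- order(key)
  lens <- c(va, vb, vc)[ord]
  txt <- paste0("(", paste0(nwk[ord], ":", vapply(lens, fmt_len, character(1)),
                            collapse = ","), ");")
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = txt)
}

# canonical bipartition keys for the internal edges of an unrooted tree:
# each split is written as the tip-label side not containing the overall
# smallest label, sorted and pasted.
tree_bipartitions <- function(phy) {
  tips <- phy$tip.label
  anchor <- min(tips)
  n <- length(tips)
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(n))
  keys <- character(0)
  for (node in internal) {
    clade <- ape::extract.clade(phy, node)$tip.label
    side <- if (anchor %in% clade) setdiff(tips, clade) else clade
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for an alignment-derived tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate and reports, for each internal bipartition of the tree built
#' from the full alignment, the percentage of replicate trees containing
#' that bipartition. Reproducible under a fixed seed.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param tree_builder Function mapping a distance matrix to a "phylo"
#'   (default [nj_tree()] on [p_distance()] output).
#' @param n_replicates Number of bootstrap replicates (>= 1; default 100).
#' @param seed Integer seed for the column resampling.
#' @return List: `tree` (the full-alignment tree), `support` (data.frame of
#'   bipartition key and support percentage).
#' @export
bootstrap_support <- function(alignment, tree_builder = NULL,
                              n_replicates = 100, seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(tree_builder)) tree_builder <- function(d) nj_tree(d)
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("sequences must have equal length")
  tree <- tree_builder(p_distance(alignment))
  splits <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(splits)), splits)
  chars <- lapply(alignment, function(s) strsplit(s, "")[[1]])
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(len, len, replace = TRUE)
    boot <- vapply(chars, function(x) paste(x[cols], collapse = ""),
                   character(1))
    bt <- try(tree_builder(p_distance(boot)), silent = TRUE)
    if (inherits(bt, "try-error")) next
    bs <- tree_bipartitions(bt)
    counts[splits %in% bs] <- counts[splits %in% bs] + 1
  }
  list(tree = tree,
       support = data.frame(split = splits,
                            support = 100 * counts / n_replicates,
                            row.names = NULL))
}

# ---- tanglegram entanglement ------------------------------------------------

# rooted nested-list view of a phylo: a leaf is its label, an internal node
# is the list of its children in stored order
phylo_to_nested <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    lapply(kids[[as.character(node)]], build)
  }
  build(n + 1L)
}

nested_leaves <- function(tr) {
  if (is.character(tr)) return(tr)
  unlist(lapply(tr, nested_leaves), use.names = FALSE)
}

# preorder paths to internal nodes (root = integer(0))
nested_internal_paths <- function(tr, path = integer(0)) {
  if (is.character(tr)) return(list())
  out <- list(path)
  for (i in seq_along(tr))
    out <- c(out, nested_internal_paths(tr[[i]], c(path, i)))
  out
}

flip_at <- function(tr, path) {
  if (length(path) == 0L) return(rev(tr))
  tr[[path[1L]]] <- flip_at(tr[[path[1L]]], path[-1L])
  tr
}

displacement_score <- function(o1, o2) {
  n <- length(o1)
  r2 <- setNames(seq_len(n), o2)
  mean(abs(seq_len(n) - r2[o1])) / (floor(n^2 / 2) / n)
}

get_at <- function(tr, path) {
  for (i in path) tr <- tr[[i]]
  tr
}

# single top-down sweep: at each internal node of the current tree, keep a
# child-order reversal iff it lowers the displacement against ref_order
greedy_sweep <- function(tr, ref_order) {
  sweep_node <- function(tree, path) {
    node <- get_at(tree, path)
    if (is.character(node)) return(tree)
    cand <- flip_at(tree, path)
    if (displacement_score(nested_leaves(cand), ref_order) <
        displacement_score(nested_leaves(tree), ref_order))
      tree <- cand
    node <- get_at(tree, path)
    for (i in seq_along(node))
      tree <- sweep_node(tree, c(path, i))
    tree
  }
  sweep_node(tr, integer(0))
}

# every leaf order reachable by flipping any subset of internal nodes
all_flip_orders <- function(tr) {
  enumerate <- function(t) {
    if (is.character(t)) return(list(t))
    child_sets <- lapply(t, enumerate)
    combine <- function(sets) {
      if (length(sets) == 1L) return(lapply(sets[[1L]], list))
      rest <- combine(sets[-1L])
      out <- list()
      for (a in sets[[1L]]) for (r in rest)
        out <- c(out, list(c(list(a), r)))
      out
    }
    res <- list()
    for (combo in combine(child_sets)) {
      res <- c(res, list(unlist(combo, use.names = FALSE)),
               list(unlist(rev(combo), use.names = FALSE)))
    }
    res
  }
  unique(enumerate(tr))
}

#' Tanglegram entanglement between two trees
#'
#' Measures leaf-order discordance between two trees over the same taxa,
#' scaled to \[0, 1\]: 0 means the two leaf orders can be made identical,
#' 1 means maximal mean rank displacement (a fully reversed order that no
#' rotation can untangle). The default `"greedy"` mode considers the two
#' one-sided optimizations (hold one tree fixed, run one deterministic
#' top-down rotation sweep over the other) and reports the better one,
#' which also makes the score symmetric in its arguments; `"exact"`
#' enumerates every child-flip configuration of both trees (feasible for
#' small trees) and returns the true minimum.
#'
#' @param t1,t2 "phylo" trees with identical leaf sets.
#' @param method `"greedy"` (default) or `"exact"`.
#' @return List of class `entanglement_score`: `score`, `order1`, `order2`.
#' @export
entanglement <- function(t1, t2, method = c("greedy", "exact")) {
  method <- match.arg(method)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must have identical leaf sets")
  n1 <- phylo_to_nested(t1)
  n2 <- phylo_to_nested(t2)
  if (method == "greedy") {
    o1_init <- nested_leaves(n1)
    o2_init <- nested_leaves(n2)
    # two one-sided options (hold one tree fixed, sweep the other); the
    # better one is reported, which also makes the score symmetric
    o2_a <- nested_leaves(greedy_sweep(n2, o1_init))
    o1_b <- nested_leaves(greedy_sweep(n1, o2_init))
    sc_a <- displacement_score(o1_init, o2_a)
    sc_b <- displacement_score(o1_b, o2_init)
    if (sc_a <= sc_b) { sc <- sc_a; o1 <- o1_init; o2 <- o2_a }
    else { sc <- sc_b; o1 <- o1_b; o2 <- o2_init }
  } else {
    os1 <- all_flip_orders(n1)
    os2 <- all_flip_orders(n2)
    sc <- Inf
    o1 <- os1[[1L]]; o2 <- os2[[1L]]
    for (a in os1) for (b in os2) {
      s <- displacement_score(a, b)
      if (s < sc) { sc <- s; o1 <- a; o2 <- b }
    }
  }
  structure(list(score = sc, order1 = o1, order2 = o2),
            class = "entanglement_score")
}

#' @export
print.entanglement_score <- function(x, ...) {
  cat(sprintf("<entanglement_score> %.4f over %d leaves\n",
              x$score, length(x$order1)))
  invisible(x)
}
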