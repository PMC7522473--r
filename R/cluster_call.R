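#' Best passing hit per query in one genome
#'
#' Aligns every query protein against every annotated gene of the genome,
#' estimates E-values against the genome's whole proteome (total residue
#' count) and keeps, per query, the passing hit with the lowest E-value
#' (ties: highest score, then lowest locus tag lexicographically).
#'
#' @param genome A [genome_record()].
#' @param queries Named character vector of query protein sequences
#'   (names are query gene ids, e.g. `ribD`).
#' @param scheme A [scoring_scheme()].
#' @param min_similarity,min_coverage,max_evalue Passed to
#'   [passes_thresholds()].
#' @return Named list mapping each query id to a one-row hit `data.frame`
#'   or `NULL` when no hit passes.
#' @export
best_hits <- function(genome, queries, scheme = scoring_scheme(),
                      min_similarity = 40, min_coverage = 70,
                      max_evalue = 1e-4) {
  if (length(queries) == 0L) stop("queries must be non-empty")
  genes <- genome$genes
  out <- setNames(vector("list", length(queries)), names(queries))
  if (nrow(genes) == 0L) return(out)
  db_len <- sum(nchar(genes$protein))
  for (q in names(queries)) {
    best <- NULL
    for (i in seq_len(nrow(genes))) {
      hit <- align_local(queries[[q]], genes$protein[i], scheme)
      hit$query_id <- q
      hit$subject_locus <- genes$locus_tag[i]
      hit$evalue <- estimate_evalue(hit$score, nchar(queries[[q]]), db_len,
                                    scheme)
      if (!passes_thresholds(hit, min_similarity, min_coverage, max_evalue))
        next
      if (is.null(best) ||
          hit$evalue < best$evalue ||
          (hit$evalue == best$evalue && hit$score > best$score) ||
          (hit$evalue == best$evalue && hit$score == best$score &&
           hit$subject_locus < best$subject_locus))
        best <- hit
    }
    out[q] <- list(best)  # keeps the element when best is NULL
  }
  out
}

#' Call rib-operon presence in one genome
#'
#' A genome is called a carrier when all four operon queries (`ribD`,
#' `ribE`, `ribAB`, `ribH`) have passing hits, the four subject genes are
#' co-located (same contig, spanning at most `window` consecutive annotated
#' genes) and their mean percent similarity is strictly above
#' `min_avg_similarity`.
#'
#' @param genome A [genome_record()].
#' @param hits Best-hit map from [best_hits()]; must cover the four operon
#'   queries.
#' @param operon_queries Names of the four operon queries.
#' @param window Maximum number of consecutive annotated genes the four
#'   subjects may span (default 10).
#' @param min_avg_similarity Strict lower bound on the mean similarity of
#'   the four best hits (default 40).
#' @return A list of class `cluster_call`: `genome_id`, `present`, `hits`,
#'   `avg_similarity`, `colocated`, `in_operon_order`.
#' @export
call_rib_cluster <- function(genome, hits,
                             operon_queries = c("ribD", "ribE", "ribAB", "ribH"),
                             window = 10, min_avg_similarity = 40) {
  if (!all(operon_queries %in% names(hits)))
    stop("hits map must cover: ", paste(operon_queries, collapse = ", "))
  four <- hits[operon_queries]
  have_all <- !vapply(four, is.null, logical(1))
  avg_sim <- if (all(have_all))
    mean(vapply(four, function(h) h$pct_similarity, numeric(1))) else NA_real_
  colocated <- FALSE
  in_order <- FALSE
  if (all(have_all)) {
    loci <- vapply(four, function(h) h$subject_locus, character(1))
    genes <- genome$genes
    idx <- match(loci, genes$locus_tag)
    contigs <- genes$contig[idx]
    if (length(unique(contigs)) == 1L) {
      # rank within the gene order of that contig
      on_contig <- which(genes$contig == contigs[1L])
      ranks <- match(idx, on_contig)
      colocated <- (max(ranks) - min(ranks) + 1L) <= window
      in_order <- identical(order(ranks), seq_along(ranks))
    }
  }
  present <- all(have_all) && colocated &&
    isTRUE(avg_sim > min_avg_similarity)
  structure(list(genome_id = genome$genome_id, present = present,
                 hits = four, avg_similarity = avg_sim,
                 colocated = colocated, in_operon_order = in_order),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat("<cluster_call>", x$genome_id, "- rib cluster",
      if (x$present) "PRESENT" else "absent",
      if (!is.na(x$avg_similarity))
        sprintf("(avg similarity %.1f%%)", x$avg_similarity) else "", "\n")
  invisible(x)
}

#' Gene-by-genome identity distribution matrix
#'
#' One row per genome, one column per query gene; each cell is the percent
#' identity of the best passing hit (0 when no hit passes). Row niche labels
#' are carried as an attribute for downstream grouping.
#'
#' @param panel List of [genome_record()]s with unique `genome_id`s.
#' @param queries Named character vector of query proteins (typically the
#'   four operon genes plus `ribCF` and `ribU`).
#' @param ... Passed to [best_hits()].
#' @return Numeric matrix (genomes x queries) with a `niche` attribute, and
#'   the per-genome best-hit maps in attribute `hit_maps`.
#' @export
build_distribution_matrix <- function(panel, queries, ...) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  ids <- vapply(panel, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome_id in panel: ",
                               ids[duplicated(ids)][1L])
  m <- matrix(0, nrow = length(panel), ncol = length(queries),
              dimnames = list(ids, names(queries)))
  hit_maps <- setNames(vector("list", length(panel)), ids)
  for (i in seq_along(panel)) {
    hm <- best_hits(panel[[i]], queries, ...)
    hit_maps[[i]] <- hm
    for (q in names(queries))
      if (!is.null(hm[[q]])) m[i, q] <- hm[[q]]$pct_identity
  }
  attr(m, "niche") <- setNames(vapply(panel, function(g) g$niche,
                                      character(1)), ids)
  attr(m, "hit_maps") <- hit_maps
  m
}

#' Hierarchical-clustering leaf order for the distribution heatmap
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' rows or columns of a distribution matrix. Items are sorted by label
#' before clustering so the result does not depend on input order.
#'
#' @param matrix Numeric matrix as from [build_distribution_matrix()].
#' @param axis `"rows"` or `"columns"`.
#' @return List with the `hclust` object (`NULL` for a single item) and the
#'   leaf `order` (character labels).
#' @export
hcluster_order <- function(matrix, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "rows") matrix else t(matrix)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 1L) stop("empty axis")
  if (nrow(m) == 1L)
    return(list(hclust = NULL, order = rownames(m)))
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}

#' Export cluster calls as JSON
#'
#' @param calls List of [call_rib_cluster()] results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_calls <- function(calls, path) {
  out <- lapply(calls, function(cc) {
    hits <- lapply(cc$hits, function(h) if (is.null(h)) NULL else
      as.list(h[c("subject_locus", "score", "pct_identity",
                  "pct_similarity", "query_coverage", "evalue")]))
    list(genome_id = cc$genome_id, present = cc$present,
         avg_similarity = cc$avg_similarity, colocated = cc$colocated,
         hits = hits)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
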