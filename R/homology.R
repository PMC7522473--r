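#' Protein alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used for E-value estimation. The default matrix
#' is BLOSUM62 with the `X` row/column set to 0 (unknown residues are
#' tolerated but uninformative); defaults follow common BLASTP practice
#' (gap open 11, gap extend 1, ungapped K = 0.041, lambda = 0.267).
#'
#' @param matrix Substitution matrix with amino-acid row/column names.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param K,lambda Karlin-Altschul parameters, both > 0.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           K = 0.041, lambda = 0.267) {
  if (is.null(matrix)) matrix <- blosum62_x0()
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be strictly positive")
  if (K <= 0 || lambda <= 0) stop("K and lambda must be > 0")
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row/column names")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda),
            class = "scoring_scheme")
}

# BLOSUM62 from Biostrings with X scored 0 against everything.
blosum62_x0 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  m
}

encode_protein <- function(seq, alphabet, what = "sequence") {
  if (!nzchar(seq)) stop("empty ", what)
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("non-amino-acid character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' Optimal local protein alignment
#'
#' Smith-Waterman alignment with affine gaps (Gotoh recurrences). Percent
#' identity and percent similarity (positive-scoring aligned columns, BLASTP
#' "positives") are computed over all aligned columns including gaps; query
#' coverage is the aligned query span as a percentage of query length.
#'
#' @param query,subject Protein sequences (non-empty, standard amino-acid
#'   alphabet; `X` tolerated and scored 0).
#' @param scheme A [scoring_scheme()].
#' @return A one-row `data.frame` (a homology hit): `query_id`,
#'   `subject_locus` (both `NA` here; filled by callers), `score`,
#'   `pct_identity`, `pct_similarity`, `query_coverage`, `evalue` (`NA`
#'   until estimated), plus alignment span columns.
#' @export
align_local <- function(query, subject, scheme = scoring_scheme()) {
  alphabet <- rownames(scheme$matrix)
  qi <- encode_protein(query, alphabet, "query")
  si <- encode_protein(subject, alphabet, "subject")
  r <- .sw_align_cpp(qi, si, scheme$matrix, scheme$gap_open,
                     scheme$gap_extend)
  alen <- r$align_len
  data.frame(
    query_id = NA_character_, subject_locus = NA_character_,
    score = r$score,
    pct_identity = if (alen > 0) 100 * r$n_ident / alen else 0,
    pct_similarity = if (alen > 0) 100 * r$n_pos / alen else 0,
    query_coverage = if (r$qend >= r$qstart && r$qstart > 0)
      100 * (r$qend - r$qstart + 1) / length(qi) else 0,
    evalue = NA_real_,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    align_len = alen, stringsAsFactors = FALSE)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' database of total length `n`.
#'
#' @param score Alignment score `S`.
#' @param query_len,db_len Positive lengths (`db_len` is conventionally the
#'   total residue count of the searched proteome).
#' @param scheme A [scoring_scheme()] supplying `K` and `lambda`.
#' @return The E-value (non-negative scalar).
#' @export
estimate_evalue <- function(score, query_len, db_len,
                            scheme = scoring_scheme()) {
  if (query_len <= 0 || db_len <= 0) stop("lengths must be positive")
  scheme$K * query_len * db_len * exp(-scheme$lambda * score)
}

#' Homology-hit significance filter
#'
#' A hit passes when percent similarity >= `min_similarity`, query coverage
#' >= `min_coverage` and E-value < `max_evalue`. Boundaries mirror the
#' screening rule: the similarity and coverage cut-offs are attainable
#' (inclusive), the E-value bound is strict.
#'
#' @param hit A one-row hit as from [align_local()] with `evalue` filled.
#' @param min_similarity,min_coverage,max_evalue Thresholds
#'   (defaults 40, 70, 1e-4).
#' @return Logical scalar.
#' @export
passes_thresholds <- function(hit, min_similarity = 40, min_coverage = 70,
                              max_evalue = 1e-4) {
  isTRUE(hit$pct_similarity >= min_similarity &&
         hit$query_coverage >= min_coverage &&
         hit$evalue < max_evalue)
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL: column-normalize the (self-loop augmented) adjacency
#' matrix, then alternate expansion (matrix squaring) and inflation
#' (elementwise power followed by column re-normalization) until the matrix
#' stops changing. Clusters are read off the limit matrix as the connected
#' components of its support, which always yields a disjoint, exhaustive
#' partition of the nodes.
#'
#' @param adjacency Symmetric non-negative weight matrix with node names.
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param self_loops Self-loop weight added to the diagonal (default 1).
#' @param tol Convergence threshold on the max elementwise change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @param prune Entries below this value are treated as zero when reading
#'   off clusters (default 1e-8).
#' @return A list of character vectors, one per cluster, covering all nodes.
#' @export
mcl_cluster <- function(adjacency, inflation = 2, self_loops = 1,
                        tol = 1e-6, max_iter = 100, prune = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  a <- as.matrix(adjacency)
  if (any(a < 0)) stop("edge weights must be non-negative")
  if (is.null(rownames(a))) rownames(a) <- colnames(a) <- as.character(seq_len(nrow(a)))
  diag(a) <- diag(a) + self_loops
  norm_cols <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  m <- norm_cols(a)
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                 # expansion
    m2 <- norm_cols(m2^inflation) # inflation
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
  }
  # clusters = connected components of the limit-matrix support
  supp <- (m > prune) | (t(m) > prune)
  n <- nrow(supp)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(supp[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  unname(split(rownames(a), comp))
}

#' Export homology hits as a BLAST-style tabular file
#'
#' @param hits A `data.frame` of hits.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_locus,
                    pident = hits$pct_identity, ppos = hits$pct_similarity,
                    qcovs = hits$query_coverage, evalue = hits$evalue,
                    bitscore = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
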