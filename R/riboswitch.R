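#' FMN riboswitch sequence model
#'
#' The regulatory elements of the FMN riboswitch searched for in 5'-UTRs:
#' the antiterminator (AntiT, `TTCAGGGC`), which permits transcription of
#' the downstream operon, and the two anti-antiterminators (`CATCTTC` and
#' `GAAGATG`), whose pairing in the FMN-bound state allows the terminator
#' hairpin to form and transcription to stop prematurely.
#'
#' @param utr_length Length of the extracted 5'-UTR (default 500 nt).
#' @param antiterminator,anti_antiterminators Literal DNA motifs.
#' @param mismatch_tolerance Mismatches allowed per motif in the fallback
#'   scan pass (default 1; the first pass is always exact).
#' @return An object of class `riboswitch_model`.
#' @export
riboswitch_model <- function(utr_length = 500L,
                             antiterminator = "TTCAGGGC",
                             anti_antiterminators = c("CATCTTC", "GAAGATG"),
                             mismatch_tolerance = 1L) {
  motifs <- c(antiterminator = antiterminator,
              setNames(anti_antiterminators,
                       paste0("anti_antiterminator",
                              seq_along(anti_antiterminators))))
  if (any(!grepl("^[ACGT]+$", motifs))) stop("motifs must be DNA over ACGT")
  structure(list(utr_length = as.integer(utr_length), motifs = motifs,
                 mismatch_tolerance = as.integer(mismatch_tolerance)),
            class = "riboswitch_model")
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Extract the 5'-UTR upstream of a gene
#'
#' Returns up to `length` bases immediately 5' of the gene's start codon,
#' reported 5'->3' on the coding strand: for a `+` strand gene the bases
#' genomically left of `start`; for a `-` strand gene the reverse
#' complement of the bases genomically right of `end`. Truncated (with a
#' warning) at contig edges.
#'
#' @param genome A [genome_record()] carrying contig sequences.
#' @param target_locus Locus tag of the gene (typically `ribD`).
#' @param length UTR length to extract (default 500).
#' @return DNA string (possibly shorter than `length` near contig edges).
#' @export
extract_utr <- function(genome, target_locus, length = 500L) {
  g <- genome$genes[genome$genes$locus_tag == target_locus, , drop = FALSE]
  if (nrow(g) == 0L) stop("locus not found: ", target_locus)
  if (is.null(genome$contigs) || !g$contig %in% names(genome$contigs))
    stop("no contig sequence available for ", g$contig)
  contig <- genome$contigs[[g$contig]]
  clen <- nchar(contig)
  if (g$strand == "+") {
    from <- max(1L, g$start - length)
    to <- g$start - 1L
    if (to < from) stop("gene starts at contig edge: no UTR to extract")
    utr <- substr(contig, from, to)
  } else {
    from <- g$end + 1L
    to <- min(clen, g$end + length)
    if (to < from) stop("gene ends at contig edge: no UTR to extract")
    utr <- revcomp(substr(contig, from, to))
  }
  if (nchar(utr) < length)
    warning("UTR truncated to ", nchar(utr), " nt at contig edge")
  toupper(utr)
}

hamming_positions <- function(seq, motif, max_mismatch) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(integer(0))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(n - k + 1L))
    if (sum(s[i:(i + k - 1L)] != m) <= max_mismatch) hits <- c(hits, i)
  hits
}

#' Scan a 5'-UTR for riboswitch motifs
#'
#' Literal motif scan: all exact occurrences first; if a motif has no exact
#' hit a fallback pass reports occurrences within the model's mismatch
#' tolerance. Exact hits rank before mismatch hits; results are sorted by
#' position within each rank.
#'
#' @param utr DNA string.
#' @param model A [riboswitch_model()].
#' @return `data.frame`: `motif` (name), `sequence`, `start`, `end`
#'   (1-based inclusive), `mismatches`.
#' @export
scan_motifs <- function(utr, model = riboswitch_model()) {
  utr <- toupper(utr)
  if (!grepl("^[ACGT]*$", utr)) stop("UTR must be DNA over ACGT")
  rows <- list()
  for (nm in names(model$motifs)) {
    motif <- model$motifs[[nm]]
    exact <- hamming_positions(utr, motif, 0L)
    pos <- exact; mm <- rep(0L, length(exact))
    if (length(exact) == 0L && model$mismatch_tolerance > 0L) {
      fuzzy <- hamming_positions(utr, motif, model$mismatch_tolerance)
      pos <- fuzzy; mm <- rep(model$mismatch_tolerance, length(fuzzy))
    }
    if (length(pos))
      rows[[nm]] <- data.frame(motif = nm, sequence = motif, start = pos,
                               end = pos + nchar(motif) - 1L,
                               mismatches = mm, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(motif = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$mismatches, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map point mutations between a wild-type riboswitch and a variant
#'
#' @param wt,variant Equal-length DNA strings (the mutants carry single
#'   point mutations; indels are out of scope and a length mismatch is an
#'   input error).
#' @return `data.frame`: `position` (1-based from the riboswitch origin),
#'   `wt_base`, `mut_base`.
#' @export
map_mutations <- function(wt, variant) {
  wt <- toupper(wt); variant <- toupper(variant)
  if (nchar(wt) != nchar(variant))
    stop("wild-type and variant must have equal length (no indels expected)")
  a <- strsplit(wt, "")[[1]]
  b <- strsplit(variant, "")[[1]]
  pos <- which(a != b)
  data.frame(position = pos, wt_base = a[pos], mut_base = b[pos],
             stringsAsFactors = FALSE)
}

is_purine <- function(b) b %in% c("A", "G")

#' Classify mutations by region and substitution type
#'
#' Region is the name of the motif whose span contains the position
#' (antiterminator / anti-antiterminator), otherwise `"other"`.
#' Substitution class is `"transition"` for purine-purine or
#' pyrimidine-pyrimidine changes, `"transversion"` otherwise.
#'
#' @param mutations `data.frame` from [map_mutations()].
#' @param motif_hits `data.frame` from [scan_motifs()] for the same UTR.
#' @param utr_length Length of the UTR the positions refer to.
#' @return The mutations with `region` and `mutation_class` columns added.
#' @export
classify_mutation <- function(mutations, motif_hits, utr_length) {
  if (nrow(mutations) && (any(mutations$position < 1L) ||
                          any(mutations$position > utr_length)))
    stop("mutation position outside the UTR")
  region <- vapply(mutations$position, function(p) {
    inside <- motif_hits$start <= p & motif_hits$end >= p
    if (!any(inside)) return("other")
    nm <- motif_hits$motif[which(inside)[1L]]
    sub("[0-9]+$", "", nm)
  }, character(1))
  klass <- ifelse(is_purine(mutations$wt_base) ==
                    is_purine(mutations$mut_base),
                  "transition", "transversion")
  mutations$region <- region
  mutations$mutation_class <- klass
  mutations
}

#' Per-column conservation profile of aligned UTRs
#'
#' For each alignment column: base frequencies over non-gap characters and
#' information content `IC = 2 - H` (Shannon entropy in bits). An all-gap
#' column gets `IC = 0` and is flagged.
#'
#' @param aligned_utrs Named character vector of equal-length aligned DNA
#'   sequences (>= 2).
#' @return `data.frame`: `column`, `A`, `C`, `G`, `T` (frequencies),
#'   `ic_bits`, `all_gap`.
#' @export
conservation_profile <- function(aligned_utrs) {
  if (length(aligned_utrs) < 2L) stop("need at least 2 sequences")
  lens <- unique(nchar(aligned_utrs))
  if (length(lens) != 1L) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned_utrs), ""))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L)
      return(data.frame(column = j, A = NA_real_, C = NA_real_,
                        G = NA_real_, T = NA_real_, ic_bits = 0,
                        all_gap = TRUE))
    f <- vapply(bases, function(b) mean(col == b), numeric(1))
    p <- f[f > 0]
    ic <- 2 + sum(p * log2(p))
    data.frame(column = j, A = f[["A"]], C = f[["C"]], G = f[["G"]],
               T = f[["T"]], ic_bits = ic, all_gap = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
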