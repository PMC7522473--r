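#' Construct a gene record
#'
#' A gene is an annotated protein-coding feature on a contig, with 1-based
#' inclusive nucleotide coordinates (GFF3 convention) and its translated
#' protein sequence carried alongside so a genome stays self-contained.
#'
#' @param locus_tag Character locus tag, e.g. `"Blon_0386"`.
#' @param contig Contig/replicon identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param protein Amino-acid sequence (non-empty, upper case).
#' @return A one-row `data.frame` with class behaviour of a plain gene row.
#' @export
gene <- function(locus_tag, contig, start, end, strand, protein) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid coordinates for ", locus_tag, ": start must be >= 1 and <= end")
  if (!strand %in% c("+", "-"))
    stop("invalid strand '", strand, "' for ", locus_tag, " (must be '+' or '-')")
  protein <- toupper(as.character(protein))
  if (!nzchar(protein)) stop("empty protein sequence for ", locus_tag)
  data.frame(locus_tag = locus_tag, contig = contig, start = start, end = end,
             strand = strand, protein = protein, stringsAsFactors = FALSE)
}

#' Construct an annotated genome record
#'
#' @param genome_id Unique genome identifier within a panel.
#' @param species Species (or subspecies) label.
#' @param niche Isolation-niche label (e.g. `"human"`, `"primate"`, `"insect"`)
#'   used for grouping in the distribution heatmap.
#' @param genes A `data.frame` of genes as produced by [gene()] (rows are
#'   re-sorted by contig then start).
#' @param contigs Optional named character vector of contig DNA sequences;
#'   required only for 5'-UTR extraction.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, species, niche, genes,
                          contigs = NULL) {
  stopifnot(is.data.frame(genes))
  need <- c("locus_tag", "contig", "start", "end", "strand", "protein")
  if (!all(need %in% names(genes)))
    stop("genes table must have columns: ", paste(need, collapse = ", "))
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, species = species, niche = niche,
                 genes = genes, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$genome_id, "(", x$species, ", niche:", x$niche,
      ")\n  ", nrow(x$genes), "genes on",
      length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Line-wrapped sequences are concatenated, record order is preserved and
#' sequences are upper-cased. A sequence line before the first header is a
#' parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are full header lines
#'   without the `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("malformed FASTA: sequence before first header at line 1: '",
         lines[1L], "'")
  if (any(nchar(trimws(sub("^>", "", lines[is_hdr]))) == 0L))
    stop("malformed FASTA: empty header line")
  rec <- cumsum(is_hdr)
  ids <- trimws(sub("^>", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated file with columns `locus_tag`, `contig`, `start`,
#' `end`, `strand`, `protein`; coordinates are validated as 1-based inclusive
#' and rows are returned sorted by (contig, start).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of validated genes.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_tag", "contig", "start", "end", "strand", "protein")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(tab)), function(i)
    gene(tab$locus_tag[i], tab$contig[i], tab$start[i], tab$end[i],
         tab$strand[i], tab$protein[i]))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene annotation table
#'
#' @param genes Gene `data.frame` (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path) {
  write.table(genes[, c("locus_tag", "contig", "start", "end", "strand",
                        "protein")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged riboswitch mutant table
#'
#' Returns the packaged table of single-point FMN riboswitch mutations in the
#' seven roseoflavin-resistant isolates together with the extracellular
#' riboflavin concentration of each mutant and of the wild type. The
#' wild-type concentration is below the bioassay detection limit and is
#' stored as an explicit flag plus the limit, never as 0.
#'
#' @return A `data.frame` with columns `mutant_id`, `position`, `wt_base`,
#'   `mut_base`, `riboflavin_ng_per_ml`, `below_detection`,
#'   `detection_limit`.
#' @export
load_mutant_table <- function() {
  path <- system.file("extdata", "fmn_riboswitch_mutants.tsv",
                      package = "ribscreen")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged mutant-table fixture is missing; reinstall the package")
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 5L || nrow(tab) < 2L)
    stop("mutant-table fixture is corrupted")
  conc_raw <- trimws(as.character(tab[[5]]))
  below <- grepl("^<", conc_raw)
  limit <- ifelse(below, as.numeric(sub("^<\\s*", "", conc_raw)), NA_real_)
  conc <- ifelse(below, NA_real_, suppressWarnings(as.numeric(conc_raw)))
  out <- data.frame(
    mutant_id = as.character(tab[[1]]),
    position = suppressWarnings(as.integer(as.character(tab[[2]]))),
    wt_base = as.character(tab[[3]]),
    mut_base = as.character(tab[[4]]),
    riboflavin_ng_per_ml = conc,
    below_detection = below,
    detection_limit = limit,
    stringsAsFactors = FALSE)
  mut <- out$mutant_id != "WT"
  if (any(out$wt_base[mut] == out$mut_base[mut]))
    stop("mutant-table fixture is corrupted: wt base equals mutant base")
  if (!any(out$below_detection))
    stop("mutant-table fixture is corrupted: no below-detection WT row")
  out
}
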