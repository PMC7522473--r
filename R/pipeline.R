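pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    # screen stage
    n_genomes = 83L, n_carriers = 16L,
    min_similarity = 40, min_coverage = 70, max_evalue = 1e-4,
    colocation_window = 10L, inflation = 2,
    genomes = NULL,            # optional list of genome_record
    queries = NULL,            # optional named protein vector
    # riboswitch stage
    utr_length = 500L,
    wt_fasta = NULL, variants_fasta = NULL,
    # expression stage
    ct_table = NULL, counts = NULL, count_groups = NULL,
    qpcr_fold = 15, rnaseq_fold = 18,
    fdr = 0.05, min_log2fc = 3,
    # kinetics stage
    timecourse = NULL, mu_max = 0.31, peak_rate = 13.9,
    bootstrap = 100L)
}

#' Build a validated pipeline configuration
#'
#' All parameters of every stage live in one flat configuration; unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param ... Overrides of the default keys (see [run_all()] for their
#'   meaning per stage).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML key/value document; keys mirror
#'   [pipeline_config()] arguments.
#' @param ... Further overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  over <- utils::modifyList(as.list(vals), list(...))
  do.call(pipeline_config, over)
}

#' Run the genome screen stage
#'
#' Homology search, rib-cluster presence calling, the gene-by-genome
#' identity matrix and its two-way hierarchical clustering order. When no
#' genome panel is supplied in the configuration, a seeded synthetic
#' pangenome with planted truth is generated and the truth is attached to
#' the report.
#'
#' @param config A [pipeline_config()].
#' @return List: `calls`, `matrix`, `row_order`, `col_order`, `clusters`
#'   (Markov clustering of genomes by identity-profile similarity),
#'   `truth` (when simulated), `report`.
#' @export
run_screen <- function(config = pipeline_config()) {
  queries <- config$queries
  if (is.null(queries)) queries <- rib_query_proteins()
  truth <- NULL
  panel <- config$genomes
  if (is.null(panel)) {
    sim <- make_pangenome(seed = config$seed, n_genomes = config$n_genomes,
                          n_carriers = config$n_carriers)
    panel <- sim$panel
    truth <- sim$truth
  }
  if (length(panel) == 0L) stop("empty genome panel")
  mat <- build_distribution_matrix(panel, queries,
                                   min_similarity = config$min_similarity,
                                   min_coverage = config$min_coverage,
                                   max_evalue = config$max_evalue)
  hit_maps <- attr(mat, "hit_maps")
  calls <- lapply(seq_along(panel), function(i)
    call_rib_cluster(panel[[i]], hit_maps[[i]],
                     window = config$colocation_window,
                     min_avg_similarity = config$min_similarity))
  names(calls) <- rownames(mat)
  row_order <- hcluster_order(mat, "rows")$order
  col_order <- hcluster_order(mat, "columns")$order
  # similarity graph between genomes: affinity of identity profiles
  sim_graph <- exp(-as.matrix(dist(mat)) / max(dist(mat), 1))
  diag(sim_graph) <- 0
  clusters <- mcl_cluster(sim_graph, inflation = config$inflation)
  present <- vapply(calls, function(cc) cc$present, logical(1))
  report <- list(stage = "screen", n_genomes = length(panel),
                 n_carriers_called = sum(present),
                 carriers = names(present)[present])
  list(calls = calls, matrix = mat, row_order = row_order,
       col_order = col_order, clusters = clusters, truth = truth,
       report = report)
}

#' Run the riboswitch stage
#'
#' Motif annotation of the wild-type 5'-UTR, mutation mapping of every
#' variant against it, and region/transition classification, one result
#' row per mutation. A variant of deviating length gets a flagged error
#' row and the run continues.
#'
#' @param config A [pipeline_config()]; when `wt_fasta`/`variants_fasta`
#'   are unset the packaged synthetic riboswitch set is generated.
#' @return List: `wt`, `motif_hits`, `mutations` (`data.frame` with
#'   `mutant_id`, `position`, `wt_base`, `mut_base`, `region`,
#'   `mutation_class`, `error`), `report`.
#' @export
run_riboswitch <- function(config = pipeline_config()) {
  if (!is.null(config$wt_fasta)) {
    wt <- read_fasta(config$wt_fasta)[[1L]]
    variants <- read_fasta(config$variants_fasta)
  } else {
    rs <- make_riboswitch_set(seed = config$seed,
                              utr_length = config$utr_length)
    wt <- rs$wt
    variants <- rs$variants
  }
  model <- riboswitch_model(nchar(wt))
  hits <- scan_motifs(wt, model)
  rows <- list()
  for (nm in names(variants)) {
    res <- try(map_mutations(wt, variants[[nm]]), silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[nm]] <- data.frame(mutant_id = nm, position = NA_integer_,
                               wt_base = NA_character_,
                               mut_base = NA_character_,
                               region = NA_character_,
                               mutation_class = NA_character_,
                               error = "length mismatch",
                               stringsAsFactors = FALSE)
      next
    }
    if (nrow(res) == 0L) next
    res <- classify_mutation(res, hits, nchar(wt))
    res$mutant_id <- nm
    res$error <- NA_character_
    rows[[nm]] <- res[, c("mutant_id", "position", "wt_base", "mut_base",
                          "region", "mutation_class", "error")]
  }
  mutations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mutant_id = character(0), position = integer(0),
               wt_base = character(0), mut_base = character(0),
               region = character(0), mutation_class = character(0),
               error = character(0))
  rownames(mutations) <- NULL
  report <- list(stage = "riboswitch", n_variants = length(variants),
                 n_mutations = sum(is.na(mutations$error)),
                 n_errors = sum(!is.na(mutations$error)))
  list(wt = wt, motif_hits = hits, mutations = mutations, report = report)
}

#' Run the expression stage
#'
#' qPCR relative quantification (2^-ddCt, dual reference genes, WT
#' calibrator) and the count-matrix differential-expression test with the
#' FDR and log2 fold-change significance rule.
#'
#' @param config A [pipeline_config()]; unset inputs are simulated with
#'   the configured fold changes.
#' @return List: `qpcr` (fold change and SD), `dge` (result table),
#'   `report`.
#' @export
run_expression <- function(config = pipeline_config()) {
  ct <- config$ct_table
  if (is.character(ct)) ct <- read.delim(ct, stringsAsFactors = FALSE)
  if (is.null(ct)) ct <- make_ct_table(seed = config$seed,
                                       target_fold = config$qpcr_fold)
  qpcr <- ddct_fold_change(ct, "ribD", calibrator_group = "WT")
  counts <- config$counts
  groups <- config$count_groups
  if (is.character(counts)) {
    counts <- as.matrix(read.delim(counts, row.names = 1L,
                                   check.names = FALSE))
  }
  if (is.null(counts)) {
    cm <- make_count_matrix(seed = config$seed, fold = config$rnaseq_fold)
    counts <- cm$counts
    groups <- cm$groups
  }
  if (is.null(groups))
    groups <- ifelse(grepl("^WT", colnames(counts)), "WT", "mutant")
  dge <- dge_test(counts, groups, reference = "WT", fdr = config$fdr,
                  min_log2fc = config$min_log2fc)
  report <- list(stage = "expression",
                 qpcr_fold = qpcr$fold_change,
                 n_genes_tested = nrow(dge),
                 n_significant = sum(dge$significant))
  list(qpcr = qpcr, dge = dge, report = report)
}

#' Run the kinetics stage
#'
#' Specific growth rate and volumetric riboflavin production rate from a
#' fermentation time course (supplied as TSV/data.frame or simulated),
#' with their maxima and timing.
#'
#' @param config A [pipeline_config()].
#' @return List: `growth`, `production`, `timecourse`, `report`.
#' @export
run_kinetics <- function(config = pipeline_config()) {
  tc <- config$timecourse
  if (is.character(tc)) tc <- read.delim(tc, stringsAsFactors = FALSE)
  if (is.null(tc)) tc <- make_timecourse(seed = config$seed,
                                         mu_max = config$mu_max,
                                         peak_rate = config$peak_rate)
  growth <- specific_growth_rate(tc$time, tc$od)
  production <- production_rate(tc$time, tc$riboflavin)
  report <- list(stage = "kinetics",
                 mu_max = growth$mu_max, t_mu_max = growth$t_mu_max,
                 peak_production_rate = production$rate_max,
                 t_peak_production = production$t_rate_max)
  list(growth = growth, production = production, timecourse = tc,
       report = report)
}

#' Run the full pipeline on one workspace
#'
#' Chains screen, riboswitch, expression and kinetics on the configured
#' (or simulated) inputs; identical configurations give identical results.
#' When `out_dir` is set, per-stage tables and a JSON run report are
#' written there.
#'
#' @param config A [pipeline_config()].
#' @return List with each stage's result plus `report`.
#' @export
run_all <- function(config = pipeline_config()) {
  screen <- run_screen(config)
  riboswitch <- run_riboswitch(config)
  expression <- run_expression(config)
  kinetics <- run_kinetics(config)
  report <- list(seed = config$seed,
                 screen = screen$report, riboswitch = riboswitch$report,
                 expression = expression$report, kinetics = kinetics$report)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(genome_id = rownames(screen$matrix),
                           niche = attr(screen$matrix, "niche"),
                           screen$matrix, check.names = FALSE),
                file.path(config$out_dir, "distribution_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_cluster_calls(screen$calls,
                        file.path(config$out_dir, "cluster_calls.json"))
    write.table(riboswitch$mutations,
                file.path(config$out_dir, "riboswitch_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_dge_table(expression$dge,
                    file.path(config$out_dir, "dge_results.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(screen = screen, riboswitch = riboswitch, expression = expression,
       kinetics = kinetics, report = report)
}
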