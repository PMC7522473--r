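AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

#' Synthetic query proteins for the riboflavin-associated genes
#'
#' A fixed, internally seeded set of synthetic protein sequences standing
#' in for the six riboflavin-associated gene products (the four operon
#' enzymes ribD, ribE, ribAB, ribH plus the unconnected ribCF and ribU),
#' at lengths typical of the real enzymes. Deterministic: every call
#' returns the same sequences.
#'
#' @return Named character vector of six protein sequences.
#' @export
rib_query_proteins <- function() {
  lens <- c(ribD = 360L, ribE = 215L, ribAB = 395L, ribH = 155L,
            ribCF = 315L, ribU = 195L)
  with_seed(190462L, {
    vapply(lens, random_protein, character(1))
  })
}

# residues scoring > 0 against each residue under BLOSUM62 (excluding self)
positive_partners <- function() {
  m <- blosum62_x0()[AA20, AA20]
  lapply(setNames(AA20, AA20), function(a) {
    p <- AA20[m[a, ] > 0 & AA20 != a]
    if (length(p) == 0L) AA20[AA20 != a] else p
  })
}

# substitute residues to hit a target percent identity; a fraction of the
# substitutions are drawn from positive-scoring partners so that percent
# similarity stays above percent identity
mutate_protein <- function(seq, target_identity, conservative_frac = 0.6,
                           partners = positive_partners()) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  n_mut <- round(n * (1 - target_identity / 100))
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  cons <- runif(n_mut) < conservative_frac
  for (k in seq_len(n_mut)) {
    a <- chars[pos[k]]
    pool <- if (cons[k]) partners[[a]] else AA20[AA20 != a]
    chars[pos[k]] <- sample(pool, 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic pangenome with planted rib-cluster truth
#'
#' Emulates a genus-wide genome panel in which a minority of species carry
#' a contiguous four-gene riboflavin biosynthesis cluster: carriers receive
#' a ribDEABH block mutated to a target percent identity, non-carriers
#' receive nothing or scrambled decoys that fall below the homology
#' thresholds, and every genome carries ribCF and ribU homologs (the
#' genus-wide conserved uptake/conversion genes), with insect-niche
#' genomes given the most divergent ribCF. The default scenario mirrors
#' the study panel shape: 83 species of which 16 are carriers, most
#' carriers primate-associated.
#'
#' @param seed Integer seed.
#' @param n_genomes Panel size (default 83).
#' @param n_carriers Number of rib-cluster carriers (default 16).
#' @param carrier_identity Length-2 range of planted percent identity for
#'   operon genes (default `c(60, 95)`).
#' @param conserved_identity Identity range for the ribCF/ribU homologs in
#'   non-insect genomes (default `c(65, 95)`).
#' @param insect_ribcf_identity Identity range for ribCF in insect-niche
#'   genomes (default `c(42, 50)`).
#' @param conservative_frac Fraction of planted substitutions drawn from
#'   positive-scoring residue pairs (default 0.6); lower values let high
#'   divergence push percent similarity below the screening cut-off.
#' @param layout Co-location layout planted in carriers: `"contiguous"`
#'   (default), `"split-contig"` (ribD moved to a second contig) or
#'   `"scattered"` (the four genes spread far apart on one contig).
#' @param n_background Background genes per genome (default 12).
#' @param decoy_fraction Fraction of non-carriers receiving scrambled
#'   decoy genes (default 0.5).
#' @return List: `panel` (list of [genome_record()]s), `truth`
#'   (`data.frame` with `genome_id`, `niche`, `rib_present`, `layout`,
#'   `target_identity`).
#' @export
make_pangenome <- function(seed = 1L, n_genomes = 83L, n_carriers = 16L,
                           carrier_identity = c(60, 95),
                           conserved_identity = c(65, 95),
                           insect_ribcf_identity = c(42, 50),
                           conservative_frac = 0.6,
                           layout = c("contiguous", "split-contig",
                                      "scattered"),
                           n_background = 12L, decoy_fraction = 0.5) {
  layout <- match.arg(layout)
  frac <- n_carriers / n_genomes
  if (frac < 0 || frac > 1) stop("carrier fraction must lie in [0, 1]")
  queries <- rib_query_proteins()
  operon <- c("ribD", "ribE", "ribAB", "ribH")
  partners <- positive_partners()
  with_seed(seed, {
    carriers <- seq_len(n_carriers)
    niches <- character(n_genomes)
    if (n_carriers > 0)
      niches[carriers] <- rep(c("primate", "human", "rodent"),
                              c(max(n_carriers - 2L, 0L),
                                min(1L, n_carriers),
                                min(1L, max(n_carriers - 1L, 0L))))[seq_len(n_carriers)]
    rest <- setdiff(seq_len(n_genomes), carriers)
    niches[rest] <- sample(c("human", "animal", "insect"), length(rest),
                           replace = TRUE, prob = c(0.45, 0.35, 0.2))
    panel <- vector("list", n_genomes)
    truth <- data.frame(genome_id = sprintf("Bsp%02d", seq_len(n_genomes)),
                        niche = niches,
                        rib_present = seq_len(n_genomes) %in% carriers &
                          layout == "contiguous",
                        layout = ifelse(seq_len(n_genomes) %in% carriers,
                                        layout, "none"),
                        target_identity = NA_real_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_genomes)) {
      gid <- truth$genome_id[i]
      prot <- vapply(sample(150:400, n_background, replace = TRUE),
                     random_protein, character(1))
      names(prot) <- sprintf("%s_bg%02d", gid, seq_len(n_background))
      contig <- rep("c1", n_background)
      is_carrier <- i %in% carriers
      if (is_carrier) {
        tid <- runif(1, carrier_identity[1L], carrier_identity[2L])
        truth$target_identity[i] <- tid
        rib <- vapply(queries[operon], mutate_protein, character(1),
                      target_identity = tid,
                      conservative_frac = conservative_frac,
                      partners = partners)
        names(rib) <- sprintf("%s_%s", gid, operon)
        if (layout == "contiguous") {
          at <- sample.int(n_background + 1L, 1L)
          prot <- append(prot, rib, after = at - 1L)
          contig <- rep("c1", length(prot))
        } else if (layout == "split-contig") {
          prot <- append(prot, rib[-1L],
                         after = sample.int(n_background + 1L, 1L) - 1L)
          contig <- rep("c1", length(prot))
          prot <- c(prot, rib[1L])
          contig <- c(contig, "c2")
        } else { # scattered: spread across the background
          gap <- max(3L, floor(n_background / 3L))
          at <- c(1L, 1L + gap, 1L + 2L * gap, 1L + 3L * gap)
          for (k in seq_along(rib))
            prot <- append(prot, rib[k], after = at[k] + (k - 1L))
          contig <- rep("c1", length(prot))
        }
      } else if (runif(1) < decoy_fraction) {
        # scrambled queries: same composition, no positional homology
        dec <- vapply(queries[sample(operon, 2L)], function(q)
          paste(sample(strsplit(q, "")[[1]]), collapse = ""), character(1))
        names(dec) <- sprintf("%s_decoy%d", gid, seq_along(dec))
        prot <- c(prot, dec)
        contig <- rep("c1", length(prot))
      }
      # every genome carries ribCF and ribU homologs
      cf_rng <- if (niches[i] == "insect") insect_ribcf_identity
                else conserved_identity
      cons <- c(mutate_protein(queries[["ribCF"]],
                               runif(1, cf_rng[1L], cf_rng[2L]),
                               partners = partners),
                mutate_protein(queries[["ribU"]],
                               runif(1, conserved_identity[1L],
                                     conserved_identity[2L]),
                               partners = partners))
      names(cons) <- sprintf("%s_%s", gid, c("ribCF", "ribU"))
      prot <- c(prot, cons)
      contig <- c(contig, rep(if (layout == "split-contig" && is_carrier)
        "c2" else "c1", 2L))[seq_along(prot)]
      # lay genes along each contig in order
      genes <- NULL
      for (ct in unique(contig)) {
        idx <- which(contig == ct)
        pos <- 1L
        for (k in idx) {
          len_nt <- 3L * nchar(prot[k]) + 3L
          genes <- rbind(genes, gene(names(prot)[k], ct, pos,
                                     pos + len_nt - 1L, "+", prot[k]))
          pos <- pos + len_nt + sample(50:200, 1L)
        }
      }
      panel[[i]] <- genome_record(gid, paste0("Bifidobacterium sp. ", gid),
                                  niches[i], genes)
    }
    list(panel = panel, truth = truth)
  })
}

#' Generate a synthetic FMN riboswitch wild type and its point mutants
#'
#' Builds a 500-nt wild-type 5'-UTR carrying the antiterminator and the
#' two anti-antiterminator motifs at fixed positions chosen so that the
#' packaged mutant table's coordinates land on the stated wild-type bases:
#' `CATCTTC` spans 41-47 and `GAAGATG` spans 102-108, so positions 41,
#' 102 and 105 fall inside anti-antiterminator spans (three mutants in
#' those regions, as observed), while `TTCAGGGC` sits downstream at
#' 150-157 clear of all mutated positions. One variant per mutant differs
#' from the wild type at exactly its tabulated position.
#'
#' @param seed Integer seed for the background sequence.
#' @param utr_length UTR length (default 500; must leave a margin beyond
#'   the last motif).
#' @param motif_starts Named integer vector of motif start positions.
#' @return List: `wt` (DNA string), `variants` (named character vector, one
#'   per mutant), `regions` (`data.frame` of motif spans), `table` (the
#'   packaged mutant table).
#' @export
make_riboswitch_set <- function(seed = 1L, utr_length = 500L,
                                motif_starts = c(anti_antiterminator1 = 41L,
                                                 anti_antiterminator2 = 102L,
                                                 antiterminator = 150L)) {
  model <- riboswitch_model(utr_length)
  tab <- load_mutant_table()
  muts <- tab[!tab$below_detection, , drop = FALSE]
  if (utr_length < max(muts$position) + 50L)
    stop("UTR too short for the tabulated mutation positions")
  motifs <- model$motifs[names(motif_starts)]
  spans <- data.frame(motif = names(motif_starts),
                      start = unname(motif_starts),
                      end = unname(motif_starts) + nchar(motifs) - 1L,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    wt <- strsplit(random_dna(utr_length), "")[[1]]
    for (k in seq_len(nrow(spans)))
      wt[spans$start[k]:spans$end[k]] <- strsplit(motifs[[k]], "")[[1]]
    # write the tabulated wild-type bases; motif overlaps must agree
    for (k in seq_len(nrow(muts))) {
      p <- muts$position[k]
      inside <- spans$start <= p & spans$end >= p
      if (any(inside) && wt[p] != muts$wt_base[k])
        stop("motif placement conflicts with required wild-type base at ", p)
      wt[p] <- muts$wt_base[k]
    }
    # keep spurious extra motif copies out of the background
    for (k in seq_len(nrow(spans))) {
      hits <- hamming_positions(paste(wt, collapse = ""), motifs[[k]], 0L)
      for (h in setdiff(hits, spans$start[k])) {
        j <- h + nchar(motifs[[k]]) - 1L  # last base of the spurious copy
        if (!j %in% muts$position && !any(spans$start <= j & spans$end >= j))
          wt[j] <- sample(setdiff(c("A", "C", "G", "T"), wt[j]), 1L)
      }
    }
    wt_seq <- paste(wt, collapse = "")
    variants <- vapply(seq_len(nrow(muts)), function(k) {
      v <- wt
      v[muts$position[k]] <- muts$mut_base[k]
      paste(v, collapse = "")
    }, character(1))
    names(variants) <- muts$mutant_id
    list(wt = wt_seq, variants = variants, regions = spans, table = tab)
  })
}

#' Generate a synthetic qPCR Ct table with an injected fold change
#'
#' Reference genes (`groEL`, `gyrA`) are drawn around fixed baselines; the
#' mutant-group target Ct is shifted by `-log2(target_fold)` relative to
#' the wild type, so with zero noise the 2^-ddCt estimate returns
#' `target_fold` exactly. Gaussian cycle noise of `noise_sd` is added to
#' every measurement.
#'
#' @param seed Integer seed.
#' @param target_fold Injected mutant/WT fold change (> 0).
#' @param n_replicates Biological replicates per group (>= 1; default 3,
#'   the usual qPCR triplicate).
#' @param noise_sd Gaussian cycle noise SD (default 0.15).
#' @param target_gene Target gene name (default `"ribD"`).
#' @return `data.frame` with columns `sample`, `group`, `gene`, `ct`.
#' @export
make_ct_table <- function(seed = 1L, target_fold = 15, n_replicates = 3L,
                          noise_sd = 0.15, target_gene = "ribD") {
  if (target_fold <= 0) stop("target_fold must be > 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  base <- c(groEL = 16, gyrA = 17.2)
  target_base <- 24
  with_seed(seed, {
    rows <- list()
    for (grp in c("WT", "mutant")) for (r in seq_len(n_replicates)) {
      smp <- sprintf("%s_%d", grp, r)
      shift <- if (grp == "mutant") -log2(target_fold) else 0
      ct <- c(base, setNames(target_base + shift, target_gene)) +
        rnorm(3L, 0, noise_sd)
      rows[[smp]] <- data.frame(sample = smp, group = grp,
                                gene = names(ct), ct = unname(ct),
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic RNA-seq count matrix with a planted cluster
#'
#' Negative-binomial counts with per-gene means drawn log-uniformly,
#' a configured dispersion, per-sample size-factor perturbations, and a
#' planted set of differentially expressed genes whose mutant-group mean
#' is multiplied by `fold`. The default shape mirrors the study design:
#' two strains (WT vs mutant) in duplicate with a 4-gene cluster
#' up-regulated in the mutant.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 200).
#' @param n_per_group Samples per group (default 2).
#' @param de_genes Names of the planted DE genes (default the four operon
#'   genes; must be a subset of the gene names).
#' @param fold Planted fold change (> 0; default 18).
#' @param dispersion NB dispersion (>= 0; default 0.05).
#' @param mean_log10_range Range of log10 per-gene means (default
#'   `c(1, 3)`).
#' @param size_factor_sd SD of the log-normal per-sample depth
#'   perturbation (default 0.15).
#' @return List: `counts` (matrix), `groups`, `truth` (`data.frame` of
#'   gene, base mean, planted fold).
#' @export
make_count_matrix <- function(seed = 1L, n_genes = 200L, n_per_group = 2L,
                              de_genes = c("ribD", "ribE", "ribAB", "ribH"),
                              fold = 18, dispersion = 0.05,
                              mean_log10_range = c(1, 3),
                              size_factor_sd = 0.15) {
  if (fold <= 0) stop("fold must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  gene_names <- c(de_genes,
                  sprintf("gene_%04d", seq_len(n_genes - length(de_genes))))
  if (!all(de_genes %in% gene_names)) stop("de_genes must be gene names")
  groups <- rep(c("WT", "mutant"), each = n_per_group)
  samples <- sprintf("%s_%d", groups, rep(seq_len(n_per_group), 2L))
  with_seed(seed, {
    base_mean <- 10^runif(n_genes, mean_log10_range[1L],
                          mean_log10_range[2L])
    names(base_mean) <- gene_names
    sf <- exp(rnorm(length(samples), 0, size_factor_sd))
    mu <- outer(base_mean, rep(1, length(samples)))
    mu[de_genes, groups == "mutant"] <- mu[de_genes, groups == "mutant"] * fold
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(gene_names, samples))
    for (j in seq_along(samples))
      counts[, j] <- if (dispersion > 0)
        rnbinom(n_genes, mu = mu[, j], size = 1 / dispersion)
      else rpois(n_genes, mu[, j])
    truth <- data.frame(gene = gene_names, base_mean = unname(base_mean),
                        planted_fold = ifelse(gene_names %in% de_genes,
                                              fold, 1),
                        stringsAsFactors = FALSE)
    list(counts = counts, groups = groups, truth = truth,
         size_factors = sf)
  })
}

#' Generate a synthetic fermentation time course
#'
#' Biomass follows either a logistic curve (default; carrying capacity
#' bounded by substrate via the yield) or a pure exponential; substrate
#' decreases with growth through the yield until exhaustion, after which
#' the culture is stationary; riboflavin is formed by Luedeking-Piret
#' kinetics `dP/dt = alpha dX/dt + beta X`. With the defaults the peak
#' specific growth rate is `mu_max` = 0.31 h^-1 and `alpha` is chosen so
#' the peak volumetric production rate is 13.9 ng mL^-1 h^-1 (the default
#' `alpha = 4 * peak_rate / (mu_max * K)`). Acetate and lactate accumulate
#' in proportion to consumed substrate.
#'
#' @param seed Seed used only when noise is added.
#' @param model `"logistic"` (default) or `"exponential"` biomass.
#' @param mu_max Maximum specific growth rate, h^-1 (default 0.31).
#' @param x0 Initial OD600 (default 0.05).
#' @param K Carrying capacity, OD600 (default 3.0, the observed final OD).
#' @param substrate0 Initial substrate, g L^-1 (default 10, the lactose
#'   dose).
#' @param yield Biomass yield, OD per g L^-1 substrate (default
#'   `(K - x0) / substrate0` so exhaustion coincides with stationary
#'   phase).
#' @param peak_rate Target peak production rate, ng mL^-1 h^-1 (default
#'   13.9); sets the default `alpha`.
#' @param alpha,beta Luedeking-Piret coefficients (growth-associated,
#'   ng mL^-1 per OD; non-growth-associated, ng mL^-1 h^-1 per OD).
#' @param t_end,dt Sampling horizon and interval in hours (defaults 15
#'   and 0.1).
#' @param noise_sd_od,noise_sd_product Gaussian noise SDs (default 0).
#' @return `data.frame`: `time`, `od`, `substrate`, `riboflavin`,
#'   `acetate`, `lactate`.
#' @export
make_timecourse <- function(seed = 1L, model = c("logistic", "exponential"),
                            mu_max = 0.31, x0 = 0.05, K = 3.0,
                            substrate0 = 10, yield = (K - x0) / substrate0,
                            peak_rate = 13.9,
                            alpha = 4 * peak_rate / (mu_max * K), beta = 0,
                            t_end = 15, dt = 0.1,
                            noise_sd_od = 0, noise_sd_product = 0) {
  model <- match.arg(model)
  if (mu_max <= 0) stop("mu_max must be > 0")
  if (yield <= 0) stop("yield must be positive")
  time <- seq(0, t_end, by = dt)
  if (model == "logistic") {
    e <- exp(mu_max * time)
    x <- K * x0 * e / (K - x0 + x0 * e)
  } else {
    x <- x0 * exp(mu_max * time)
  }
  x_cap <- x0 + substrate0 * yield
  x <- pmin(x, x_cap)
  substrate <- pmax(substrate0 - (x - x0) / yield, 0)
  # cumulative Luedeking-Piret product (closed forms)
  if (model == "logistic") {
    integral_x <- (K / mu_max) * log((K - x0 + x0 * exp(mu_max * time)) / K)
  } else {
    integral_x <- (x0 / mu_max) * (exp(mu_max * time) - 1)
  }
  p <- alpha * (x - x0) + beta * integral_x
  acetate <- 0.45 * (substrate0 - substrate)
  lactate <- 0.30 * (substrate0 - substrate)
  if (noise_sd_od > 0 || noise_sd_product > 0) {
    with_seed(seed, {
      x <- pmax(x + rnorm(length(x), 0, noise_sd_od), 1e-4)
      p <- pmax(p + rnorm(length(p), 0, noise_sd_product), 0)
    })
  }
  data.frame(time = time, od = x, substrate = substrate, riboflavin = p,
             acetate = acetate, lactate = lactate)
}

#' Generate synthetic fecal riboflavin concentrations
#'
#' Per-donor riboflavin content drawn from a right-skewed log-normal
#' distribution truncated, by default, to the observed range of fresh
#' fecal samples (80.7-728.2 ng per g).
#'
#' @param seed Integer seed.
#' @param n_donors Number of donors (>= 1; default 10).
#' @param meanlog,sdlog Log-normal parameters (defaults `log(250)`, 0.55).
#' @param bounds Truncation bounds in ng per g (default
#'   `c(80.7, 728.2)`).
#' @return `data.frame`: `donor`, `riboflavin_ng_per_g`.
#' @export
make_fecal_table <- function(seed = 1L, n_donors = 10L,
                             meanlog = log(250), sdlog = 0.55,
                             bounds = c(80.7, 728.2)) {
  if (n_donors < 1L) stop("n_donors must be >= 1")
  with_seed(seed, {
    vals <- numeric(0)
    while (length(vals) < n_donors) {
      draw <- rlnorm(n_donors * 4L, meanlog, sdlog)
      vals <- c(vals, draw[draw >= bounds[1L] & draw <= bounds[2L]])
    }
    data.frame(donor = sprintf("donor_%02d", seq_len(n_donors)),
               riboflavin_ng_per_g = vals[seq_len(n_donors)])
  })
}
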