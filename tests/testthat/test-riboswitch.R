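test_that("UTR extraction obeys strand-aware coordinate arithmetic", {
  set.seed(51)
  contig <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
  genes <- rbind(
    gene("plus", "c1", 1000L, 1200L, "+", "MKT"),
    gene("minus", "c1", 100L, 200L, "-", "MKT"),
    gene("edge", "c1", 300L, 500L, "+", "MKT"))
  g <- genome_record("G", "sp", "human", genes, contigs = c(c1 = contig))
  expect_identical(extract_utr(g, "plus", 500L), substr(contig, 500, 999))
  minus_utr <- extract_utr(g, "minus", 500L)
  expect_identical(minus_utr,
                   chartr("ACGT", "TGCA",
                          paste(rev(strsplit(substr(contig, 201, 700),
                                             "")[[1]]), collapse = "")))
  expect_warning(u <- extract_utr(g, "edge", 500L), "truncated")
  expect_equal(nchar(u), 299L)
  expect_error(extract_utr(g, "nope"), "not found")
})

test_that("a planted motif is recovered and UTR extraction round-trips on both strands", {
  set.seed(52)
  model <- riboswitch_model()
  for (strand in c("+", "-")) {
    utr <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
    utr <- paste0(substr(utr, 1, 36), "TTCAGGGC", substr(utr, 45, 500))
    contig_left <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                         collapse = "")
    if (strand == "+") {
      contig <- paste0(contig_left, utr, "ATGGGG")
      genes <- gene("tgt", "c1", nchar(contig_left) + 501L,
                    nchar(contig_left) + 506L, "+", "MG")
    } else {
      rc <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(utr, "")[[1]]), collapse = ""))
      contig <- paste0("CCCATG", rc, contig_left)
      genes <- gene("tgt", "c1", 1L, 6L, "-", "MG")
    }
    g <- genome_record("G", "sp", "human", genes,
                       contigs = c(c1 = contig))
    got <- extract_utr(g, "tgt", 500L)
    expect_identical(got, utr)
    hits <- scan_motifs(got, model)
    expect_true(any(hits$motif == "antiterminator" & hits$start == 37))
  }
})

test_that("motif scanning matches a brute-force Hamming scan and ranks exact first", {
  model <- riboswitch_model(mismatch_tolerance = 1L)
  set.seed(53)
  utr <- paste(sample(c("A", "G"), 400, replace = TRUE), collapse = "")
  # motif-free random UTR over A/G cannot contain CATCTTC or TTCAGGGC
  expect_equal(nrow(scan_motifs(utr,
                                riboswitch_model(mismatch_tolerance = 0L))), 0L)
  # plant a single-mismatch copy of CATCTTC (CATCTTG) at 101
  utr1 <- paste0(substr(utr, 1, 100), "CATCTTG", substr(utr, 108, 400))
  h0 <- scan_motifs(utr1, riboswitch_model(mismatch_tolerance = 0L))
  expect_false(any(h0$motif == "anti_antiterminator1"))
  h1 <- scan_motifs(utr1, model)
  fuzzy <- h1[h1$motif == "anti_antiterminator1", ]
  # brute-force sliding-window Hamming oracle
  s <- strsplit(utr1, "")[[1]]
  m <- strsplit("CATCTTC", "")[[1]]
  oracle <- which(vapply(seq_len(length(s) - 6L), function(i)
    sum(s[i:(i + 6L)] != m) <= 1L, logical(1)))
  expect_setequal(fuzzy$start, oracle)
  expect_true(101 %in% fuzzy$start)
  expect_true(all(fuzzy$mismatches == 1L))
})

test_that("mutation mapping is exact and applying it back reproduces the variant", {
  expect_equal(nrow(map_mutations("ACGT", "ACGT")), 0L)
  set.seed(54)
  wt <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  wt_chars <- strsplit(wt, "")[[1]]
  for (k in 1:5) {
    n_mut <- sample(1:8, 1)
    pos <- sample(200, n_mut)
    var_chars <- wt_chars
    for (p in pos)
      var_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), wt_chars[p]), 1)
    variant <- paste(var_chars, collapse = "")
    muts <- map_mutations(wt, variant)
    expect_setequal(muts$position, pos)
    # positionwise oracle
    expect_equal(nrow(muts), sum(wt_chars != var_chars))
    # applying the reported mutations back to WT reproduces the variant
    rebuilt <- wt_chars
    rebuilt[muts$position] <- muts$mut_base
    expect_identical(paste(rebuilt, collapse = ""), variant)
  }
  expect_error(map_mutations("ACGT", "ACG"), "equal length")
})

test_that("every position differing yields one mutation per site", {
  wt <- "AAAA"; variant <- "CCCC"
  muts <- map_mutations(wt, variant)
  expect_equal(muts$position, 1:4)
  expect_true(all(muts$wt_base == "A" & muts$mut_base == "C"))
})

test_that("mutation classification follows the purine/pyrimidine rule and motif spans", {
  hits <- data.frame(motif = c("anti_antiterminator2", "antiterminator"),
                     sequence = c("GAAGATG", "TTCAGGGC"),
                     start = c(102L, 150L), end = c(108L, 157L),
                     mismatches = 0L)
  m <- data.frame(position = c(105L, 20L, 151L), wt_base = c("G", "G", "C"),
                  mut_base = c("A", "T", "T"))
  got <- classify_mutation(m, hits, 500L)
  expect_equal(got$mutation_class, c("transition", "transversion",
                                     "transition"))
  expect_equal(got$region, c("anti_antiterminator", "other",
                             "antiterminator"))
  expect_error(classify_mutation(data.frame(position = 501L, wt_base = "G",
                                            mut_base = "A"), hits, 500L),
               "outside")
})

test_that("conservation profile computes exact information content", {
  al <- c(a = "AAAG", b = "ACCG", c = "AGGG", d = "ATTG")
  prof <- conservation_profile(al)
  expect_equal(prof$ic_bits[1], 2)              # all A
  expect_equal(prof$ic_bits[2], 0)              # 25% each base
  expect_equal(prof$ic_bits[4], 2)              # all G
  al2 <- c(a = "AA", b = "AC", c = "AG", d = "AA")
  # column 2: A,C,G,A -> H(0.5,.25,.25) = 1.5 -> IC 0.5
  expect_equal(conservation_profile(al2)$ic_bits[2], 0.5)
  al3 <- c(a = "-A", b = "-C")
  prof3 <- conservation_profile(al3)
  expect_true(prof3$all_gap[1])
  expect_equal(prof3$ic_bits[1], 0)
})
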