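---
title: "Methods: screening, regulation and kinetics of riboflavin biosynthesis in bifidobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, regulation and kinetics of riboflavin biosynthesis in bifidobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribscreen)
```

`ribscreen` chains six analysis stages: a protein homology screen for the
riboflavin biosynthesis operon across a genome panel, presence/absence
calling with a co-location rule, distance-based phylogenomics with
tanglegram comparison, FMN riboswitch annotation and mutant classification,
expression analysis (qPCR and count matrices), and fermentation kinetics
with the study-level statistics. This vignette records the models, the
parameters that matter, and the numerical and design choices behind each
stage.

## Homology screen

Candidate homologs are found by optimal Smith–Waterman local alignment
with affine gaps (Gotoh recurrences, implemented in C++), scored with
BLOSUM62. Unknown residues (`X`) are tolerated and scored 0 so that they
neither reward nor penalize a column. Three derived statistics feed the
screening rule:

* **percent identity** — identical residue pairs over all aligned columns
  (including gap columns);
* **percent similarity** — columns with a positive substitution score
  ("positives"); by construction similarity ≥ identity;
* **query coverage** — the aligned query span as a percentage of query
  length.

Identity and similarity are deliberately kept apart: the screen's cut-off
is phrased on *similarity*, while the distribution heatmap reports
*identity*, and conflating the two changes which borderline genomes pass.

Significance uses the Karlin–Altschul expectation
`E = K · m · n · exp(−λS)` with ungapped BLOSUM62 conventions
`K = 0.041`, `λ = 0.267`, where `m` is the query length and `n` the total
residue count of the searched proteome. These constants are documented,
overridable defaults of `scoring_scheme()`; the screen's conclusions rest
on the relative ordering of E-values against a fixed threshold rather
than on their absolute calibration. Gap penalties default to open 11 /
extend 1 (a gap of length *k* costs `11 + k`).

A hit passes when **similarity ≥ 40% AND coverage ≥ 70% AND E < 10⁻⁴**.
The similarity and coverage boundaries are inclusive (a stated cut-off is
attainable), the E-value bound strict, mirroring the wording of the
screening rule ("40% of similarity" vs "< 0.0001"). `passes_thresholds()`
is monotone in all three arguments, which the test suite checks by
perturbation.

Markov clustering (`mcl_cluster()`) follows the standard scheme: unit
self-loops, column normalization, then alternating expansion (matrix
squaring) and inflation (elementwise power, default 2.0, then column
re-normalization) until the maximum elementwise change falls below 10⁻⁶
or 100 iterations. Clusters are read off the limit matrix as connected
components of its support (entries above 10⁻⁸), which always yields a
disjoint, exhaustive partition — including singleton clusters for
isolated nodes. Inflation controls granularity; 2.0 is standard practice
and no value was stated for the original analysis.

## Cluster presence calling

A genome is called a carrier of the biosynthesis operon when

1. all four operon queries (ribD, ribE, ribAB, ribH) have passing hits,
2. the four subject genes are **co-located**: on one contig, spanning at
   most `window = 10` consecutive annotated genes, and
3. their mean percent similarity is **strictly above 40%**.

"Same genomic region" has no canonical definition; the 10-gene window
admits an operon with a few intervening ORFs while rejecting paralogs
scattered around a replicon, and is configurable. Note the deliberate
asymmetry: per-hit filtering uses *similarity ≥ 40* (inclusive), the
cluster average uses *> 40* (strict, "above 40%"). Operon order
(D, E, AB, H) is recorded (`in_operon_order`) but not enforced — the
field's definition of an intact cluster is co-location, not gene order,
and enforcing order would silently drop rearranged but functional
operons.

Best hits are chosen by lowest E-value, then highest score, then lowest
locus tag — a fully deterministic tie-break so paralogous duplicates
cannot flip calls between runs.

The distribution matrix holds the best-hit percent identity per genome ×
query (0 when nothing passes) with isolation-niche metadata on the rows.
Heatmap ordering uses agglomerative clustering with average linkage on
Euclidean distances; rows/columns are sorted by label before clustering
so the leaf order is invariant to input order.

## Phylogenomics and tanglegrams

Distances are uncorrected p-distances with pairwise deletion (sites where
either sequence has a gap are excluded per pair); a Jukes–Cantor
correction is available behind `model = "jc"`. p-distance is the simplest
defensible default when the original distance model is unstated, and at
the within-genus divergences involved the correction changes distances
nearly proportionally, leaving neighbor-joining topologies essentially
unchanged.

`nj_tree()` is a from-scratch Saitou–Nei implementation: Q-criterion
agglomeration with the standard branch-length formulas, deterministic
tie-breaking (the candidate pair whose smallest-descendant-tip labels
sort lowest), and clamping of negative branch-length estimates to zero
with a warning — the common convention, since small negative estimates
are sampling noise, not signal. On additive matrices NJ is an exact
reconstruction, which the tests verify against trees drawn at random
(≤ 8 taxa) and against the independent `ape::nj` implementation.

Bootstrap support resamples alignment columns with replacement
(default 100 replicates, seeded), rebuilds a tree per replicate and
reports, per internal bipartition of the full-alignment tree, the
percentage of replicates containing that bipartition.

**Entanglement** quantifies leaf-order discordance between two facing
trees. After rotation optimization, the score is the mean absolute rank
displacement of leaves between the two orders, divided by the maximum
possible mean displacement for *n* leaves (`floor(n²/2)/n`, attained by a
full reversal), so 0 means the orders can be made identical and 1 means
maximal discordance. The default optimizer considers the two one-sided
options — hold one tree fixed and run a single deterministic top-down
sweep over the other, keeping a node's child-order reversal only if it
lowers the score — and reports the better one, which makes the score
symmetric in its arguments and seed-free. A single greedy sweep does not
in general reach the global optimum, so `method = "exact"` additionally
enumerates every child-flip configuration of both trees (feasible to
roughly ten leaves) and returns the true minimum; the test suite verifies
the exact mode against an independent exhaustive oracle and that greedy
never undercuts it. The biological use is comparative: a
horizontally transferred gene's tree entangles more against the
housekeeping tree than a resampled housekeeping tree does, which the
suite demonstrates on planted-discordance distances at desk scale.
Display rooting of an unrooted tree at a user-designated outgroup is
purely presentational and does not affect the score's inputs.

## Riboswitch annotation

The 5'-UTR is taken as the `utr_length = 500` nt immediately upstream of
the target gene's start, reported 5'→3' on the coding strand (reverse
complement for minus-strand genes) and truncated with a warning at contig
edges. The FMN riboswitch's regulatory elements are searched for as
literal motifs: the antiterminator `TTCAGGGC` and the two
anti-antiterminators `CATCTTC` and `GAAGATG`. Scanning is exact first; a
motif with no exact hit gets one fallback pass at Hamming distance ≤ 1
(configurable), with exact hits ranked first. Literal scanning replaces
covariance-model search deliberately: the elements of interest are given
as literal sequences, the pipeline's question is *where they are and
whether a mutation falls inside them*, and a structural model would add a
heavy dependency without changing that answer. The motifs are annotated
on the given strand only, since the UTR is already oriented relative to
the downstream gene. The cost is that diverged riboswitches beyond one
mismatch per element are invisible to the scan.

Point mutations are mapped by positionwise comparison of equal-length
sequences (the mutants of interest are single-point mutants; indels are
out of scope and a length mismatch is an input error, reported per
variant without stopping a batch run). Classification assigns the region
(name of the motif span containing the position, else "other") and the
substitution class: purine↔purine or pyrimidine↔pyrimidine is a
transition, otherwise a transversion. Conservation profiles report
per-column base frequencies over non-gap characters and information
content `IC = 2 − H` bits, with all-gap columns flagged and set to 0.

Position 1 of the riboswitch coordinate system is defined by the packaged
wild-type construction (first base of the annotated region). The original
coordinate origin is not stated anywhere, so the synthetic wild type is
built so that the packaged mutant table's positions land on their stated
bases — e.g. position 105 is a G inside an anti-antiterminator span. Of
the three anti-antiterminator mutants only one is pinned by the source to
that region; the synthetic placement (`CATCTTC` at 41–47, `GAAGATG` at
102–108) puts positions 41, 102 and 105 inside spans, consistent with
"three mutants" without asserting which two beyond the pinned one.

## Expression

**qPCR.** Per sample, `ΔCt = Ct(target) − mean(Ct(references))` with the
arithmetic mean of the two reference-gene Cts (equivalent to a geometric
mean of reference expression — standard dual-reference practice);
`ΔΔCt = mean ΔCt(test) − mean ΔCt(calibrator)`; fold = `2^(−ΔΔCt)`. The
fold's SD is delta-method propagated from the test-group ΔCt spread.
Swapping test and calibrator inverts the fold exactly.

**Count matrices.** Normalization is median-of-ratios: per sample, the
median over genes (with all-positive counts) of the ratio to the gene's
geometric mean across samples; if no such gene exists the code falls back
to library-size ratios with a warning. All-zero genes are discarded
before testing. The differential-expression test is a transparent
negative-binomial Wald test rather than a clone of any existing package:
per gene, the log2 fold change of normalized group means (pseudocount
0.5), a method-of-moments dispersion estimate
`α̂ = max(0, (s² − m)/m²)` from within-group variances, and a Wald
statistic `log2FC / SE` with the delta-method standard error
`SE = sqrt(Σ_groups (1/μ_g + α)/n_g) / ln 2`, normal two-sided p-values
and Benjamini–Hochberg adjustment (an explicit step-up implementation,
cross-checked against `stats::p.adjust` in the tests).

With only two replicates per group the per-gene moment estimate of
dispersion is extremely noisy, and any test that relies on per-gene
variance alone (e.g. a Welch t-test with ~2 degrees of freedom) cannot
reach BH-adjusted significance for a handful of true positives among
hundreds of genes, *no matter how large the fold change*. The dispersion
is therefore stabilized by flooring each per-gene estimate at the
across-gene median — pooling information across genes exactly as the
field's standard tools do, but by the simplest defensible rule. The floor
is conservative: it widens the standard error of quiet genes and never
shrinks anyone's.

Significance follows the study's rule: `FDR < 0.05` **and**
`log2FC > 3`, applied one-sided for "upregulated" calls
(`two_sided_fc = TRUE` gives the symmetric variant). The fold filter
makes the rule very conservative under the null, which the suite
confirms over 500 seeded null matrices.

## Kinetics and statistics

Rates are central finite differences — `μ(t) = d ln(OD)/dt` for growth,
`dP/dt` for production — with optional moving-average pre-smoothing
(window 1, i.e. off, by default; 3 is a sensible choice for noisy data).
Finite differences are transparent and testable against closed forms: on
an exact exponential the log-derivative is recovered exactly, and on
logistic curves the estimate matches the analytic derivative to
discretization error. Because it is unclear whether a reported μmax is a
point estimate or a regression over an exponential window,
`specific_growth_rate()` offers both (`method = "regression"` fits
`ln OD ~ t` around the finite-difference maximum). Estimates are
invariant to time shifts and equivariant under time rescaling (per-minute
rates are per-hour rates divided by 60), which the suite checks.

Bioassay quantification inverts a monotone piecewise-linear calibration
curve (standards spanning 0–300 ng mL⁻¹) and multiplies by the dilution
factor. Responses below the lowest standard's span return an explicit
below-detection flag carrying the detection limit — below-detection
concentrations are *never* stored as 0, matching how the packaged mutant
table records the wild type ("< 0.2 ng mL⁻¹"). Responses above the top
standard raise an error suggesting further dilution rather than
extrapolating.

Group comparisons use two-way ANOVA with type-II sums of squares
(`car::Anova`) and Tukey HSD post-hoc p-values from the studentized range
(`stats::TukeyHSD`), read at p < 0.05. An all-identical response is
reported as F = 0 with all Tukey p = 1 by convention (the raw statistics
are 0/0). Summary statistics use the even-*n* median convention (midpoint
of the two central order statistics).

## What the synthetic generators emulate — and what they do not

Every generator is a pure function of its seed (byte-identical reruns)
and returns a machine-readable truth object consumed by the recovery
tests.

* `make_pangenome()` — default scenario: 83 species, 16 carriers (the
  genus-panel shape), most carriers primate-associated, every genome
  carrying ribCF/ribU homologs, insect-niche genomes given the most
  divergent ribCF (identity 42–50%). Carriers receive a contiguous
  ribDEABH block mutated to a target identity (default 60–95%);
  substitutions draw 60% from positive-scoring residue pairs so that
  similarity stays above identity and the two statistics remain
  distinguishable. Non-carriers receive nothing or scrambled decoys
  (same composition, no positional homology). Alternative layouts plant
  the same sequences split across contigs or scattered along one, to
  exercise the co-location rule in isolation.
* `make_riboswitch_set()` — a 500-nt wild type carrying the three motifs
  at fixed spans and the packaged mutant table's wild-type bases at its
  positions, plus one single-point variant per mutant.
* `make_ct_table()` — triplicate qPCR design; the mutant target Ct is
  shifted by −log2(fold) so a zero-noise table encodes the fold exactly;
  Gaussian cycle noise (default SD 0.15 cycles) on every measurement.
* `make_count_matrix()` — duplicate RNA-seq design: NB counts, per-gene
  means log-uniform over 10–1000, dispersion 0.05, log-normal per-sample
  depth perturbations (SD 0.15), a planted 4-gene cluster at 18-fold.
* `make_timecourse()` — logistic biomass (μmax 0.31 h⁻¹, X₀ 0.05,
  K 3.0 — the observed final OD), substrate (10 g L⁻¹) consumed through
  a yield chosen so exhaustion coincides with stationary phase, and
  Luedeking–Piret product formation `dP/dt = α·dX/dt + β·X` with β = 0
  and α set so the peak volumetric rate is 13.9 ng mL⁻¹ h⁻¹. The
  generator is anchored to the reported *rates*; it does not reproduce
  the timing of the real fermentation's rate peak (growth-associated
  formation on a symmetric logistic peaks at K/2) nor the post-peak
  decline of extracellular riboflavin, which a cumulative
  Luedeking–Piret model cannot produce.
* `make_fecal_table()` — log-normal donor concentrations truncated to
  80.7–728.2 ng g⁻¹ (the observed range). The shape is an assumption;
  only the range is anchored.

These generators produce sequence panels by uniform random residues plus
planted substitutions — no realistic evolutionary model, no indels in
proteins, no rate heterogeneity, no compositional bias. Passing recovery
tests therefore demonstrates that the *inference machinery* is correct
under its stated model (planted truth is recovered, thresholds behave
monotonically, normalization cancels depth), not that real genomes would
be called with the same accuracy: real panels add annotation errors,
split genes, true paralogy and diverged riboswitches that literal motif
scanning cannot see.

## Problem sizes and numerical choices

The shipped tests run the default 83-genome screen once and otherwise use
panels of 4–12 genomes, trees of ≤ 8 taxa, 200-gene count matrices, and
500 null-matrix replicates for the FDR property — sizes chosen so the
whole suite completes in about two minutes while every stage is exercised
at its default parameters. Convergence and tolerance constants: MCL
tolerance 10⁻⁶ with cap 100 and support cut-off 10⁻⁸; NJ tie-break by
sorted label pairs with a 10⁻¹² band for Q-ties; ANOVA degeneracy
detected at relative scale 10⁻²⁰; all are internal constants documented
at their definition sites.

## Known limitations

* The homology stage has no heuristic seeding; it is exact but
  quadratic per pair, sized for panels of tens-to-hundreds of genomes
  with bacterial proteomes, not for all-vs-all searches of large
  databases.
* E-value calibration uses fixed ungapped Karlin–Altschul constants;
  absolute E-values differ from gapped, composition-adjusted BLASTP
  values (the screen's threshold logic does not depend on this).
* The greedy entanglement optimizer is a heuristic; use
  `method = "exact"` below ~10 leaves when the exact minimum matters.
* Literal motif scanning misses riboswitch elements diverged beyond the
  mismatch tolerance and reports nothing about RNA secondary structure.
* The DGE test trades the sophistication of shrinkage estimators for
  transparency; with two replicates per group its dispersion floor is
  deliberately conservative, and recovery is validated by parameter
  recovery on synthetic data, not by matching any external tool's
  output.
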