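---
title: "Label-free metaproteomic differential abundance: models, thresholds and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free metaproteomic differential abundance: models, thresholds and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdiff)
```

# The analysis problem

`mpdiff` implements an integrated quantification and differential-abundance
workflow for shotgun metaproteomics of complex microbial communities such as
the human distal gut, where MS/MS spectra are searched either against
per-sample "matched metagenome" (MM) protein databases predicted from the
community's own sequencing reads, or against a reference database of
sequenced isolate genomes (HMRG). Strain- and species-level redundancy in
such databases would otherwise split spectral counts across near-identical
proteins, so microbial ORFs sharing high sequence identity are first
collapsed into *orthologous clusters* (OCs) and all quantification happens
at the cluster level. The pipeline covers:

1. **Database construction** — redundancy removal (a protein is dropped when
   its full length is contained in a longer protein at 100% identity) and
   ortholog clustering by Markov clustering (MCL) of the >80%-identity
   alignment graph, inflation 1.5.
2. **PSM quality control** — charge-dependent XCorr floors (1.8/2.5/3.5 for
   1+/2+/3+, boundary inclusive), deltCN ≥ 0, fully tryptic termini, at most
   4 missed cleavages, and (for MM searches) a closed −10..+10 ppm precursor
   mass window; then ≥2 distinct peptides per protein (HMRG) or per cluster
   (MM, after a 1-peptide read-level stage).
3. **Target-decoy FDR** — the concatenated-search estimator
   2·D/(T+D), where D and T are decoy and target PSMs passing all filters.
4. **Label-free quantification** — a spectrum counts toward a cluster only
   when *every* protein it matches belongs to that cluster (peptides
   spanning clusters count nowhere); human proteins instead count shared
   peptides toward every match. Counts from run *i* are rescaled by
   α*ᵢ* = N/nᵢ with nᵢ the run's total acquired MS/MS count and N the cohort
   mean, so a fully accounted run renormalizes exactly to N.
5. **Differential abundance** — features with more than five counts in four
   or more of the runs under comparison (pooled) are tested with the
   two-sided Wilcoxon rank-sum test; Storey q-values are computed across the
   prefiltered set; a feature is called significant only when q < 0.05 *and*
   the group medians differ by more than 5 normalized counts.
6. **Taxonomy** — nearest-neighbor assignment at ≥80% identity and ≥80%
   query coverage, genus-level ties left unassigned (the "human gut
   microbiome" fallback), contigs labelled by majority vote of their reads,
   and rarefied annotation abundances (subsample without replacement to the
   smallest depth, 100 iterations, report the mean).
7. **KEGG modules** — modules with more than 30% of member KOs detected are
   kept; module abundance is the sum of member-KO normalized counts;
   differential modules use Wilcoxon + Benjamini–Hochberg at 10% FDR with
   the same >5 median-difference rule; and per-(taxon, module) log2
   fold-changes are regressed on the taxon's own abundance fold-change, with
   points outside the 95% prediction interval of the OLS fit flagged as
   deviating from their host taxon's behavior (e.g. butyrate-production
   modules falling faster than *Faecalibacterium* itself).

# Statistical components authored here

**Wilcoxon rank-sum.** Exact two-sided p-values by enumeration of all
`C(m+n, m)` labelings when the pooled sample size is ≤12 and tie-free (the
p-value is the proportion of labelings whose rank-sum deviates from its mean
at least as much as observed); otherwise mid-ranks with the tie-corrected
normal approximation, without continuity correction. With 4-vs-6 runs the
smallest achievable two-sided p is 2/210 ≈ 0.0095 — a hard floor that
matters for q-value behavior (below).

**Storey q-values.** π̂₀ = #{p > λ}/((1−λ)m) at fixed λ = 0.5, clamped to
[1/m, 1]; q-values are the step-down minima π̂₀·m·p₍ⱼ₎/j on the sorted
p-values, capped at 1. Forcing π₀ = 1 reproduces Benjamini–Hochberg exactly,
which the tests exploit as an oracle identity. λ is fixed rather than
smoothed because the prefiltered feature sets here are small (tens of
features), where the smoother is unstable.

**MCL.** Column-stochastic normalization of the thresholded identity graph
(edge weight = percent identity; self-loops at the maximum incident weight
keep the iteration aperiodic), alternating expansion (matrix power 2) and
inflation (elementwise power 1.5, renormalize), pruning entries below 1e−8,
convergence when the flow matrix changes by less than 1e−8 (at most 200
iterations; non-convergence is an error). Read-out is attractor-based;
attractors with mutual flow merge, every node follows its largest incoming
flow, ties resolve to the smallest cluster id — making the partition
deterministic. On disjoint-clique graphs the output provably equals the
connected components, which is the test oracle.

**Alignment.** All identity computations go through Smith–Waterman local
alignment (BLOSUM62, gap opening 10, extension 0.5) via `Biostrings`;
identity is recomputed from the alignment path (matches / alignment
columns) so only the optimal path matters, not the score scale. A minimum
alignment length (default 30 residues) replaces the BLASTP e-value gate:
e-values depend on database size, which is meaningless for the small
synthetic databases, while identity and coverage carry the actual decision.

# The synthetic cohort generator

`cohort_spec()` fixes every stochastic element of a simulated study behind
one integer seed. The default cohort mirrors the motivating design: 12
subjects (4 healthy, 6 ICD, 2 CCD) in technical duplicate, 24 MS runs.

* **Abundances.** Genus base abundances are log-normal (sdlog 1.0 —
  heavy-tailed, a few dominant genera), multiplied per sample by log-normal
  noise (sdlog 0.4) and renormalized to proportions. Group effects
  (depletion maps, e.g. Firmicutes-like genera at 0.2–0.25 in ICD) multiply
  before renormalization.
* **Spectra.** Run totals are negative binomial (mean 4000, dispersion 50);
  spectra are allocated to proteins ∝ genus abundance × log-normal protein
  detectability; peptides come from full tryptic digestion (cleave after
  K/R, not before P, ≤4 missed cleavages, length ≥6) with flanking residues
  recorded.
* **Errors.** A fraction 2·`decoy_hit_rate` of PSMs are incorrect, split
  evenly between reversed-protein decoys and random target peptides — the
  symmetry that makes 2·D/(T+D) a consistent estimator of the incorrect
  fraction among accepted PSMs. Correct matches draw XCorr from a shifted,
  charge-sloped gamma and ppm errors from Normal(0, 3); incorrect matches
  from a low-mean gamma and Uniform(−50, 50) ppm, so the ±10 ppm filter is
  informative.
* **Planted signal.** Cluster-level fold-changes and (genus, module) effects
  multiply detection weights in the targeted group only, and are recorded in
  the returned ground truth.

Because per-run spectrum totals are fixed by the instrument, spectral
counting is **compositional**: depleting part of the pool inflates
everything else. Two consequences shaped the calibration scenarios (both
verified analytically before simulation): a planted depletion affecting
~20% of the spectral pool inflates null clusters past the median-difference
gate, so the recovery scenario plants its 10 depleted clusters in a genus
holding only ~5% of the pool (a two-tier abundance profile, typical of gut
communities); and per-sample *genus-level* noise moves all clusters of a
genus coherently, so a single lucky genus-block separation flags many
correlated nulls at once. The recovery scenario therefore uses
technical-replicate-scale sample noise (sdlog 0.05), making per-cluster
noise counting-dominated and independent. Passing it shows the decision
procedure is calibrated under counting noise; it does *not* show robustness
to strong inter-subject biological variability, which a 4-vs-6 rank test
cannot overcome when noise is block-correlated.

# Numerical and design choices

* Ties in `remove_redundant` (identical sequences) keep the
  lexicographically smaller id; representatives are the longest member with
  the same tie rule — all outputs are byte-deterministic.
* The prefilter pools runs across both groups ("more than five counts in
  four or more of the runs under comparison"); a per-group variant would
  change eligibility only for features absent from one group.
* deltCN ≥ 0.0 is kept as printed — a non-negativity check rather than a
  real gate; charges above 3+ use the 3+ threshold.
* n_i is the run's total *acquired* MS/MS count (contaminant and decoy
  matches included), recorded from metadata, not the accepted subset.
* FDR is estimated at the peptide-spectrum level after all spectrum-level
  filters (including the ppm window); the ≥2-peptide protein filter is
  applied to targets only, since decoy counting is peptide-level.
* Module-level calls default to BH at 10% FDR (the procedure's stated
  operating point) while the deviation figure's significance coloring is
  sometimes quoted at 5%; both are exposed (`module_fdr`) and the report
  carries whichever was used.
* Module medians are computed per run (technical replicates as separate
  observations), not per subject.
* The deviation fit uses group-median log2 fold-changes with a pseudo-count
  of 1, and flags points outside the per-point 95% OLS prediction interval.
  For in-sample points that interval is conservative — fitted residuals have
  variance (1−h)σ² against a (1+h)σ̂² interval — so the null flag rate is
  bounded by, rather than equal to, 5% (about 2–3% at 20 points). This is
  the desirable direction for a deviation screen.
* `pipeline_config()` validates group references before any stage runs;
  every threshold lands in the run manifest.

# What the tests do and do not show

The test suite generates all fixtures in code (plus one 6-protein/12-PSM
hand-derived golden table) and checks, among others: MCL against a
connected-components oracle on 100 clique graphs; exact Wilcoxon against
exhaustive permutation on all 70 splits of 8 values; the Storey/BH identity
on 1000 random p-vectors; FDR calibration on ~10,000-spectrum runs with 20%
incorrect matches (estimate within ±20% relative of truth, averaged over 20
seeds); exact renormalization to N and scale invariance; recovery of ten
5-fold-depleted clusters at baseline median ≈20 counts (median sensitivity
≥0.8, FDP ≤0.1, 20 seeds); a global-null significant-call rate within
Monte-Carlo error of nominal (50 cohorts); and detection of a 4-fold
(genus, module) effect beyond its genus shift in ≥90% of 50 cohorts. Problem
sizes (40–72 clusters, 8–10 runs, 1000–5000 spectra/run) are the smallest at
which the planted signal structure is realistic; they keep the whole suite
within a few minutes. Scenarios at these sizes say nothing about behavior on
cohorts with hundreds of thousands of ORFs, where clustering cost is
quadratic in database size and would need a pre-screening stage.

# Known limitations

* The generator produces amino-acid ORFs directly — no nucleotide reads,
  assembly, chromatography or spectra; search-engine scores are *modelled*,
  not computed from spectra.
* Identity-based taxonomy is performed in protein space; the thresholds (80%
  identity, 80% coverage) keep their meaning but absolute assignment rates
  differ from nucleotide alignments.
* Human and contaminant proteins are not simulated by default;
  `human_protein_counts()` is exercised on constructed tables.
* With 4-vs-6 runs the exact-p floor means Storey/BH can only reject when
  the eligible feature set is small (≈50 features for ten true positives at
  q < 0.05); larger matrices need more runs, not better code.
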