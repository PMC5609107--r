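---
title: "Delineating bacterial genospecies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating bacterial genospecies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bacterial "species" boundaries are increasingly drawn from whole genomes
rather than phenotype or a single marker gene. For a cohort of genomes
assigned to one nominal species, the question is whether the cohort in fact
contains several *genospecies*: groups of strains that are far more similar
to each other than to the rest. `genospecies` implements a complete workflow
for that decision and a synthetic cohort generator that provides ground truth
for every stage.

The workflow combines five lines of evidence:

1. **Fragmented genome similarity.** Each genome is cut into sliding windows
   (200 bp, step 100 bp by default) and every fragment is locally aligned
   against every other genome. The similarity of A to B is the summed best
   score normalized by the fragments' self-scores, so `sim(A,A) = 100`
   exactly and non-homologous content drives values far below the ANI scale
   (inter-species values of 15–50% are normal for this statistic). The
   symmetrized complement `100 − (sim(A,B)+sim(B,A))/2` is exported as a
   nexus distance matrix suitable for phylogenetic-network software.
2. **Average nucleotide identity (ANI).** The query genome is cut into
   consecutive 1,020-bp pieces; a piece contributes if its best hit in the
   subject reaches 70% identity over 70% of the piece, and ANI is the mean
   identity of contributing pieces, averaged over both directions. ANI of
   95–96% corresponds to the classical 70% DNA–DNA hybridization species
   boundary; clusters are called by single linkage at a configurable cutoff
   (default 94%). Pairs with no qualifying fragment are reported *missing*,
   distinct from a low value.
3. **wgMLST.** A pan-locus allele database is built by greedy, length-ordered
   clustering of the cohort's genes (a gene joins the first locus it matches
   at ≥ 90% identity and ≥ 80% mutual coverage). Strains are called against
   the database with the same filters; allele numbers are minted per locus in
   order of first observation. Profile distance is the fraction of shared
   loci with differing alleles, and a UPGMA dendrogram summarizes the cohort.
4. **Pangenome openness.** Proteins are compared all-vs-all; hits at ≥ 40%
   identity and ≥ 50% coverage form a weighted graph clustered with an
   in-house Markov Cluster (MCL) implementation (inflation 1.5). Families are
   partitioned into core (all genomes), singletons (one genome) and shell.
   Seeded permutations of genome order yield pangenome/core/new-gene
   development curves; the pangenome curve's log–log slope γ gives Heap's
   exponent and α = 1 − γ (α ≤ 1: open pangenome), and core/new-gene curves
   are extrapolated with `n(x) = k·exp(−x/t) + tg(θ)`, whose asymptote
   `tg(θ)` is the converged core size or novel-gene rate.
5. **The joint decision.** A cluster is *supported* as a genospecies when
   every intra-cluster ANI meets the cutoff **and** its α exceeds the whole
   cohort's α by a margin (default 0.02): a clonal, species-like group grows
   its pangenome more slowly than the mixed cohort. The core-fraction
   contrast (cluster core / cluster pangenome vs the global figure) is
   reported as corroborating evidence.

A distance-based marker module (Kimura 2-parameter distances with set-wide
complete deletion, neighbor joining) stands in for likelihood marker-gene
trees; maximum-likelihood search is out of scope.

# The alignment engine

All stages share one pairwise local-alignment primitive instead of an
external BLAST. It is k-mer seed-and-extend (11-nt words for DNA, 4-aa for
protein): shared words vote for diagonals, and the best-voted candidates are
aligned with an affine-gap (Gotoh) local DP — exhaustive when both sequences
are ≤ `exact_threshold` (600 bp), banded around the seeded diagonal
(half-width 16) otherwise. Scoring defaults are match +1, mismatch −1, gap
open −2, gap extend −1, with a gap of length L costing
`gap_open + (L−1)·gap_extend`. Identity is computed over all alignment
columns including gaps, matching common BLAST reporting and making the
90%/70% retention thresholds conservative. Both DNA strands are searched;
ties prefer the plus strand, then the smallest query and subject start.

Design consequences worth knowing:

* The banded score never exceeds the true Smith–Waterman optimum; on the
  simulator's indel-free genomes it is exact. Real genomes with indels larger
  than the band near a fragment boundary can be under-scored; raise `band` if
  that matters.
* Diagonal buckets supported by a single shared word are almost always chance
  matches; they are aligned only when nothing better seeded
  (`min_seed_votes = 2`). With ≥ 90%-identity targets and 11-nt words, a
  200-bp fragment is expected to share dozens of words with its true match,
  so real hits are never filtered; an adversarial mutation spacing that
  removes every shared word is accepted as a miss.
* The published study used BLASTn/BLASTp whose word sizes and penalties it
  does not state; every engine parameter here is explicit configuration.
* The protein-graph gate (identity ≥ 40%, coverage ≥ 50%) replaces the
  published BLASTp e-value of 1e−6, which cannot be reproduced without
  Karlin–Altschul statistics. Edge weights are
  `identity · min(coverage)` rather than raw score to avoid length bias.

# The synthetic cohort: what it emulates and what it does not

`sim_config()` describes a cohort by its gene-content architecture and two
divergence levels. The defaults are the published cohort's structure at desk
scale: 3 clusters of 5/4/4 strains plus 4 unclustered singleton strains;
`d_within = 0.02` and `d_between = 0.13`, so intra-cluster ANI sits near 98%
and inter-cluster ANI near 87%, the regime reported for the real cohort
(intra ≥ 95%, inter 85–88%). Each lineage (cluster or singleton strain)
carries the shared core (60 genes by default), its own accessory set (20),
and each strain a Poisson number of private genes (mean 8); genes average
330 bp with 60-bp spacers, giving ~35-kb genomes rather than ~3 Mb. The scale
factor (~100× smaller) keeps the full pipeline and the 20-cohort parameter
recovery inside desk-scale runtime while preserving every statistic's
structure; gene counts, not genome size, drive the pangenome curves.

Divergence is applied on two levels. Lineage ancestors are mutated away from
the root at rate `(d_between − d_within)/2` per branch and strains from their
lineage ancestor at `d_within/2`, so the *expected pairwise* divergence is
exactly `d_within` within clusters and `d_between` between lineages — this is
the contract recorded in the truth table (`expected_identity = 100·(1−d)`).
Substitutions are drawn independently per site with transition:transversion
odds `kappa:2` and are *resampled* rather than modeled with multiple hits;
at the d ≤ 0.15 used here the collision bias raises observed identity by at
most a few tenths of a percent, which the tests' tolerances account for.
Genes stay intact ORFs — first/last codons are never mutated, and internal
stop codons arising from mutation are repaired at the third codon position —
so every emitted protein translates cleanly.

Not emulated: indels, rearrangements, recombination tracts, horizontal
transfer from outside the gene pool, codon-level selection, and sequencing
error. A green test on this generator therefore establishes that the
statistics and decision rules behave correctly on cohorts with known,
clean cluster structure — not that the pipeline is robust to assembly
artifacts or saturated divergence.

# Numerical choices

* **Heap's fit.** Ordinary least squares of `log(median)` on `log(N)`,
  medians for robustness to permutation outliers; `N = 1` is included by
  default but exposed as a flag, since published fits rarely state its
  treatment. α is derived as `1 − γ` exactly. The published formula prints
  the power law with a negative exponent while using α = 1 − γ in its
  results; this package fits the growth exponent γ and derives α, which
  matches the reported α range semantics (α near 1 = closed-ish).
* **Decay fit.** Nonlinear least squares (`nls`, port algorithm) on per-N
  *means* (the published choice for these curves), multi-start over
  `t ∈ {1, 2, 5, 10}`, bounds `t > 0`, `tg(θ) ≥ 0`; constant curves
  short-circuit to `k = 0`.
* **MCL.** Column-stochastic matrix with self-loops at each node's maximum
  incident weight; expansion/inflation alternate with pruning below 1e−6 and
  renormalization until the matrix change drops below 1e−5 (cap 100
  iterations, error with diagnostics otherwise). Families are read as
  connected components of the converged nonzero pattern, which makes the
  "attractor" interpretation robust to numerically tiny overlaps.
* **Clustering.** Single linkage (connected components of the thresholded
  graph) is the primary rule, because "did not cluster with any other
  genome" semantics are component-based; complete linkage is available
  behind a flag. Cluster labels A, B, C… are assigned by decreasing size,
  then lexicographically smallest member, which reproduces the published
  labeling on the packaged ANI table. Printed ANI tables are slightly
  asymmetric (rounding); input within a 0.5% asymmetry tolerance is
  symmetrized by the mean.
* **wgMLST distance** excludes loci missing in either profile (draft-genome
  absence is usually assembly-driven); `missing_as_diff = TRUE` counts
  one-sided absences instead. The 80% coverage filter is applied to the
  locus representative's length. Note the statistic's informative regime:
  with ~300-bp genes, allele-sharing requires within-group divergence well
  below 1% (at 2% essentially every allele differs and distances saturate
  near 1), while homologs beyond 10% divergence drop below the 90% identity
  filter and found per-lineage loci — exactly the published filter behaving
  as specified, but worth knowing when reading the dendrogram.
* **K2P.** Complete deletion is applied matrix-wide (a column with a gap or
  N anywhere is removed for every pair), the convention of the published
  marker tree, not per pair. Saturated pairs (log-domain violation) raise an
  error rather than returning NaN.
* **Seeds.** The pipeline derives per-stage seeds as
  `(seed·1009 + 97·stage) mod 2^31 − 1`, so stages are isolated but the whole
  run is reproduced by one integer.

# Known limitations

* The fragmented-similarity and ANI statistics share the seed-and-extend
  engine; they are heuristic lower bounds in the presence of large indels.
* The greedy wgMLST database depends on gene length order; the published
  web-service's internal algorithm is undocumented, so scheme identity across
  tools is not expected — only the 90%/80% filter semantics are.
* Bootstrap support values on dendrograms and the likelihood marker tree are
  out of scope.
* The species-support margin (0.02 on α) is a pragmatic default; the source
  analysis offers no margin, and cohorts with heavy within-species gene flux
  can legitimately show low α in a true cluster.
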