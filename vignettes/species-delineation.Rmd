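---
title: "Methods: taxonogenomic species delineation with ogri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonogenomic species delineation with ogri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogri)
```

# The problem

A new bacterial isolate is described as a new species when its sequence
relatedness to every named relative falls below conventional boundaries:
16S rRNA identity below 98.65% (below 95% the genus itself is in
question), digital DNA–DNA hybridization (dDDH) below 70%, and average
amino-acid identity (AAI) below the 95–96% band. `ogri` implements that
decision pipeline end to end — 16S screening, K2P/neighbor-joining
phylogeny with bootstrap, reciprocal-best-hit orthology, the AGIOS, AAI
and dDDH indices, and the threshold verdict — together with a forward
simulator that provides exact ground truth for every estimator.

# Models and procedures

## Kimura 2-parameter distances

For a pair of aligned sequences, `pair_counts()` computes the proportion
of sites differing by a transition (`P`: A↔G, C↔T) and by a transversion
(`Q`), over the sites where both sequences carry an unambiguous base
(pairwise deletion). The distance is the closed form

d = −½ ln((1 − 2P − Q) √(1 − 2Q)),

in expected substitutions per site. The model assumes independent,
identically distributed sites, equal base frequencies and a single
transition/transversion rate ratio; none of these hold exactly for real
16S alignments, which is why the distance feeds a *relative* placement
(the tree), not the species verdict itself. When 1 − 2P − Q ≤ 0 the pair
is saturated: the distance is undefined and reported as `Inf` with a
warning, and the tree stage refuses such matrices rather than guessing.

Before any distances are computed, `coverage_filter()` removes alignment
columns where fewer than 95% of taxa carry an unambiguous base. This is
the "partial deletion, 95% site coverage" convention of the common MEGA
workflow, interpreted as: one global column filter, then pairwise
deletion of remaining gap/ambiguous cells per pair. The filter is
deliberately applied once — bootstrap replicates resample columns of the
*filtered* alignment, so every replicate sees the same site universe.
Ambiguity codes (N and the IUPAC letters) are treated as missing sites,
never as mismatches; this is the conservative reading and matches how
partial deletion treats them.

## Neighbor joining and bootstrap

`nj_tree()` is the canonical Saitou–Nei agglomeration: join the pair
minimizing the Q-criterion, with the standard branch-length formulas. Two
numerical choices matter:

* **Tie-breaking.** When several pairs minimize Q (common on symmetric
  synthetic data), the pair whose cluster representatives are
  lexicographically smallest is joined, so results are bit-reproducible.
* **Negative branches.** NJ can produce negative branch lengths on
  non-additive matrices. They are clamped to zero with the difference
  moved to the sister branch, preserving the joined pair's path length —
  the common practice in distance-tree software.

On additive matrices NJ is consistent; the test suite verifies exact
recovery (topology and branch lengths) against random trees and, for six
or fewer taxa, against exhaustive enumeration of all topologies with a
least-squares embedding oracle.

`nj_bootstrap()` resamples alignment columns with replacement, rebuilds
the NJ tree per replicate (500 replicates by default; tests and the
acceptance script use 100, which is ample for a strongly marked split),
and labels each internal bipartition of the full-data tree with the
percentage of replicates containing it. Replicates that produce a
saturated pair are skipped and the denominator adjusted, with a warning.
Only the NJ tree is bootstrapped; maximum-likelihood inference is out of
scope.

## Orthology

Ortholog detection is strict reciprocal best hits (RBH) between the two
proteomes. A deterministic k-mer prefilter (`candidate_pairs()`: at least
2 shared protein 4-mers) stands in for heuristic database seeding; every
candidate pair is then aligned with exact global Needleman–Wunsch under
BLOSUM62 with affine gaps. Hits must reach 30% identity over aligned
columns and 70% coverage of *both* sequences. These identity/coverage
floors replace a database-search E-value cutoff, which has no meaning
outside Karlin–Altschul statistics; on real proteomes the identity and
coverage floors dominate the E-value filter anyway, and the exact
alignment makes the result deterministic. RBH (rather than one-way best
hits or multi-genome clustering) was chosen as the stricter, symmetric
variant: swapping the genomes permutes the pair set but never changes
it, which the tests assert.

For each RBH pair the corresponding CDS are globally aligned and the
nucleotide identity recorded; that table is the AGIOS input.

## Relatedness indices

* **AGIOS** (`agios()`): the unweighted arithmetic mean of per-pair
  nucleotide identities × 100 — the plain reading of a "mean percentage
  of identity among orthologous ORFs". A length-weighted variant is
  available (`weighted = TRUE`) but off by default.
* **AAI** (`aai()`): the unweighted mean of per-pair protein identities.
* **dDDH** (`fragment_ddh()`): genome A is cut into consecutive 1020-bp
  fragments (a common fragment convention for genome-distance tools;
  configurable). Each fragment is mapped against genome B with the
  seeded local search (11-mer anchors, banded local extension, both
  strands); over fragments with a qualifying HSP, the distance is
  d = 1 − (identical positions / total HSP length) — the
  sum-of-identities statistic that is robust to incomplete assemblies —
  and a logistic model maps d to a dDDH percentage.

The logistic coefficients are configuration, not science fixed by the
method: `ddh_model()` defaults to midpoint 0.06 and slope 80 (version
tag `ogri-logistic-1`, recorded in every result). This calibration puts
the 70% dDDH boundary at d ≈ 0.05, consistent with the conventional
95–96% nucleotide-identity species boundary, the self-comparison limit
above 99%, and unrelated genomes at the lower plateau. Comparisons with
dDDH values produced by other tools are therefore approximate by
construction, and every result records `ddh_model_version`.

Two guards keep the dDDH statistic honest: fragments shorter than 200 bp
(assembly tails) are dropped, and HSPs scoring below 50 (match +1,
mismatch −1) are ignored, because random 20-kb-scale sequences otherwise
contribute short, high-identity spurious segments that would inflate the
index — the role an E-value cutoff plays in database-search pipelines.

## Decision rules

`classify_16s()`: identity ≥ 98.65% supports conspecificity (flagged
provisional — genomic confirmation required); strictly between 95% and
98.65% proposes a new species within the genus; at or below 95% flags a
possible new genus. Boundary equality always resolves to the non-novel
side, matching the strict "greater than / lower than" phrasing of the
thresholds. `classify_genomic()`: dDDH < 70% and AAI < 95% declare a
distinct species; both at or above declare conspecificity; a conflict is
`inconclusive`, never auto-resolved. The AAI threshold defaults to the
lower edge (95) of the 95–96 band — conservative toward declaring
conspecificity. AGIOS is reported descriptively but excluded from the
verdict: no accepted demarcation threshold exists for it.

`species_report()` combines the calls: unanimous genomic evidence
dominates the 16S screen (the role in-silico DDH inherits from wet-lab
hybridization), so a 16S conspecificity hypothesis refuted by all
genomic indices yields a new-species verdict, while a 16S novelty signal
contradicted by genomic conspecificity is reported inconclusive. The
verdict is monotone: raising any identity or relatedness value never
moves it toward greater novelty (property-tested).

# The synthetic-data generator

`simulate_ancestor()` builds an annotated genome: non-overlapping genes
on both strands, each CDS starting ATG, ending with a stop, free of
internal stops, base composition targeting a requested G+C. The defaults
(200 genes of mean 900 bp, 150-bp intergenic spacers, 40% G+C, one
scaffold) give a ~200-kb miniature with the gene density and composition
of a *Bacillaceae*-like genome — large enough for stable index estimates,
small enough that a full pairwise comparison runs in under a minute.

`evolve_k2p()` applies the continuous-time K2P process per site for a
branch length d (transition rate ακ, each transversion β, scaled so the
expected substitutions per site equal d) and returns the realized P and
Q, giving closed-form expectations to test against. `make_pair()` evolves
two descendants independently for d/2 each, deletes exactly
`round(fraction × n)` genes from descendant B, and optionally applies
small indels to B's intergenic regions, updating coordinates. Three
deliberate simplifications keep the ground truth analytic:

* substitutions are the only within-gene events — indels stay intergenic
  by default, so homologous CDS align without gaps and the per-gene
  identity is a direct positionwise comparison;
* codons whose evolved state is an in-frame stop are redrawn until sense
  (a crude purifying selection), so every descendant gene translates and
  the RBH count equals the retained-gene count exactly;
* protein divergence *emerges* from nucleotide substitution through
  translation rather than being simulated separately — exactly how AGIOS
  and AAI differ in the real pipeline (at moderate divergence AAI falls
  below AGIOS, because most nucleotide changes are nonsynonymous under
  this neutral process).

What the generator does **not** emulate: rearrangements, horizontal
transfer, codon-usage and strand-composition bias, paralogous families,
assembly errors and contamination. Passing the recovery tests therefore
shows the estimators are correct *as algorithms*; it does not show
robustness to those real-data complications, and real comparisons
(`scripts/validation.R`) remain the end-to-end check against published
reference values.

# Parameters at a glance

| parameter | default | where | rationale |
|---|---|---|---|
| 16S species / genus threshold | 98.65 / 95 % | `thresholds()` | conventional demarcation bounds |
| dDDH species threshold | 70 % | `thresholds()` | conventional DDH boundary |
| AAI species threshold | 95 % | `thresholds()` | lower edge of the 95–96 band (conservative) |
| site-coverage filter | 0.95 | `coverage_filter()` | partial-deletion convention |
| bootstrap replicates | 500 | `nj_bootstrap()` | standard bootstrap depth |
| ortholog identity / coverage | 0.30 / 0.70 | `best_hits()` | standard orthology floors |
| protein scoring | BLOSUM62, gap −10/−0.5 | `scoring_scheme()` | EMBOSS-needle-like defaults |
| nucleotide scoring | +1/−1, gap −10/−0.5 | `scoring_scheme()` | EMBOSS-needle-like defaults |
| dDDH fragment length | 1020 bp | `fragment_ddh()` | common fragment convention |
| dDDH logistic | midpoint 0.06, slope 80 | `ddh_model()` | 70% boundary at d ≈ 0.05; plateaus at the identity/unrelated limits |
| local search seeds | k = 11, band 32, min HSP score 50 | `local_search()` | seeds sensitive to ~80% identity; score floor rejects spurious segments |
| genetic code | NCBI table 11 | `load_genome()` | bacterial standard; configurable |

# Numerical choices and degenerate inputs

* Affine gap convention: a gap of length L costs `gap_open + L ×
  gap_extend` (both non-positive). The test suite pins the alignment
  engine to an exhaustive enumeration oracle under exactly this
  convention for all short sequences.
* Identity denominators: the default is aligned columns where both
  sequences have a residue; `percent_identity()` also offers the
  shorter-sequence denominator. Ambiguity characters never count as
  matches, even to themselves.
* Zero-length denominators, empty ortholog tables, saturated distances,
  out-of-range coordinates and empty FASTA records are all errors or
  warnings with explicit messages, tested per module.
* All randomness flows through explicit integer seeds; generators are
  pure functions of (parameters, seed), and identical seeds give
  byte-identical FASTA, Newick and report output.

# Problem sizes

The test suite runs on miniatures (12–30 genes, 300–1200-site
alignments) in about two minutes. The acceptance script uses the study
conditions for parameter recovery — 100-kb sequences × 20 replicates at
d ∈ {0.02, 0.1, 0.3}, a 200-gene pair at 10% gene loss, 100 additive
matrices up to 8 taxa, 200 random scoring schemes against the
enumeration oracle, and a 10-taxon × 1200-site bootstrap — chosen so the
standard errors are far smaller than the tolerances being checked while
the whole script completes in a few minutes on one CPU.

# Known limitations

* The dDDH logistic is a package-level calibration (see above);
  cross-tool dDDH values agree only approximately.
* The 16S identity of two real sequences depends on the aligner and the
  denominator convention; second-decimal agreement with values computed
  by heuristic database search is not expected.
* NJ supports are NJ-only; no maximum-likelihood tree is built.
* The pipeline consumes gene annotations; it does not call genes
  (the validation script uses an external caller for that).
* Ortholog detection is pairwise RBH; no multi-genome clustering or
  paralog resolution beyond deterministic best-hit ties.
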