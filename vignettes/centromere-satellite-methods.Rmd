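---
title: "Methods: satellite monomer decomposition, CENH3 profiling and HOR mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite monomer decomposition, CENH3 profiling and HOR mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pancent` implements the analyses used to dissect satellite-based plant
centromeres: decomposing assembled arrays into monomers, harvesting
monomer-sized fragments from reads, measuring satellite diversity and
duplication, classifying repeat families by 5-mer composition, profiling
CENH3 enrichment and its within-monomer phasing, mining higher-order repeats
(HORs), and dating centromeric retrotransposon (CRM) insertions. This
vignette records the models, the tunable parameters, and the design choices
behind each step.

## The biological setting

Plant centromeres are typically megabase arrays of a short tandem satellite
(here ~156–157 bp, one monomer ≈ one CENH3 nucleosome wrap). Two satellite
families that diverged by a handful of fixed differences (the CentBd/CentBs
situation: 19 SNPs and 1 single-base indel between consensuses) can occupy
the centromeres of different sub/genomes in an allopolyploid. The functional
centromere is defined epigenetically by CENH3 occupancy, measured as
log2(ChIP/Input). Gypsy-family CRM retrotransposons intersperse the arrays;
the divergence of an element's two LTRs dates its insertion.

## Monomer decomposition

`decompose_array()` segments genomic sequence into monomers of a supplied
family consensus.

* **Canonical phase.** A tandem monomer has no intrinsic start. All
  consensuses are stored in their lexicographically minimal rotation
  (`canonical_rotation()`), and the decomposition cuts every boundary at
  consensus position 0, so monomers are comparable across arrays, strands
  and genomes. The synthetic generator returns consensuses already in
  canonical rotation for the same reason — planted boundaries then coincide
  with reported ones.
* **Seeding.** Candidate regions are located by exact 12-mer matches of the
  (circular) consensus on both strands; seed clusters separated by more than
  `max_gap` start new regions. 12 is small enough that at 5% per-copy
  divergence every copy retains dozens of clean seeds, and large enough that
  random hits in flanks are negligible (expected ≈ L·156/4^12 per flank).
* **Wraparound DP.** Each region is aligned against *tandem copies* of the
  consensus by a cyclic edit-distance dynamic program (Rcpp): position L of
  the consensus wraps to position 0, and every wrap marks a monomer
  boundary. Costs are mismatch 1, indel 1, and a *junk state* that skips a
  text base for 0.45 between copies. Random DNA aligns against the consensus
  at ≈ 0.5–0.65 cost/base while monomers above ~55% identity cost less than
  0.45/base, so flanks and interspersed CRM elements are skipped rather than
  absorbed; the default reporting threshold `min_identity = 0.6` is chosen
  to sit above the skip cost. The phase of partial first/last copies is
  free.
* **Arrays.** Contiguous same-strand monomers at most `max_gap = 2000` bp
  apart share an `array_id`. 2 kb terminates arrays at LTR-element
  insertions (typical elements are much longer) while tolerating short
  internal disruptions.
* **Identity** is matched columns / total alignment columns (gaps count
  against identity) — one definition reused everywhere in the package.

`build_consensus()` recovers a consensus by majority rule over a center-star
alignment. The reference copy is chosen in two passes (modal length, then
maximal identity to the first-pass majority) so that a reference carrying an
indel cannot corrupt the column space; ties in the majority vote break by
fixed base order. At 500 copies and ≤ 5% divergence the majority vote
recovers the planted consensus exactly (verified in the tests).

## Read-based fragments

`merge_pairs()` merges mates at their best 3' overlap (minimum 10 bp,
mismatch rate ≤ 0.1, ties to the longer overlap, disagreements resolved by
base quality). The merging tool used in the original analyses is not
specified anywhere, so these defaults are the package's own; they are
conservative for 101-bp reads of 146–166-bp fragments, where the true
overlap is 36–56 bp. `filter_fragments()` keeps the inclusive 146–166 bp
window — single-monomer, CENH3-nucleosome-sized fragments.

`assign_fragments()` aligns each fragment (both strands) locally against
each consensus *doubled*, so matches across the monomer phase junction score
fully. Scoring is +1/−2 with affine gaps (open 5, extend 2), converted to an
E-value via Karlin–Altschul statistics (λ solved from the scoring scheme at
uniform base composition, K = 0.621, search space = fragment length × total
consensus length × 2 strands), with the BLAST-style cut-off E ≤ 1e-5.
Because the E-value is monotone in score, the cut-off and the best-consensus
choice do not depend on the K constant's precision.

## Diversity statistics

* `identity_to_consensus()`: end-to-end alignment of the monomer against the
  doubled consensus (free subject ends) — rotation-invariant identity.
* `count_snps_indels()`: unit-cost global alignment; SNPs = mismatch
  columns, indels = maximal gap runs. Among co-optimal alignments the DP
  minimizes gap openings with a fixed move-order tie-break, making the
  (19, 1) consensus-pair comparison deterministic.
* `duplication_proportion()` / `shared_monomer_proportion()`: "identical
  monomers" means exact string equality of the sequence as read on the
  annotated strand. The original analyses never state a similarity cut-off
  for "identical"; exact equality is the crispest predicate and is what the
  bundled brute-force oracles verify.
* `kmer_table()` counts the L−k+1 linear 5-mers per monomer on the annotated
  strand (circular counting would add k−1 wrap k-mers; linear matches the
  "within a unit repeat" reading) and row-normalizes.
* `pca_project()` mean-centers but does not variance-scale: 5-mer
  frequencies already share a scale and scaling 1024 sparse columns inflates
  noise. Up to 100 components are kept (fewer if rank-limited);
  `hca_groups()` applies Ward (`ward.D2`) clustering on Euclidean distances
  of the scores. Both choices are configurable; the source analyses name
  only "PCA" and "HCA".
* `group_compare()` is a two-sided Welch t-test; `subsample_fragments()`
  draws seeded uniform samples without replacement (the 500-fragment
  per-genome displays).

## CENH3 profiling

Coverage is binned as per-bin mean depth (`bin_coverage()`, terminal partial
bins averaged over their true width), ratios are
`log2((chip + 0.5)/(input + 0.5))` after optional library-size rescaling —
the pseudocount keeps empty bins finite and the rescaling makes the ratio
invariant to sequencing depth.

"The region of highest CENH3 intensity" is a verbal definition;
`call_centromere()` operationalizes it as threshold-and-merge: bins with
log2 ratio ≥ 1 merged across gaps ≤ 100 kb, the merged region with maximal
summed signal reported (one call per chromosome — monocentric; secondary
regions are available via `all_regions = TRUE`). For calling we use 10-kb
bins; 100-kb bins suit genome-wide overview tracks. `enrichment_level()` is
the mean centromeric ChIP depth over the genome-wide mean, width-weighted,
scale-invariant.

The centromeric repeat-cluster rule is strict on both sides: normalized
CENH3/Input ratio > 2.6 *and* genome fraction > 0.5% (a literal reading of
the published thresholds; boundary cases are pinned in the tests). Counts
are library-normalized before the ratio; whether the original used raw or
normalized counts is unstated.

`quantile_groups()` bands monomers into five equal-count groups by
decreasing occupancy or identity (five matches the published displays), ties
keeping stable input order. `metaprofile()` rescales each feature body to a
fixed number of segments and keeps flanks at native bin resolution; segment
values are exact means of the binned step function (not midpoint samples),
which is what the brute-force per-base oracle in the tests checks.
`phase_profile()` maps ChIP fragment midpoints to strand-aware offsets
within monomers and reports the argmax of a ±2-bp circular moving average —
smoothing stabilizes the peak against bin noise without shifting it.

## HOR mining

`label_monomers()` clusters monomers greedily: each joins the *first*
representative within the identity threshold (default 0.95), else founds a
new label. This is a deliberate simplification of hierarchical HOR-monomer
clustering: deterministic, linear-time, and adequate at satellite divergence
levels, but it can merge variant classes whose fixed differences are within
the noise envelope — variants separated by ≥ 12 fixed substitutions are
recovered reliably at ≤ 1% per-copy noise. `find_hors()` scans all primitive
unit lengths up to 20 for maximal tandem runs (≥ 2 copies), ranks by copy
number (ties: longer unit, then leftmost) and resolves overlaps greedily;
unit length 1 reports monomic expansions.

## CRM dynamics

`ltr_divergence()` uses the gap-excluded p-distance of a global LTR
alignment, JC69-corrected by default (−3/4·ln(1 − 4p/3)); at the young ages
relevant here (K < 0.05) the correction is nearly neutral. The clock is
`r = 1.3e-8` substitutions/site/year — the standard grass rate used by
LTR-dating pipelines; the original's rate is not printed, so absolute ages
are comparable only under this clock. `insertion_time()` is `K/(2r)`.

`crm_adjacent_identity()` splits monomers at a 5-kb adjacency window by
default ("near a CRM insertion" is not defined in the source analyses).
`ltr_density_vs_identity()` tiles 100-kb windows, requires ≥ 10 monomers per
window (mean identity is unstable below that), and reports the Pearson
correlation between LTR bp-fraction and mean monomer identity.

## The synthetic generator

`simulate_centromere()` *generates* arrays; it does not evolve them (no
unequal-crossover homogenization dynamics). It plants, in order: the
consensus or HOR-unit tiling, i.i.d. per-copy substitutions (never
reproducing the original base) and single-base indels, whole-block strand
flips (after mutation, so strand and divergence stay independent), CRM
elements whose initially identical LTRs are each mutated at
`clock_rate × age` (pairwise divergence 2rT in expectation), hypermutated
monomers within a window of each insertion, and random flanks. Defaults
follow the study conditions where stated (156-bp monomer, 101-bp paired-end
reads, 146–166-bp fragment window, two consensuses 19 SNPs + 1 indel apart)
and otherwise use values a centromere researcher would call realistic: 2%
per-copy substitution rate (matching the observed identity mode near 98%),
0.2% single-base indel rate, 8-fold ChIP enrichment, nucleosomal fragment
lengths (mean 156, sd 5, truncated to [read length, 2× read length]).

ChIP fragment midpoints are drawn with weight `fold` over the centromere,
modulated within each monomer by a von-Mises-like periodic weight
`exp(κ·cos(2π(offset − phase_offset)/L))` normalized to mean 1 (the
published phasing shows phased peaks but no functional form; κ defaults
to 3). The ChIP library is scaled so its background density matches the
Input library, making the in-centromere coverage ratio equal the configured
fold. Reads carry constant Q40 qualities and no sequencing error by default
— the error model is not the object of study.

What the generator deliberately does not emulate: homogenization gradients
along arrays, nested/fragmented TE insertions, CpG-context mutation bias,
mappability artifacts, and library GC bias. Tests passing on this generator
therefore demonstrate algorithmic correctness and statistical calibration,
not robustness to every property of real sequencing data.

## Numerical and scale choices

Coordinates are 0-based half-open everywhere (BED convention). All
simulations are seeded and byte-reproducible; test and acceptance problem
sizes (500-copy arrays for recovery, 250 + 250 fragments for two-family
separation, a ~1.2-Mb chromosome with a 1-Mb planted centromere for calling,
100 replicates for the null calibration of the flank-hypermutation test) are
the package's choice of the smallest sizes at which the sampling error of
each statistic is comfortably inside the tolerance being checked. The
interfaces are tidyverse-native — tibbles in and out, ggplot2 displays,
broom-style `tidy()`/`glance()` for the PCA — because every record type here
(monomers, fragments, bins, windows, HORs) is naturally tabular.

## Known limitations

* The decomposition DP holds a full traceback matrix; regions are bounded at
  ~600M cells (≈ 4-Mb arrays for a 156-bp consensus). Larger arrays should
  be split at seed gaps first.
* Greedy variant labelling is order-dependent by design (deterministic, but
  not an optimal clustering); closely spaced variant classes can merge.
* `assign_fragments()` E-values use ungapped Karlin–Altschul constants with
  a gapped alignment, as BLAST-style tools commonly approximate; assignment
  decisions are driven by score differences and are insensitive to this.
* One centromere call per chromosome: genuinely dicentric or highly
  fragmented signals surface only through `all_regions = TRUE`.
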