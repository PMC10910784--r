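# pancent

Tools for dissecting plant centromeres built from tandem satellite DNA, with
the two-family situation of *Brachypodium* (the ~156-bp CentBd and ~157-bp
CentBs repeats of the D and S sub/genomes) as the motivating system. The
package is aimed at researchers studying centromere sequence evolution who
have assembled centromeres, satellite consensus sequences, and CENH3
ChIP/Input sequencing — and who want reproducible, testable versions of the
standard analyses instead of one-off scripts.

## What it computes

* **Monomer decomposition.** Satellite arrays are segmented into individual
  monomers by a wraparound edit-distance dynamic program anchored on the
  family consensus: every boundary is cut at consensus position 0 (the
  lexicographically minimal rotation), so monomers are comparable across
  arrays and genomes. Random flanks and interspersed retrotransposons are
  skipped by an explicit junk state rather than absorbed into monomers.
* **Read-based satellite harvesting.** Paired-end reads are merged at their
  3' overlap, length-filtered to the single-monomer window (146–166 bp,
  inclusive), and assigned to a family consensus by local alignment against
  the doubled consensus with a Karlin–Altschul E-value cut-off (E ≤ 1e-5).
* **Diversity statistics.** Identity to the consensus over the circularly
  best phase (identity = matched columns / alignment columns), SNP + indel
  counts between consensuses from a unit-cost global alignment,
  exact-duplication proportions within and between chromosomes, and shared
  monomer proportions between sets.
* **5-mer PCA + HCA.** Each monomer/fragment becomes a 1024-dimensional
  5-mer frequency vector; mean-centered PCA (up to 100 components) followed
  by Ward hierarchical clustering classifies repeat families.
* **CENH3 enrichment.** Binned log2(ChIP/Input) tracks with pseudocount,
  centromere calling as the maximal-signal merged region, enrichment level
  (mean centromeric depth / genome-wide mean), the strict (> 2.6 ratio,
  > 0.5% genome) centromeric repeat-cluster rule, occupancy/identity
  quantile bands, metaprofiles over features, and the within-monomer phase
  profile of fragment midpoints.
* **HOR mining.** Greedy variant labelling of monomers plus a tandem scan
  for primitive repeated label tuples, ranked by copy number (unit length 1
  = monomic expansion).
* **CRM dynamics.** LTR-pair divergence (raw or JC69), insertion-time dating
  `T = K / (2r)` with the grass clock `r = 1.3e-8` subs/site/year, satellite
  identity near CRM insertions vs array interiors (Welch test), and the
  per-window LTR-density vs identity correlation.
* **Synthetic centromeres.** A fully seeded generator plants arrays with
  per-copy substitutions/indels, HOR units, strand blocks, aged CRM
  insertions with flank hypermutation, and ChIP/Input read pairs with fold
  enrichment and a phased within-monomer bias — together with the ground
  truth every recovery test needs.

## Worked example

```r
library(pancent)
library(dplyr)

pair <- synthetic_consensus_pair()          # bundled synthetic CentBd/CentBs pair
count_snps_indels(pair$sequence[1], pair$sequence[2])
#> # A tibble: 1 × 3
#>   n_snp n_indel  edit
#>   <int>   <int> <dbl>
#> 1    19       1    20

cfg <- sim_config(seed = 42, monomer_consensus = pair$sequence[1],
                  n_copies = 400, sub_rate = 0.02,
                  crm_spec = data.frame(at_copy = 200, element_length = 4000,
                                        ltr_length = 1200, age_mya = 0.5,
                                        flank_factor = 3, flank_window = 3000),
                  flank_length = 10000)
sim <- simulate_centromere(cfg)

mon <- decompose_array(sim$sequence, consensus_repeat("CentBd", pair$sequence[1]))
mon
#> # A tibble: 400 × 8
#>   chrom   start   end strand sequence           consensus_name identity array_id
#> 1 sim_chr 10000 10156 +      AAAAACTGGAGGAGATA… CentBd            0.968 sim_chr…
#> 2 sim_chr 10156 10310 +      AAAAACTGGAGGAGATA… CentBd            0.981 sim_chr…
#> ...
mean(mon$identity)
#> [1] 0.9736        # 1 - mean identity recovers the 2% mutation rate

rd   <- simulate_reads(sim)
frag <- arrange(rd$fragments, start)
len  <- unname(nchar(sim$sequence))
chip  <- bin_coverage(filter(frag, sample == "ChIP"),  2000, c(sim_chr = len))
input <- bin_coverage(filter(frag, sample == "Input"), 2000, c(sim_chr = len))
call_centromere(log2_ratio(chip, input), threshold = 1, merge_gap = 1e4)
#> # A tibble: 1 × 6
#>   chrom   start   end n_bins sum_log2 mean_log2
#> 1 sim_chr 10000 78000     34     99.2      2.92   # the planted array span

phase_profile(filter(frag, sample == "ChIP")$mid, sim$truth$monomers)
#> <pancent_phase> 49279 fragments, peak offset 81 bp   # planted at 80

cr <- sim$truth$crms
K  <- ltr_divergence(substring(sim$sequence, cr$ltr5_start + 1, cr$ltr5_end),
                     substring(sim$sequence, cr$ltr3_start + 1, cr$ltr3_end))
insertion_time(K)
#> [1] 0.4528    # planted age 0.5 Mya
```

The monomer table feeds directly into `kmer_table()` |> `pca_project()` |>
`hca_groups()` for family classification, `label_monomers()` |> `find_hors()`
for HOR structure, and `crm_adjacent_identity()` /
`ltr_density_vs_identity()` for the satellite–retrotransposon interplay.
`autoplot()`, `plot_identity_distribution()`, `plot_enrichment_track()`,
`plot_phase_profile()` and `plot_metaprofile()` draw the standard displays.

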