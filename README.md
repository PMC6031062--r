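# hicmat

Hi-C contact-matrix construction, correction and analysis in R.

Chromosome-conformation-capture (Hi-C) experiments produce paired-end reads
whose two mates mark genomic loci that were spatially close in the nucleus.
Tabulated over genomic bins, they form a symmetric **contact matrix** whose
structure encodes the folding of chromatin: a power-law decay of contacts
with genomic distance, megabase-scale **A/B compartments** (the plaid pattern
of open vs closed chromatin), self-interacting **topologically associating
domains (TADs)**, and focal contacts between anchor loci. `hicmat` implements
the computational core of this analysis for bioinformaticians who want the
pipeline as composable R functions (or a small CLI) rather than a workflow
server:

* **Genome model** — fixed-size binning and in-silico restriction digestion
  (`make_fixed_bins`, `digest_genome`, `locate_bin`).
* **Pair pipeline** — readers for SAM and 4DN `.pairs` records, a classifier
  for artifact read classes (unmapped / low-mapq / PCR duplicates /
  dangling ends / self-circles / self-ligations), matrix building and a
  mergeable QC report (`build_matrix`, `classify_pairs`, `merge_qc`).
* **Correction** — coverage diagnostics with MAD-based pruning thresholds,
  bin masking and iterative correction (ICE): multiplicative per-bin biases
  `b_i` are estimated by iterative proportional fitting so that the
  corrected matrix `W_ij / (b_i b_j)` has equal row sums
  (`coverage_diagnostics`, `mask_bins`, `ice_correct`).
* **Transforms** — distance-decay curves, observed/expected (O/E = contact
  divided by the mean contact at the same distance on the same chromosome),
  Pearson and covariance matrices, matrix comparison and inter-sample
  correlation (`distance_decay`, `obs_exp`, `pearson_and_covariance`,
  `compare_matrices`, `correlate_matrices`).
* **Compartments** — per-chromosome eigenvector tracks of the covariance of
  the O/E Pearson matrix; the sign of eigenvector 1 partitions bins into
  A/B (`ab_compartments`, `orient_track`).
* **TADs** — multi-window TAD-separation score (mean distance-normalized
  contact in a "diamond" across each bin boundary), local-minimum boundary
  calling with a depth and a rank-sum significance filter, and domain/BED
  export (`tad_separation_score`, `find_boundaries`, `write_tads`).
* **Locus tools** — virtual-4C viewpoint tracks, aggregate contact maps
  around anchor pairs, and the 45° rotation behind triangle TAD plots
  (`viewpoint`, `aggregate_contacts`, `rotate45`).
* **Synthetic Hi-C** — a fully seeded generator (`hic_truth`,
  `simulate_truth_matrix`, `simulate_pairs`, `simulate_counts`) that plants
  every one of these structures with known parameters and writes
  ground-truth sidecars, so the whole pipeline is testable offline.

Matrices travel in a plain-text container (a BED-like bin table plus a
`bin1 bin2 value` pixel table with a JSON metadata header); tracks and
intervals use bedGraph/BED. All coordinates are 0-based half-open.

## Worked example

Simulate a two-chromosome genome (2 × 2 Mb, 5-kb bins) with planted decay,
TADs, compartments, biases and artifact reads; build and inspect the matrix;
correct it; call TADs:

```r
library(hicmat)
spec <- hic_truth(seed = 42)
spec
#> synthetic Hi-C ground truth: 2 chromosome(s), 800 bins of 5000 bp
#>   alpha=1, TAD t=3, checkerboard c=0.3, bias sd(log)=0.243, seed=42

sim <- simulate_pairs(spec, 50000, seed = 42)
res <- build_matrix(sim$pairs, spec$bins, sim$frags)
res$qc
#> Hi-C pair QC report
#>   total                    50000
#>   unmapped                 1500
#>   low_mapq                 2500
#>   duplicate                2500
#>   same_fragment_dangling   2500
#>   self_circle              1000
#>   self_ligation            0
#>   valid                    40000
#>   inter_chromosomal        549
#>   intra_short_range        21244
#>   intra_long_range         18207
#>   orientation: inward 12869, outward 12091, same_strand_forward 10839, same_strand_reverse 10849
```

Every filtered category matches the generator's sidecar exactly
(`sim$sidecar$counts`). At deeper coverage the corrected matrix yields the
planted structure back:

```r
m <- simulate_counts(spec, 4e5, seed = 420)          # sampled valid contacts
corr <- ice_correct(mask_bins(m))                    # mask + balance
calls <- find_boundaries(tad_separation_score(corr$matrix))
head(calls$boundaries, 4)
#>   chrom    pos  score delta   pvalue    padj
#> 1  chr1 125000 -0.984  1.15 0.000442 0.00126
#> 2  chr1 250000 -0.744  1.11 0.000442 0.00126
#> 3  chr1 315000 -2.033  2.23 0.000442 0.00126
#> 4  chr1 375000 -0.571  1.12 0.000852 0.00200
```

`score` is the averaged TAD-separation score at the minimum (z-units),
`delta` its depth below the flanking maxima. With this seed the planted
chr1 TAD boundaries sit at bins 64, 89, 168, 243 and 336 — the call at
315 kb is bin 64 — while the remaining calls sit exactly on the planted
compartment block junctions (every 25 bins), which are genuine insulation
points of this genome. On a TAD-only genome (`comp_strength = 0`) the
caller recovers all planted boundaries with no spurious calls (see the
test suite).

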