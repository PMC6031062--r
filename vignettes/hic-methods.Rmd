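---
title: "Models and methods behind hicmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicmat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicmat)
```

This vignette explains what each stage of the package computes, why the
defaults are what they are, and what the synthetic validation does and does
not demonstrate about real data.

## Coordinates, containers and conventions

All genomic coordinates are 0-based half-open, internally and in every BED
and bedGraph file the package writes; `.pairs` input, which is 1-based by
convention, is converted on read. A contact matrix stores only the upper
triangle (`bin1 <= bin2` in global bin order). Off-diagonal pixels represent
unordered bin pairs and the diagonal is counted once, so "total counts"
equals the number of tabulated read pairs. Masked bins are never deleted:
they keep their row in the bin table (indices stay stable across the whole
pipeline) and their pixels stay in storage, but every downstream computation
excludes them. The interchange container is deliberately plain text — a bins
table and a pixel triple table with a JSON metadata header — so round trips
are bit-exact and diffable; values are printed with `%.17g`, which is
lossless for doubles.

## Read-pair classification

A Hi-C library contains, besides informative ligation products, several
artifact classes with recognizable geometric signatures on the digested
genome. After putting the two mates of each pair in canonical order (lower
(chromosome, position) first), the classifier assigns exactly one category
per pair with a fixed precedence:

1. **unmapped** — either mate unmapped;
2. **low_mapq** — either mate below `min_mapq` (default 15, a conventional
   uniqueness cut-off for short-read aligners);
3. **duplicate** — an exact repeat of an earlier canonical
   (chrom, pos, strand) × 2 key among pairs passing the mapping filters;
   the first occurrence keeps its geometric class;
4. **same_fragment_dangling** — a mate whose leading (5′) bases equal the
   dangling-end sequence, or both mates on a single restriction fragment
   not facing outward. Unligated fragments produce inward-facing
   same-fragment pairs whose reads start with the fill-in overhang, so the
   sequence signature and the geometry are two views of the same artifact
   and are reported as one class. The dangling-end sequence defaults to the
   recognition sequence itself, the right answer for blunt fill-in
   protocols; enzymes with distinct overhang chemistry can override it.
5. **self_circle** — both mates on one fragment facing outward (the
   fragment ligated to itself);
6. **self_ligation** — mates on adjacent fragments facing inward (ligation
   of a fragment to its immediate neighbour carries no spatial
   information);
7. **valid** — everything else; tabulated into the matrix at the bin pair
   of the two 5′ positions.

The precedence makes the categories a partition, so category counts always
sum to the stream size — an invariant the tests enforce. Orientation counts
(inward / outward / same-strand) are tallied over all intra-chromosomal
mapped pairs before any filtering, so their sum is also a stream-level
invariant. Same-fragment pairs on the same strand have no standard name; we
file them under `same_fragment_dangling` rather than inventing a class.
Distances of valid intra-chromosomal pairs are split at 20 kb into short-
and long-range, the conventional figure of merit for library quality.

In-silico digestion places a fragment boundary at the first base of every
(possibly overlapping) occurrence of the recognition site on the forward
strand — a blunt cut model. The true cut chemistry only matters through the
dangling-end sequence, which is configurable; modelling overhangs in the
fragment coordinates would shift every boundary by a constant without
changing any downstream classification.

## Coverage diagnostics, masking, iterative correction

Per-bin coverage (dense row sums) varies over orders of magnitude in real
data; bins at the extremes are unfixable by rescaling and must be masked.
The diagnostic suggests thresholds at median ± 3 MAD of the log coverage of
nonzero bins — a robust band that adapts to sequencing depth — and always
flags zero-coverage bins. Thresholds can be given in these MAD-score units
or in raw counts.

Iterative correction models the observed matrix as `W_ij = T_ij b_i b_j`
with a balanced true matrix `T`. Each iteration computes unmasked row sums
`s`, relative deviations `delta = s / mean(s)`, divides every pixel by
`delta_i delta_j` and accumulates `delta` into the bias estimate, stopping
when `max |delta - 1| < tol` (default `1e-5`; the max-norm matches the
per-bin convergence statement "every row is within tol of flat" and is
cheap on sparse data). Two normalizations pin down the output, which the
iteration alone leaves scale-free: the corrected matrix is rescaled to the
input total (so pre/post comparisons and distance-decay curves stay on one
scale) and the bias vector to mean 1 over unmasked bins. Correction is
genome-wide by default, matching the single-matrix tool semantics. On a
matrix that is already balanced the first iteration measures `delta = 1`
and returns immediately; on `outer(b, b)`-type planted biases the fixed
point is exact, which is what the oracle tests check.

## Distance decay, O/E and the compartment eigenvector

The expected profile is computed per chromosome, never pooled: chromosome
length sets the distance support, and pooling would confound decay with
composition. Absent pixels count as zeros in the per-distance mean — the
denominator is the full number of unmasked pairs at that distance — so
sparsity does not inflate the expectation. O/E divides each
intra-chromosomal pixel by the expected value at its distance; pixels at
distances with zero expectation are undefined and dropped, and
inter-chromosomal pixels have no distance expectation and are dropped too.

For the decay exponent we fit the log–log slope of the genome-wide curve
over 100 kb–1 Mb (20–200 bins at the 5-kb default). The lower cut matters:
the planted intensity is `(d + 1)^-alpha` in bins, whose local log–log
slope is `-alpha·d/(d+1)`, noticeably shallower than `-alpha` at single-digit
`d`; beyond ~20 bins the discreteness bias is under 5 %, while beyond the
megabase scale per-distance means get noisy on a 2-Mb test chromosome.

A/B compartments come from the eigenstructure of the correlation pattern of
O/E: per chromosome we form the dense O/E block, its Pearson correlation
matrix (pairwise exclusion of missing entries; undefined rows dropped), the
covariance of that Pearson matrix, and its eigendecomposition, ordering
eigenvectors by absolute eigenvalue with ties broken by first occurrence so
output is deterministic. Decomposing the Pearson matrix directly is
available behind `method = "pearson"`; on planted checkerboards both
recover the labels, and we default to the covariance route because the
extra correlation step sharpens block structure on noisy matrices. An
eigenvector's sign is mathematically arbitrary, so the package never
asserts which sign is "A": `orient_track` flips per chromosome against a
user-supplied guide (GC content or gene density binned to the matrix) and
flags orientations with `|r| < 0.1` as unreliable rather than guessing.

## TAD-separation score and boundary calling

Contacts are `log(1 + x)`-transformed and z-scored per genomic distance
(up to `z_depth`, default five times the largest window), which removes
both the decay and the scale of the matrix — boundary calls are invariant
under global rescaling by construction. The TAD-separation score at a bin
boundary is the mean z-value of the `w × w` diamond of contacts crossing
it; low scores mean insulation. Scores are computed at windows
`{2, 4, 6, 8, 10, 12} × bin_size` and averaged where all windows fit. The
multi-window set serves two purposes: the average is robust across TAD
sizes, and the per-window values give each candidate boundary a sample for
the significance test below — with six windows a fully separated rank-sum
comparison against the two flanking maxima (6 vs 12 values) reaches
p ≈ 4 × 10⁻⁴, enough resolution to survive per-chromosome
Benjamini–Hochberg correction at `alpha = 0.05`.

Candidates are local minima of the averaged score, strictly lower than
every neighbour within ±2 bins (plateaus take the leftmost position — a
deterministic tie-break). Two filters remove noise minima: the depth
`delta` (mean of the two flanking local maxima minus the minimum) must
reach `min_delta`, and the per-window scores at the minimum must rank
significantly below those at the flanking maxima. Any local minimum is by
construction lower than its flanks, so the rank-sum test alone separates
poorly; the depth filter carries the specificity. Its default of 1 z-unit
expresses that a genuine boundary should be at least one standard deviation
of distance-normalized contact deeper than its surroundings; on simulated
genomes (enrichment `t = 3`, 400 bins, 4 × 10⁵ contacts) this recovers all
planted boundaries with no spurious calls across seeds, while weak dips
within the per-distance variance are rejected. Consecutive surviving
boundaries delimit the exported domains; regions outside the first/last
boundary of a chromosome are intentionally not closed into domains.

## Viewpoint, aggregate maps, rotation

A viewpoint track sums, for each bin within the flank, its contacts with
the reference bin(s) — additive over multi-bin references, so the track's
total equals the reference rows' total, another tested identity. Aggregate
maps average fixed-size submatrices centred on qualifying anchor pairs;
they operate on O/E by default so that the distance decay does not swamp
the focal signal, with a raw-counts mode behind a flag. Blocks that would
cross a chromosome edge are skipped and counted rather than padded. The 45°
transform maps upper-triangle cell `(i, j)` to `x` = genomic midpoint and
`y = (j - i) · bin_size / 2`; it is a coordinate transform only — figure
composition is out of scope.

## The synthetic generator: what it emulates, what it does not

`hic_truth` fixes, from one seed, a complete ground truth: expected
intensity `A (d+1)^{-alpha}` per chromosome (default `alpha = 1`, the
canonical contact-probability exponent), multiplied by `t` (default 3)
within planted TADs (5 boundaries per chromosome, kept ≥ 20 bins apart on
the default 400-bin chromosomes), by `1 ± c` (default `c = 0.3`) for
same/opposite checkerboard compartment labels (25-bin blocks), by planted
anchor-pair enrichment (factor 3), and by log-normal per-bin biases
(`sdlog = 0.25`, a moderate real-data-like spread), with a small constant
inter-chromosomal floor. The default genome is two 2-Mb chromosomes of
5-kb bins — large enough for every structure at minutes-scale runtimes.
`simulate_counts` draws a multinomial sample of contacts from these
intensities; `simulate_pairs` emits actual read records (positions uniform
within bins) and then injects artifact pairs at fixed fractions
(duplicates 5 %, dangling ends 5 %, self-circles 2 %, unmapped 3 %,
low-mapq 5 %) with exactly the signatures the classifier tests for.
Artifacts are injected, not drawn, so the sidecar's category counts are
exact and tests can assert equality rather than distributional closeness;
valid pairs are rejection-sampled away from artifact geometries and key
collisions so no valid pair masquerades as an artifact or duplicate.

The generator does **not** emulate mapping error, chimeric reads, copy-number
variation, unmappable regions, fragment-length biases coupled to GC, or
nested/hierarchical TADs. Passing tests therefore demonstrate that the
implementations are correct against their definitions and recover planted
structure under realistic noise — not that the defaults are optimal for any
particular real library.

## Numerical choices and degenerate inputs

* Validation sizes: the validation script and tests run 400-bin chromosomes
  with 4–5 × 10⁵ contacts for structure recovery and 5 × 10⁴ read pairs for
  the classifier; oracle comparisons use ≤ 12-bin toys against brute-force
  dense reimplementations at `1e-8`.
* ICE on the planted-bias check uses a balanced base matrix (the package's
  own correction applied to an unbiased truth) multiplied by fresh seeded
  biases, so the expected fixed point is exact and the measured correlation
  isolates estimator error.
* All-zero matrices yield empty diagnostics, not errors; thresholds that
  would mask every bin are refused with the observed coverage range in the
  message; non-convergent ICE warns and returns the last iterate with its
  residual.
* Comparison ratios with zero denominators are emitted as missing and
  counted, never as infinities; depth normalization scales both matrices to
  the smaller total so comparisons are unaffected by sequencing depth.
* Chromosomes with fewer than 3 unmasked bins are skipped (with a warning)
  by the eigenvector pipeline; windows larger than a chromosome are skipped
  for that chromosome by the TAD score.
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; equal seeds give byte-identical output files.

## Known limitations

Restriction-fragment binning exposes single fragments as bins (fragment
clustering is left to `merge_bins`); balancing variants other than ICE
(e.g. Knight–Ruiz) and reproducibility scores, loop calling, hierarchical
TADs and differential-TAD testing are out of scope; the optional HDF5
matrix export is not implemented — the text container is the interchange
format. The CLI is a thin wrapper over the documented functions and adds no
semantics of its own.
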