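---
title: "Methods: block-processed extraction and aggregation of Hi-C contact maps"
author: "hicblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-processed extraction and aggregation of Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(hicblocks)
```

## The problem

Proximity-ligation assays (Hi-C, Micro-C, HiChIP) measure genome-wide pairwise
contact frequencies. Binned at a resolution of a few kilobases, a mammalian
experiment becomes a sparse symmetric matrix with 10^5–10^6 rows, stored in the
cooler dialect: an HDF5 container with a chromosome table, a bin table
(optionally carrying per-bin balancing weights), and an upper-triangle COO
pixel table `(bin1_id, bin2_id, count)` indexed by `bin1_offset`. Downstream
analyses — differential loop testing, aggregate peak analysis (APA), aggregate
domain plots, boundary pileups — rarely need the whole matrix. They need the
counts at a *list* of interactions (loop calls, domains, boundaries), usually
across many files at once, which poses two practical problems this package
addresses:

1. pulling thousands of scattered pixels or submatrices from multiple
   multi-gigabyte files without reading everything into memory, and
2. reconciling loop calls that land on slightly different pixels across
   replicates and callers before any cross-sample comparison.

## Block-processed extraction

All queries are first snapped to the file's bin grid (`snap_to_bins`): an
anchor collapses to the bin containing its start, midpoint or last base
(`anchor_point`, default `center` — loop callers emit variable anchor widths
and the midpoint is the least biased single-bin representative; exact
half-integer midpoints resolve by floor so the rule is deterministic).
`expand_pixels(buffer)` grows each pixel to a `(2*buffer+1)^2` footprint.
Footprints that would leave the chromosome are *flagged*, never clipped, so
every regular-path submatrix keeps one shape; `drop_out_of_range` removes them
with a count.

`plan_blocks` tiles the genome with square blocks of `block_span_bp` per side
and assigns each query footprint to the tile containing its upper-left corner,
enlarging a tile just enough when a footprint straddles its boundary. Each
block is then fetched *once per file* as a dense rectangle (`fetch_block`,
which mirrors the upper-triangle storage so callers never worry about
orientation) and values are scattered into the result container. Consequences:

* peak working memory is one dense block per file in flight, independent of
  the number of queries (the executor records the largest block actually
  fetched in the result's `stats`, which the tests assert against);
* results are identical for any block span and any query order, because every
  scatter writes to the row of its originating query.

The default `block_span_bp = 10 Mb` keeps a dense block at 10 kb resolution
near 1000 x 1000 doubles (~8 MB); `max_blocks = k` instead chooses the span so
the longest chromosome is covered by at most `k` blocks per axis. Queries
larger than one block raise an error instructing the user to increase the
span rather than silently splitting a footprint.

Results live in a self-describing HDF5 container (`counts`, plus a `dims` and
`offsets` index for jagged stacks, plus the serialized query table), chunked
along the interaction axis so random access to one interaction is one chunk
read. `persist`/`load_result` relocate and reopen the container without
reading counts into memory; an unknown `layout_version` is a refusal, not a
guess.

Balanced counts follow the cooler convention `raw * w[bin1] * w[bin2]`, with
the weight column name configurable (default `"weight"`). A missing weight
makes the balanced value *missing*, never zero; the `missing_policy` default
is therefore `zero` for raw queries (an absent pixel is an observed zero) and
`missing` for balanced ones (a value at a filtered bin is undefined).
Estimating balancing weights (ICE/KR/VC) is out of scope: the package exposes
exactly the weight columns present in the file.

## Diagonal filtering

`remove_short_pairs(padding)` keeps an intra-chromosomal footprint iff the gap
between its lowest column bin and highest row bin is at least `padding` bins.
The gap is measured on the bin grid — the diagonal is a bin-grid object — and
a base-pair padding argument is converted with a ceiling. With `padding = 0`
this retains exactly the footprints lying fully above the diagonal.
Inter-chromosomal pairs always survive.

## Merging redundant loop calls

Stochastic data collection assigns the same loop to slightly different pixels
across datasets. `merge_pairs` concatenates the call sets (keeping a source
label per call), snaps them to a common grid, and clusters per chromosome
pair with DBSCAN at `minPts = 2` and `eps = radius_bp`. Choices made here:

* **`minPts = 2`** means every point with a neighbour is a core point, so the
  clusters coincide exactly with the connected components of the
  at-most-`eps` graph (the property the test oracle asserts by union-find
  transitive closure), and an isolated call is never discarded as noise — it
  becomes its own singleton cluster. Dropping unreplicated calls is a
  filtering concern, not a merging one.
* **Distance metric.** The default is Manhattan distance on the snapped bin
  coordinates scaled to base pairs, which makes `radius_bp` interpretable and
  is robust to sub-bin jitter. A `metric = "chebyshev"` option exists because
  it is the natural choice when merging replicate calls with a known per-axis
  jitter `j`: two calls of one loop are always within Chebyshev distance
  `2j`, so `radius_bp = 2j * binsize` merges them deterministically, while
  loops farther than `2j + radius` bins apart on every axis can never be
  linked. Under Manhattan the same radius would fragment a loop whose
  replicate offsets land on opposite corners of the jitter box (enumerating
  all offset triples on `{-1,0,1}^2` gives a 21% fragmentation probability
  per loop at `j = 1`, radius 2 bins), so the replicate-recovery workflow and
  its tests use Chebyshev.
* **Representative selection**: `max_metric` (member maximizing a metadata
  column, ties to the first by concatenation order), `most_frequent` (modal
  pixel, ties broken by the metric when present, else first), or
  `mean_position` (member nearest the coordinate-wise mean, ties first). The
  default is `max_metric` when a metric column is given, else
  `most_frequent`. Every original call, with all metadata and its source
  label, remains retrievable through the cluster membership table.

## Loop enrichment

`calc_loop_enrichment` scores each pixel against a customizable local
background inside its `(2*buffer+1)^2` window. Foreground and background are
boolean stencils (`make_mask`): focal center, donut between two Chebyshev
radii (excluding the center row/column to avoid stripe contamination, unless
`include_axes`), center block, corner blocks, center row/column; masks
compose by union/intersection/difference/complement. The default geometry is
an 11 x 11 window (`buffer = 5`) with focal foreground and a 2–5 donut
background — the conventional APA-style annulus clear of the immediate peak.

The default score is the pseudocounted median ratio

\[
S = \frac{\mathrm{median}(\text{fg}) + 1}{\mathrm{median}(\text{bg}) + 1},
\]

recorded verbatim in the result's `score_definition`. The pseudocount guards
sparse windows (a flat window scores exactly 1, an empty one cannot divide by
zero) at the cost of compressing scores toward 1 at very low depth — the
fold-recovery test therefore runs at depths where the median window count is
at least 20. Missing (unweighted) cells are excluded from the medians; a
background left empty by missingness yields a missing score, not an error.
Significance testing and observed-over-expected normalization are
deliberately out of scope.

## Aggregation and pileups

`agg_matrices` reduces a regular submatrix stack over interactions, files or
both with `sum`, `mean` or `median`, excluding missing cells per cell and
tracking `n_contributing`. Sums and means stream from disk in chunks along
the interaction axis; medians materialize the stack (documented trade-off).

`regularize` resamples jagged stacks to a common `ndim x ndim` shape by
bilinear interpolation: cell centers of an `r x c` source map to
`u = ((t - 0.5)/ndim) * r - 0.5`, clamped to `[0, r-1]`, and the output is a
convex combination of the four nearest source cells (computed as a product of
two interpolation-weight matrices; an independent per-cell oracle in the
tests agrees to 1e-12). A source already at the target shape passes through
unchanged, and `scale_to_sum` rescales each output to its source total.
Sources thinner than 2 cells in either dimension cannot be interpolated and
are dropped with a count.

The all-in-one pileups chain the modular steps:

* `pileup_pixels` (APA): snap, expand by `buffer`, drop out-of-range
  footprints, optionally drop windows within `buffer` bins of the diagonal,
  pull, and average per file. The mean (not the sum) keeps values comparable
  across call-list sizes, and per-file outputs are kept separate.
* `pileup_domains`: each domain grows by `buffer_frac` of its width per side
  (default 0.5, so the domain occupies the middle half of the window), snaps
  outward to bins, is pulled as an on-diagonal square block, optionally
  divided by its total (`per_matrix_norm = "sum"`, the default, so deep and
  shallow domains weigh equally), regularized to `ndim` (default 100) and
  averaged.
* `pileup_boundaries`: a window of `2*(flank_bp %/% binsize) + 1` bins
  centered on the boundary bin (odd by construction, so the boundary is the
  exact center cell), averaged per file. This is a boundary-centered pileup;
  compartment-strength saddle binning is out of scope.

## The simulator

`simulate_contact_map` draws Poisson counts around a fully known intensity
surface, per chromosome:

\[
\Lambda_{ij} = \mathrm{depth}\cdot(|i-j|+1)^{-\alpha}\cdot L_{ij}\cdot
T_{ij}\cdot b_i b_j ,
\]

where each planted loop multiplies a Gaussian bump in Chebyshev radius with
peak `fold` and scale `width_bins` (placed symmetrically), each domain
multiplies `fold` on its on-diagonal block, and `b` is a positive per-bin
bias whose reciprocal is stored as the balancing weight — so balanced
expected counts are bias-free by construction, which the balancing-recovery
test checks per distance band. Counts are sampled on the upper triangle and
mirrored; all draws run under one seed threaded through every output, and the
caller's RNG state is restored afterwards. `simulate_loop_calls` emulates
replicate loop calling: each true loop appears with probability `1 - fnr`,
displaced by independent uniform integer offsets in `[-jitter, +jitter]^2`
bins, with the sampled count at the jittered pixel attached as metadata.

Defaults follow what small mammalian-genome fixtures need: decay exponent
`alpha = 1` (the classic power-law slope of intra-chromosomal contact decay),
Poisson noise rather than negative binomial (analytic simplicity;
overdispersion is an extension hook), multiplicative log-normal biases. The
simulator deliberately does *not* emulate inter-chromosomal signal,
compartment checkerboards, fragment-level reads, or overdispersion — so
passing tests demonstrate correctness of extraction, merging, scoring and
aggregation arithmetic on realistic marginal structure, not robustness to
every artefact of real Hi-C libraries.

## Problem sizes and numerical tolerances

The validation suite runs on a two-chromosome genome (5 Mb + 3 Mb at 10 kb
bins, 800 bins, ~25k pixels) with 500 random queries, 200-call merge sets
over an eps grid of 0–5 bins, and 40–60 planted loops at depths giving median
window counts above 20 — sizes chosen so every oracle (dense lookup,
union-find closure, per-cell bilinear) is exhaustively checkable while the
full suite stays interactive. Raw-count comparisons are exact integer
equality; balanced comparisons allow 1e-9 relative error (one weight
multiplication); the bilinear oracle 1e-12; stochastic recovery checks use
±10% (distance-band ratios) and ±20% (median enrichment), with expectations
computed from the noiseless \(\Lambda\), never fitted to the sample.

## Known limitations

* Only the cooler dialect is read and written; the `.hic` binary format is a
  non-goal, as is any balancing-weight estimation.
* Inter-chromosomal blocks are served by `fetch_block` and the extraction
  engine, but the simulator populates intra-chromosomal contacts only, so
  inter-chromosomal paths are exercised with empty ground truth.
* Stored arrays offer random-access slicing, not a delayed-operation algebra;
  whole-stack medians load the stack.
* DBSCAN is quadratic in the number of calls per chromosome pair — fine for
  loop-call sets (10^3–10^4), not meant for millions of points.
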