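---
title: "Mapping single-cell nucleosome-free-region landscapes with scValley"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-cell nucleosome-free-region landscapes with scValley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scValley)
```

## The problem

Single-cell MNase-seq digests the linker DNA between nucleosomes, so the
midpoint of a nucleosome-sized fragment (140–180 bp) marks a nucleosome
dyad. Around an active cis-regulatory element the dyad profile looks like
a valley — a nucleosome-free region (NFR) — flanked by phased nucleosome
peaks. The depth, width and steepness of that valley track the element's
potential for transcription-factor (TF) binding, and they differ between
cell types. scValley quantifies these valleys per cell and per TF motif,
clusters cells on the resulting matrix, and calls motifs whose sites are
significantly nucleosome-depleted.

## The model

**Piled-up vectors.** For a cell and a motif, every candidate binding-site
center contributes the fragment midpoints within ±`window` bp (default
400), binned at `bin` bp (default 1) and summed across sites into a
single vector $x$. Strand is not used: dyad counts are symmetric evidence
and the upstream/downstream statistics below are themselves symmetric, so
flipping minus-strand sites would only permute noise. This is a deliberate
simplification.

**Positioning score.** $S_i = \sum_{j=i-15}^{i+15} x_j \big/
\sum_{j=i-100}^{i+100} x_j$: the local concentration of dyads in a 31-bin
window relative to a 201-bin window, a normalised measure of positional
consistency in $[0,1]$. Bins whose 201-bin denominator is empty score 0;
bins without full support at the vector edges are undefined.

**Center-weighted score.** $CS_i = \sum_{j=-73}^{73} S_{i+j} w_j$ with the
Gaussian kernel $w_j = e^{-(j/20)^2/2}$. The kernel half-span (73 bins)
and scale (20 bins) spread evidence over roughly half a nucleosome
footprint, smoothing bin-level noise without erasing the valley.

**Dynamic center, summits, summit distance.** The dynamic center (DC) is
the minimum of $CS$ within ±`r` bins of the motif center (default 20),
absorbing small offsets between the motif match and the protected
footprint. The flanking summits are the maxima of $CS$ upstream and
downstream of the DC within `search` bp of the center (default 200,
roughly nucleosome plus linker). The summit distance is the count-weighted
mean distance of raw midpoint counts from the DC, computed independently
on $[uS, dc]$ and $[dc, dS]$ and summed:

$$SD = \frac{\sum_{i=uS}^{dc} d_i n_i}{\sum_{i=uS}^{dc} n_i} +
       \frac{\sum_{i=dc}^{dS} d_i n_i}{\sum_{i=dc}^{dS} n_i},
\qquad d_i = |i - dc|.$$

A deep, broad valley pushes dyad mass out to the summits and enlarges SD;
a filled valley pulls mass to the center and shrinks it. A single pooled
weighted mean over $[uS, dS]$ is *not* the sum of the two one-sided means;
the two-sided form is the default because the one-sided distances are the
quantities with a physical reading (distance to the upstream/downstream
nucleosome), and the pooled variant remains available via
`summitDistance(method = "pooled")` for comparison.

**Tie-breaking and edges.** Argmin/argmax ties resolve to the bin nearest
the reference point (vector center for the DC, the DC for summits), then
to the smaller index — deterministic and symmetric up to exact ties. The
window must satisfy `window/bin >= search/bin + r + 173` so that every bin
the DC and summit searches touch has a defined $CS$ (173 = kernel
half-span 73 + score support 100); the default geometry (400 ≥ 393)
satisfies this and the precondition is enforced.

**Exception tag.** A piled-up vector with fewer than 5% nonzero bins is
too sparse to support a geometry estimate; its SD is recorded as 0 and
flagged. Cells with more than 70% flagged entries, then motifs with more
than 90% flagged entries over the retained cells, are dropped (both
comparisons strict, cells first — the order matters and is fixed).

## From matrix to clusters

The cell × motif SD matrix is winsorised within each motif at the 1st and
99th percentiles (type-7 quantiles; the mildest standard limits — the
choice is configurable), exception zeros participating as genuine
"no-signal" values. Motifs are then selected by coefficient of variation,
$CV = \hat\sigma/\bar x$ with the sample standard deviation, keeping
$CV > 0.5$. Before distances are computed each motif column is z-scored so
motifs with large SD scales do not dominate; the tree method uses
Euclidean distance with Ward linkage (`ward.D2`) cut at `k`, and the graph
method a k-nearest-neighbour graph (default 15, cosine distance) with
Louvain modularity at a given resolution, seeded. Linkage and distance are
not dictated by the statistic itself; Ward/Euclidean on z-scores is the
package's documented choice. A UMAP embedding (PCA fallback below 5 cells
or when uwot is unavailable) is provided for visualisation only.

## Motif activity calls

For a unit (cell or pooled group) and a region set, $n_{center}$ counts
midpoints within ±100 bp of site centers and $n_{flank}$ those at
100–200 bp on either side (inner edge half-open, so no midpoint is
double-counted), giving the center fraction
$F = n_{center}/(n_{center}+n_{flank})$. The nucleosome-free score is
$NS = \log_2(F_b/F_t)$ against a background region set; positive values
mean the motif's centers are depleted relative to background. The default
background is the accessible-region centers themselves (downsampled to
50,000, seeded), which measures motif-specific depletion against generic
accessible chromatin; a user-supplied background overrides it. Whether the
original design used matched random regions instead is unknowable from the
method description alone, so the default is documented rather than
inferred.

Significance comes from the 2 × 2 center/flank × treatment/background
table: Fisher's exact test when any expected count is ≤ 5, otherwise
chi-square with Yates correction (the boundary is inclusive so that the
canonical skewed small table lands in the exact branch). A call is
significant iff $NS > 0.1$ **and** $p < 0.01$, both strict. Cluster-specific
motifs are then found by an upper-tail hypergeometric test on the counts
of significant cells per cluster, with BH adjustment across motifs within
each cluster; the universe is the evaluable cells per motif (cells with
defined $F$), not all cells — the alternative would silently count
no-data cells as negatives.

## Evaluation harness

Predicted clusters are matched to truth classes by the Hungarian
assignment maximising the confusion-matrix diagonal (rectangular cases are
zero-padded to square). Overall accuracy is the matched diagonal fraction;
Cohen's kappa corrects it for chance agreement. The robustness protocol
stratified-samples cells at a class ratio (the largest sample attainable
at that ratio, shrunk by a `fraction` of 0.8 so iterations differ), runs
the full filter→winsorise→select→cluster chain per iteration, and sums the
matched confusion matrices element-wise; accuracy and kappa are reported
on the aggregate matrix (per-iteration values are kept for reference).
Accuracy is computed over the cells surviving QC in each iteration.

## The synthetic generator

`simulateScenario()` plants a ground-truthed scenario on a virtual genome:
non-overlapping site centers assigned to motifs at random, each
surrounded by a nucleosome array. A fragment attributed to a site falls in
the valley interior (uniform over ±half-width) with probability
$1 - depth$, otherwise on an array dyad at ±(half-width + k·180 bp) with
10 bp Gaussian jitter; a `noiseFraction` of fragments is uniform over the
genome. Each cell type carries `floor(nMotifs/(nTypes+1))` signature
motifs at depth 0.8 / half-width 150 bp, all other pairs sitting at depth
0.1 / half-width 80 bp (a depth contrast of 0.7). Defaults — 3 types × 50
cells, 20 motifs × 50 sites, 2000 fragments per cell, 10% noise — describe
the sparse single-cell regime the QC thresholds were designed for; the
jitter matches the ±15-bin positioning window so summits are detectable
but not trivial. `expectedNS()` integrates the mixture analytically as a
target for parameter-recovery tests.

What the generator does *not* emulate: MNase digestion bias, GC bias,
chromosome structure, overlapping regulatory elements, or
chromatin-state heterogeneity within a type. Passing tests therefore
demonstrate correctness of the statistics and recoverability of a planted
signal, not performance on real tissue.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED); fragment length is
  `end − start`; length bounds (140–180 mnase, 147–294 atac) are closed.
* Midpoints and site centers of even-length intervals take the floor of
  the mean — one deterministic convention applied everywhere.
* Duplicate fragments are retained; identical (chrom, center, strand)
  motif hits are deduplicated; overlapping same-strand hits are kept.
* Zero-count sides of the summit distance contribute 0; a zero row or
  column in the 2 × 2 table yields p = 1 with a degenerate flag; a
  clustering with all mass in one matched cell has kappa 1 if accuracy is
  1 and 0 otherwise, flagged.
* Scan thresholds: the log-odds score cutoff is computed by exact dynamic
  programming over the discretised (1/1000) score distribution under the
  background so that a random background window passes with probability
  ≤ the match p-value (default 1e-4, pseudocount 0.8). Ambiguous bases
  take the column-minimum score, never favouring a match. Precomputed hit
  BEDs bypass scanning and are the recommended route for parity with
  external scanners.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run the full pipeline on the
default synthetic conditions (150 cells, 20 motifs, 1000 sites, ~300k
fragments), a 10-iteration subsampling protocol and 10 replicate
simulations; unit tests use smaller scenarios (tens of cells, hundreds of
sites). These sizes were chosen to exercise every code path at
single-core scale while keeping the whole suite in the minutes range.

## Known limitations

* Strand-aware flipping of piled vectors is deliberately not performed.
* The CV printed in the original method description reduces to zero as
  written; the package implements the coefficient of variation
  (sd/mean), the only reading under which a variability filter selects
  variable motifs.
* Whether site-level vectors with no local coverage should be excluded
  before summing is unspecified; all sites are summed.
* The hypergeometric universe uses evaluable cells per motif; the
  all-cells alternative would be slightly more conservative.
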