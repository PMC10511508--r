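---
title: "Calling single-cell copy-number alterations from scATAC-seq counts"
author: "cnatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling single-cell copy-number alterations from scATAC-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnatac)
```

## The model

Single-cell ATAC-seq fragment counts over large genomic windows reflect two
things at once: chromatin accessibility and the number of DNA copies
underneath. At a 100-kb scale, accessibility averages out enough that the
per-bin fragment count of a single cell is approximately proportional to
local copy number: a 3-copy region carries about 1.5x, a 1-copy region
about 0.5x, the diploid rate. `cnatac` exploits this to call per-cell copy
states (loss / normal / gain) without a matched euploid reference.

The pipeline, in order:

1. **Binning.** The genome is cut into fixed-width windows (default
   100,000 bp). Trailing partial windows are dropped: the segmentation step
   compares count *distributions* across bins, and bins of unequal width
   would have systematically different counts. Mitochondrial and
   non-canonical contigs are excluded by default.
2. **Filtering.** Blacklisted regions are removed first, then cells with
   fewer than `min_frags` total fragments, then bins with zero counts in
   strictly more than `zero_frac` (default 0.85) of the remaining cells.
   This order is fixed: the zero-bin fraction is only meaningful after
   low-coverage cells are gone.
3. **GC correction.** Per cell, counts are regressed on bin GC content with
   LOESS (`span = 0.75`) and rescaled by `mean(x) / fit(gc)`, which is
   mean-preserving by construction up to fit error. Fitted values are
   floored at a small epsilon and the per-bin correction factors clipped to
   [0.2, 5] so that sparse GC extremes cannot blow up single bins.
4. **Segmentation.** Per cell and chromosome, iterative binary segmentation:
   every admissible split of every open segment is scored by the two-sample
   Anderson–Darling (AD) distance between the left and right count
   distributions, and the globally strongest split is accepted at each
   iteration until `k_max` (default 15) breakpoints per chromosome are
   found or nothing is splittable. The greedy-global order spends the
   breakpoint budget on the strongest signals first.
5. **Pruning.** Per cell, breakpoints with an AD distance strictly below
   the mean AD of all of that cell's breakpoints (computed genome-wide,
   before any removal) are discarded.
6. **State assignment.** Each resulting segment gets the 10%-trimmed mean
   of its bin counts. Segments whose z-score — relative to the mean and
   standard deviation of the cell's segment trimmed means — lies in
   [-1, 1] are collapsed to the cell's genome-wide trimmed mean. The state
   is then the rounded fold change over the genome-wide mean: 0 is loss, 1
   normal, 2 or more gain (a single gain state; amplification levels are
   not quantified).

Cells are finally clustered on their 0/1/2 state rows with Euclidean
distance and Ward linkage to expose karyotype clones.

## The Anderson–Darling distance with ties

Binned counts are small integers, so ties dominate and the textbook
continuous two-sample AD statistic does not apply directly. `ad_distance`
evaluates the discrete form over the pooled distinct values $z_j$ with
multiplicities $l_j$,

$$A^2 = \frac{nm}{N} \sum_{j : H_j < 1}
  \frac{\{F_n(z_j) - G_m(z_j)\}^2}{H_N(z_j)\,\{1 - H_N(z_j)\}}
  \cdot \frac{l_j}{N},$$

with $F_n$, $G_m$, $H_N$ the right-continuous empirical distribution
functions of the two segments and their pool. The top pooled point, where
$H_N = 1$, is degenerate and excluded. Two properties make this the right
discrete form: it reduces *exactly* to the classical continuous statistic
when all values are distinct, and it is zero if and only if the two sides
are identical as multisets. (A midrank variant was considered and rejected:
it disagrees with the continuous statistic even on tie-free data.) The
implementation is vectorized over all split points of a segment — the
pooled values are shared across splits, only the left-side cumulative
counts change — and is checked in the test suite against a deliberately
naive per-value loop.

Segmentation runs on GC-corrected counts rounded to the nearest integer:
the EDF-based distance tolerates reals, but rounding keeps tie handling
stable and reproducible.

## Numerical conventions

* Coordinates are 0-based half-open (BED convention) everywhere, including
  fragment files; a fragment is assigned to the single bin containing its
  midpoint, so each molecule is counted once.
* Split ties in `best_split` go to the smallest index; cells are ordered by
  sorted barcode; clone labels are contiguous integers in order of first
  appearance — all outputs are byte-reproducible for fixed seeds.
* Fold changes are rounded half-away-from-zero (1.5 becomes 2, a gain),
  a fixed rule chosen for cross-platform reproducibility.
* The trimmed mean drops `floor(trim * n)` values from each end of the
  sorted vector; degenerate cases fall back to the plain mean.
* GC content uses the non-N denominator; bins that are mostly N are
  dropped.

## The synthetic-data generator

`simulate_counts` emulates exactly the features the caller relies on:
clone-structured copy states in {1, 2, 3} on a diploid baseline, Poisson
emission with per-cell log-normal depth factors
(`d_c ~ LogNormal(0, 0.15)`), and a smooth multiplicative GC bias
(quadratic in GC, normalized to mean one). `write_fragments` serializes a
simulated matrix as a 10x-style fragments file whose round-trip through
`count_fragments` is exact, and `downsample_counts` applies binomial
thinning for robustness studies.

The benchmark configuration (`reference_sim`) is 200 cells, two chromosomes
of 500 100-kb bins, 10 reads per diploid bin, and two equal clones, each
carrying six private 60-bin events — three losses and three gains,
alternating across the chromosomes. Gains and losses balance within every
cell, so the genome-wide mean stays at the diploid level, and the two
clones' loci are disjoint, so every event is informative about clone
identity. Problem sizes throughout the tests (30–200 cells, hundreds of
bins) were chosen as the smallest at which the law-of-large-numbers
behaviour of the benchmarked quantities is stable.

What the generator does *not* model: Tn5 insertion-site structure, peak
landscapes, accessibility differences between cell states, doublets, or
overdispersion beyond the log-normal depth factor. Passing the synthetic
benchmarks therefore demonstrates the statistical machinery (segmentation,
pruning, state assignment, evaluation) under the proportionality
assumption, not robustness to every artifact of real chromatin data.

## A knife-edge property of fold-change rounding

One behaviour of the state-assignment rule deserves explicit documentation.
Under pure proportionality the *expected* fold ratios of 1-copy and 3-copy
segments are exactly 0.5 and 1.5 — precisely the rounding boundaries that
separate loss from normal and normal from gain. A single cell's trimmed
segment mean fluctuates around these boundaries (about ±3% for a 60-bin
segment at 10 reads per bin), so an individual cell calls any given true
event with probability only ~0.4–0.6. Moreover the direction is coupled
within a cell: the shared denominator (the genome-wide trimmed mean) sits
in a window only ~0.5% wide between the two boundaries, so most cells
preferentially call *either* their losses *or* their gains, depending on
which side of the window their genome mean lands.

Two practical consequences follow. First, copy-number concordance should
be assessed on pseudo-bulk profiles (as `pseudobulk` + `classify_profile`
+ `prf1` do), where per-cell fluctuations average out: the reference
benchmark reaches per-state F1 above 0.99 there. Second, clone clustering
degrades gracefully rather than failing: cells that happen to call one or
no events are ambiguous, and with six informative events per cell the Ward
clustering recovers the two reference clones with ARI around 0.85–0.95
depending on the random draw. Heavier aneuploidy does not help — it skews
the genome-wide trimmed mean, which suppresses one call direction entirely
and also erases small events during pruning (a small event's AD distance
falls below the genome-wide mean AD when large events coexist in the same
cell). This is a property of the published state-assignment rule itself,
faithfully reproduced, not an implementation artifact.

## Evaluation choices

* Pseudo-bulk profiles use the 1/2/3 encoding (loss/normal/gain averaged
  over cells), so an all-normal bin scores exactly 2.
* `profile_mse` defaults to the conventional `sum((a-b)^2)/N`; the
  `per_bin_squared` flag divides by `N^2` instead for literal
  reproduction of reports that normalize that way.
* `standardize_profile` centers to mean 0 and scales by the population
  (1/N) standard deviation, making standardization idempotent.
* Cross-modality state comparison is threshold-based: `classify_profile`
  calls bins above `c_high` gain and below `c_low` loss. Because the right
  thresholds depend on clone penetrance, `scan_thresholds` reports the
  maximum per-state F1 over a grid of threshold pairs — the standard way
  such profile comparisons are summarized.
* Retention under downsampling (`concordance_vs_reference`) restricts both
  matrices to common cells and bins and reports, per reference state, the
  fraction of entries that kept their state. At 50% depth the reference
  benchmark retains normal calls best (≈0.93) and loss/gain calls at
  ≈0.6 — the qualitative ordering expected when shallower data pushes
  fold ratios back toward the normal band.

## Known limitations

* Whole-genome duplications and deletions are invisible: they scale every
  bin and the genome-wide mean together, leaving all fold changes at 1.
* Copy numbers beyond the three states are not quantified.
* Only flat dendrogram cuts are automated for clone detection; nested
  sub-clone labels require manual inspection of the tree.
* The breakpoint budget `k_max` doubles as an implicit stopping rule; the
  pruning step assumes the true number of breakpoints per chromosome is
  well below it.
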