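---
title: "Methods: calling and spatially mapping rare quiescent cancer cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and spatially mapping rare quiescent cancer cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qccmap)
```

## The problem

Quiescent cancer cells (QCCs) are a rare, chemotherapy-resistant
subpopulation identifiable in multiplexed immunofluorescence by a joint
three-marker phenotype: low cytoplasmic pan-AKT, low nuclear H3K9me2, high
cytoplasmic HES1. Two questions drive the pipeline: *how many* QCCs does a
tissue section contain (QCC-P, QCC-D), and *are they spatially clustered*
(QCC-CI)? The raw input is a per-cell table exported from tissue/cell
segmentation software — we consume its output and never touch pixels.

## Quality filtering

Fields of view with under 1% tumor component or over 70% technical artifacts
(tissue folds, bubbles, tissue loss) are excluded together with their cells.
The inequalities are strict on both sides — a FOV at exactly 1% tumor or
exactly 70% artifact is kept — reading the published rule literally.
Exclusion is applied per FOV (whether the original criteria were evaluated
per multispectral image or per region of interest is not documented; per-FOV
is the finest granularity available in the data model). Excluded FOV
metadata is retained so maps can gray out the dropped footprints.

## Relative thresholding

The markers show continuous intensity distributions without a natural
cutoff, and absolute intensities are not comparable across sections because
staining batches rescale the signal. The working definition is therefore
*relative*: with threshold fraction $t$ (default $0.25$), a tumor cell is a
QCC iff it lies in the bottom $t$ of pan-AKT, the bottom $t$ of H3K9me2 and
the top $t$ of HES1, each computed over the tumor cells of the same section.

The published description ("top 25% of values") names no quantile estimator
or tie rule. We adopt a **rank-based** definition: sort ascending with ties
broken by `(intensity, cell_id)`; direction *low* flags ranks
$1 \dots \lceil tN \rceil$, direction *high* the top $\lceil tN \rceil$
ranks. Consequences we rely on (and test):

* exactly $\lceil tN \rceil$ cells qualify per marker, so
  $|\mathrm{QCC}| \le \lceil tN \rceil$;
* calls are invariant under any strictly increasing per-marker, per-section
  transform — in particular multiplicative batch scaling — which is the
  computational content of preferring relative over absolute thresholds;
* rank sets are nested in $t$, so QCC-P is monotone along the
  $\{0.25, 0.33, 0.50\}$ sweep;
* absolute mode with cutoffs set to the realized rank-boundary intensities
  reproduces the relative call exactly (internal consistency oracle, exact
  for distinct values; ties at the boundary can enlarge the absolute set).

Percentiles are computed over tumor cells only — QCCs are defined among
*cancer* cells — with a flag to widen the reference population if an export
lacks reliable tissue classes. With three markers carrying no class
information, independence of the ranks gives the expected
$\mathrm{QCC\!-\!P} \approx t^3$ ($\approx 0.0156$ at $t = 0.25$), a law the
tests verify at $N = 10{,}000$.

## Digital tumor maps

Each ×20 tile has local pixel coordinates; the whole-section map translates
them by the tile origin derived from the grid position:
$x = \mathrm{col} \cdot (w - \mathrm{overlap}) + x_\mathrm{local}$ and
likewise for $y$ (0-based grid, y down, default 1392×1040 px tiles, overlap
0 — the scan geometry is not published, so it is an explicit, testable
parameter rather than instrument metadata). Stitching is a rigid translation
per tile; pairwise within-tile distances are preserved exactly. Sections are
"stacked" in 3D only by assigning a z-rank — no image registration is
attempted. Rendering writes plain SVG text (QCC red, other cancer cells
blue, stroma pale gray dots, excluded footprints gray rectangles) so output
is byte-deterministic and glyphs are countable by the tests.

## The cluster index and its null

For a focal QCC, candidate neighbors are the *tumor* cells (both classes,
never stroma, focal excluded) within ±`window` coordinate units on **each
axis** (a Chebyshev box, default 500 in map pixel units — the published
"coordinate units" are not defined further, so the window is a parameter).
If fewer than `k` candidates exist the focal cell is **discarded**;
otherwise its score is the fraction of QCCs among the `k` nearest by
Euclidean distance (default `k = 100`; distance ties broken by `cell_id`).
The section's QCC-CI is the mean score over retained focal QCCs; all-focals
discarded yields an explicitly *undefined* index, distinct from the
zero-QCC error.

Significance: draw `B = 1000` uniform random sets of $n_\mathrm{QCC}$ tumor
cells from the same section geometry, score each identically, and report the
one-sided add-one empirical p-value
$p = (1 + \#\{s \ge \mathrm{obs}\}) / (B_\mathrm{defined} + 1)$, so $p > 0$
always. One-sided "$\ge$" is the natural test for clustering; the published
account does not state sidedness or the estimator, and a two-sided variant
would simply double small p here. Replicates whose pseudo-focals are all
discarded are excluded from the denominator and counted (the published rule
is silent; with realistic geometry this never triggers). Under exchangeable
labels in a dense field the per-focal score has hypergeometric mean
$(q-1)/(N-1)$, which anchors the calibration tests. `exact_null` enumerates
all $\binom{N}{n_\mathrm{QCC}}$ labelings on small maps as the independent
oracle for the Monte-Carlo engine, and a full-distance-matrix implementation
in the test helpers is the oracle for the windowed k-NN path.

## Cohort statistics

Group comparisons use the classical unpaired t-test (pooled variance by
default — the published analysis does not state its variance assumption —
Welch by flag), Pearson correlation with validation, and no multiplicity
correction (none was applied originally). The post-hoc power computation
uses the normal approximation with noncentrality $\Delta/\mathrm{SE}$:
one-sided power $\Phi(\Delta/\mathrm{SE} - z_\alpha)$. A printed
"$0.567 \pm 0.25$" is ambiguous between an SD and an SE of the difference;
only the SE reading with a one-sided $\alpha = 0.05$ reproduces the
published power of 0.73 ($\Phi(2.268 - 1.645) = 0.733$; the SD reading gives
$\approx 0.99$ and the two-sided SE reading $\approx 0.62$), so that is the
default, with both readings available via `dispersion` and `sided`.

## What the synthetic generator does (and does not) emulate

Defaults describe one "stated world": a 3×3 grid of 1392×1040 px tiles, 1000
tumor cells, 30% stroma admixture, 5% ground-truth QCC fraction.

* **Spatial**: `csr` places cells uniformly with i.i.d. Bernoulli labels
  (the null); `thomas` places QCCs as Gaussian offspring (sd `sigma`,
  default 2% of field width — tight clusters) of uniform parents, the
  alternative encoding "QCCs cluster". Parent positions can be reused across
  sections to emulate contiguous sections.
* **Intensities**: class-conditional log-normals (positivity plus naturally
  multiplicative batch effects; no distribution is published). The default
  separation is 4 `sdlog` units — strong but imperfect, so percentile
  calling recovers ≥ 90% of ground truth at 5% prevalence without being a
  tautology.
* **Batch effects**: per-marker multiplicative scale factors, the mechanism
  that breaks absolute thresholds while leaving relative calls untouched.

Not emulated: segmentation errors, spatially structured staining gradients
within a section, intensity correlation between markers within a cell, and
cell-density gradients between tumor regions. A green calibration test
therefore establishes correctness of the statistics under the stated model,
not robustness to those artifacts.

## Numerical and design choices

* Determinism everywhere: rank tie-breaks by `cell_id`, k-NN distance ties
  by `cell_id`, seeded permutation draws that restore the caller's RNG
  state, SVG output byte-stable.
* The k-NN structure over tumor cells is label-free, so it is computed once
  per map (O(N²) windowed scan in C++) and shared by the observed statistic
  and all permutation replicates, making 1000 permutations essentially free.
* Degenerate inputs are explicit: zero tumor cells error in `qcc_percentage`;
  zero QCCs error in `qcc_ci`; all-focals-discarded is an undefined index;
  zero pooled variance in the t-test is flagged rather than returning NaN.
* The cohort-detection example from the generator's contract (two groups at
  QCC fractions 0.02 vs 0.06, 10+16 sections, 100 replicates) runs at
  reduced scale in the routine tests (10 replicates, 5+8 sections of 500
  cells) purely for runtime; the standardized effect is so large that the
  detection rate is indistinguishable from 1 at either scale.

## Limitations

The package consumes segmentation output as ground truth; misclassification
of tumor/stroma propagates directly into both the reference population and
the neighbor sets. The ±window/k discard rule censors QCCs near section
edges and in sparse regions, so QCC-CI is a statement about QCCs in
sufficiently dense neighborhoods. Patient-level results from the motivating
study (post-treatment QCC-P increases, specific correlation coefficients)
depend on unreleased clinical data and are deliberately not reproduced;
the synthetic cohort only emulates their design.
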