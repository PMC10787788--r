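---
title: "Self-supervised cell segmentation for subcellular spatial transcriptomics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised cell segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Imaging-based subcellular spatial transcriptomics (SST) platforms (Xenium,
CosMx, MERSCOPE, Stereo-seq) record the position of individual transcripts at
sub-micron resolution, but assigning transcripts to *cells* requires a cell
body segmentation, and no ground truth exists at pixel level. Nuclei can be
segmented reliably from DAPI, yet most cytoplasmic transcripts fall outside
nuclei, and naive fixes (fixed-radius dilation, Voronoi expansion) produce
cells with wrong sizes, wrong shapes (everything round), and contaminated
expression profiles.

`sstseg` trains a segmentation network with no manual labels. The supervision
is assembled from the data itself plus prior biological knowledge: where
nuclei are, how far a cell of a given type plausibly extends, which genes a
cell of that type should (positive markers) and should not (negative markers)
express. A five-category evaluation suite and a synthetic data generator with
exact ground truth complete the package.

## Data model

Detected transcripts (columns `x`, `y`, `gene`, optional phred-scaled `qv`)
are quality-filtered (records with `qv` strictly below 20 are removed, as is
standard for Xenium; names containing control patterns like `"NegPrb"` or
`"Blank-"` are dropped) and rasterised onto a pixel grid: the expression map
is an `H x W x n_genes` array of counts; pixel `(i, j)` covers the half-open
unit square, positions are binned by floor. The nuclei instance mask is taken
as given input (any upstream nuclei segmenter works). A reference profile
(cell type x gene mean expression, e.g. aggregated from an atlas) supplies
the cell-type knowledge, together with a user-declared list of *elongated*
cell types (e.g. fibroblasts and smooth muscle cells).

## Nucleus typing and expansion masks

Each nucleus is typed by the Spearman correlation between its in-nucleus
expression vector and each reference row (argmax; average ranks on ties,
name-order tie break; zero-variance vectors fall back to an untyped round
class). An ellipse is fitted to each nucleus by second-order moments
(axis length = 4 sqrt(eigenvalue)), giving eccentricity
`ecc = sqrt(1 - b^2/a^2)` and an orientation.

The *expansion mask* `e_c` encodes how far a cell may plausibly extend:

* non-elongated types: one dilation of the nucleus with a disc inscribed in
  a 20 x 20 pixel window;
* elongated types: dilation with a rotated elliptical kernel whose horizontal
  length is `l_h = alpha * ecc * l_t` (alpha = 0.9, total length l_t = 60 px)
  and vertical length `l_v = l_t - l_h`, floored at `l_vm = 3` px, rotated to
  the nucleus orientation. `l_h` is floored at 1 px first so the two lengths
  still sum to `l_t`.

These constants are tissue-scale quantities in pixels (about 1 micron per
pixel); they are the defaults of the published method and are kept fixed
across datasets.

## Markers

For training, each type's genes are ranked by a differential score — mean
`log1p` expression in the type minus the mean over the other types — and the
top and bottom `ceiling(0.10 * n_genes)` genes form the positive and negative
candidates (ties broken by gene name). Positive candidates shared by at least
a third of the types are removed from every set; sharing additionally
requires at least two types, so the rule remains meaningful for small type
panels. The evaluation variant uses a strict "more than 25% of types" rule.
Per cell, marker maps `m_pos`, `m_neg` are binary maps of pixels carrying
any marker transcript, masked by `e_c` (markers far from the cell are
irrelevant) and dilated 3 x 3 (neighbouring pixels likely share the cell).

## Model

The backbone is pluggable behind a registry; the reference backbone is a
small three-level encoder-decoder (1x1 input projection, 3x3 convolutions,
2x2 mean pooling, nearest-neighbour upsampling, skip concatenations, 16
channels) written directly in R with hand-derived backward passes. Each cell
of a 48 x 48 patch is one batch element: the input is the shared expression
patch concatenated with that cell's binary nucleus mask — the network's
published input reshaping places cells in the batch dimension, but without a
per-cell conditioning channel all cells of a patch would receive identical
predictions, so the nucleus channel is the per-cell signal. Softmax over two
output channels yields per-cell foreground probabilities `q`.

At inference, per-pixel labels come from the argmax over each cell's
foreground probability and the *mean* background probability across cells;
ties go to background, then the lowest cell id.

## Losses

Six losses are combined with weights all fixed at 1:

* **Nuclei encapsulation** — binary cross-entropy between each cell's
  nucleus mask and its predicted foreground.
* **Cell calling** — cross-entropy against the expansion mask `e_c`,
  averaged over the `M` cells of the patch; grows cells to plausible,
  type-shaped extents.
* **Over-segmentation** — `p_nuc = sum sigmoid(q * x_nuc - 0.5)`,
  `p_cyto = sum sigmoid(q * (1 - x_nuc) - 0.5)`; the loss is
  `mean(p_cyto - p_nuc)` over cells when the total excess is positive, else
  exactly 0 (the hinge is applied to the total). Counters the size-growing
  pressure of cell calling.
* **Overlap** — per pixel `-(1 - x_nuc) + sum_c sigmoid(q_c (1 - x_nuc) -
  0.5)` with `x_nuc` the union of nuclei, summed and divided by `M h w`,
  hinged at 0; penalises several cells claiming one pixel.
* **Positive marker** — cross-entropy against `m_pos`.
* **Negative marker** — `sum sigmoid(q * m_neg - 0.5) / M`. Non-marker
  pixels contribute a constant `sigmoid(-0.5)` floor with zero gradient;
  this offset is kept verbatim (it shifts the value, not the optimisation).

### Loss scales (a deliberate design choice)

The published equations state pixel *sums* for the over-segmentation,
overlap, and negative-marker losses (with explicit `1/M` and `1/(M h w)`
normalisations "to aid smooth training") but leave the reduction of the
three cross-entropy losses unstated. The choice matters enormously: if the
cross-entropies are per-pixel means while over-segmentation is a pixel sum,
the latter's per-pixel gradient is larger by roughly the patch area (about
2300x), and training collapses to empty predictions — we verified this
empirically across learning rates and schedules (the raw prediction reaches
zero foreground pixels and stays there).

The loss system's intended mechanics are explicit in its design: cell
calling *grows* cells, over-segmentation *counters* it. For that balance to
exist the two must act on commensurate scales. The package therefore trains
with the cell-calling and positive-marker cross-entropies at pixel-*sum*
scale and nuclei encapsulation at pixel-*mean* scale: the expansion and
marker targets are the size-setting signals, balanced against the
over-segmentation and negative-marker sums, while encapsulation acts as a
gentle nucleus-anchoring regulariser that must not fight the expansion ring
pixel for pixel (its target is 0 exactly where cell calling's is 1). All
`lambda` weights remain 1.0. The exported loss functions default to the
patch-size-invariant mean reduction and take a `reduction` argument, so both
conventions are first-class and testable; the closed forms (ln 2 at uniform
0.5 predictions, the hinge identities) hold for the default.

On the synthetic study conditions this convention takes the end-to-end mean
IoU from 0.35 (nucleus-collapsed) to about 0.64 at 300 training steps (0.78
at 600) against ground truth, versus 0.48 for a 3 x 3 nuclei-dilation
baseline.

## Training

Adam (first/second moments 0.9/0.999, weight decay 1e-4) on one patch per
step, the patch's cells forming the effective batch; raw counts, no input
normalisation; He initialisation. Patches come only from the primary
(non-overlapping) grid; each draw applies one of the 8 dihedral
augmentations (rotations by multiples of 90 degrees, optional flip)
uniformly — the published description names flips and rotations without
probabilities, and the uniform choice over the 8 distinct symmetries is the
natural completion. A single seed controls weight initialisation (first)
and the stream (shuffling, then augmentation). When the dataset has fewer
patches than iterations the stream cycles with per-epoch reshuffling. The
reference schedule is 4000 iterations at learning rate 1e-5 for a full-size
backbone; for the desk-scale reference backbone the package's examples and
tests use 300 steps at 1e-3 — the small-network equivalent chosen once, up
front (Adam step sizes trade off directly against network depth and
iteration count).

## Inference and post-processing

Both patch grids (the second offset by half a patch in each axis) are
predicted; per pixel the label comes from the patch whose centre is nearest
(Euclidean; ties to the primary grid). The published method combines the two
grids "without additional operations", leaving the rule open — nearest
centre is deterministic and minimises boundary artefacts. Each cell is then
refined: closing with a disc in a 5 x 5 window (two dilations, two
erosions), keep the connected component with the largest nucleus overlap,
fill its holes (8-connected background), union the nucleus back in.
Components are 4-connected, holes 8-connected. After reassembly, nucleus
pixels always belong to their own cell, contested pixels go to the nearest
nucleus centroid, and each cell keeps the component containing its nucleus,
so every final cell is one connected component containing its whole nucleus.
Transcripts are then counted into the cell whose mask covers their pixel,
yielding the gene-cell matrix.

## Evaluation suite

Five categories: (A) baseline characteristics — cell counts, proportion of
transcripts assigned, per-cell counts/genes/area/density, and eight shape
descriptors (area; elongation = oriented-bounding-box width/height;
circularity `4 pi A / P_convex^2`; sphericity = max-inscribed over
min-enclosing circle radius; compactness `4 pi A / P_cell^2`; convexity
`P_convex / P_cell`; eccentricity = minor/major moment-ellipse axes;
solidity `A / A_convex`). Masks are converted to marching-squares contour
polygons so rasterised discs converge to the analytic identities (all
ratios 1 for a circle; elongation 1 for a square). The bounding box is the
oriented minimum-area rectangle by default (axis-aligned would punish
rotated elongated cells); `bbox = "axis"` is available. (B) expression
purity — per-cell top/bottom-decile gene sets scored against the
reference marker sets (precision/recall/F1), combined as
`purityF1 = 2 (1 - F1_neg) F1_pos / (1 - F1_neg + F1_pos)`, plus Pearson
concordance of per-type mean log-normalised expression (scale factor 1e4)
with the reference. (C) spatial diversity — Shannon entropy (natural log)
of regional type composition against the coefficient of variation of cell
characteristics, correlated across regions (default grid about 10 regions
per axis; regions with fewer than 3 cells are excluded from CVs).
(D) neighbour contamination — the fraction of type-A cells expressing a
type-B negative marker, binned by distance to the nearest type-B cell.
(E) replicability — per-type means of the baseline characteristics
correlated between replicates.

## Synthetic data generator

The generator defines the study conditions: a 256 x 256 px image, 50
non-overlapping elliptical cells of three types (one elongated),
eccentricity drawn from [0.85, 0.98] for elongated and [0, 0.6] for round
types, mean cell area 500 px^2 (so the fixed 20-px and 60-px expansion
scales are tissue-realistic), concentric nuclei at 35% of cell area,
Poisson(200) transcripts per cell sampled from the type's profile (a
disjoint marker block per type enriched 5-fold, then renormalised),
positions uniform within the cell, plus uniform background noise at 0.001
transcripts per pixel. Everything is deterministic given the seed.

What it does *not* emulate: optical blur and z-stack effects, platform
noise (crosstalk, misassignment), irregular non-elliptical cell shapes,
density gradients, or cell-type-dependent expression depth. Passing tests
on this generator therefore demonstrate the pipeline's mechanics —
conservation, geometry, typing, loss behaviour, recovery under the model's
own assumptions — not segmentation accuracy on real tissue.

## Numerical choices

Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logs (clipped pixels
carry no gradient). The hinge conditions are evaluated on totals, read
literally from the published forms. Percentile counts use
`ceiling(fraction * n_genes)` with gene-name tie breaks. The minimum
enclosing circle uses a shuffled incremental algorithm; the maximum
inscribed circle a coarse interior grid refined by Nelder-Mead on the
signed boundary distance. Sub-pixel transcript coordinates are floor-binned
(the convention is unstated upstream; floor with half-open pixels is this
package's choice, applied consistently in the generator and the rasteriser).

## Known limitations

The reference backbone is deliberately small; it trains on a CPU in about a
minute at the study scale but is not the published full-scale architecture.
Typing is done once from nuclear expression (no iterative re-typing). The
evaluation suite reports missing values rather than guessing when a
quantity is undefined (constant references, types with fewer than two
cells, empty distance bins). Whole-cell typing for concordance reuses the
Spearman assigner rather than an external annotation tool.
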