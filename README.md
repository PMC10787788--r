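# sstseg

Self-supervised cell segmentation for subcellular spatial transcriptomics
(SST), with a five-category evaluation suite and a synthetic data generator.

## The problem

Imaging SST platforms (Xenium, CosMx, MERSCOPE, Stereo-seq) detect individual
transcripts at sub-micron resolution, but turning them into single-cell
expression profiles requires segmenting *cell bodies* — and no pixel-level
ground truth exists. Nuclei are easy to segment from DAPI; cytoplasm is not,
and simple expansions produce uniformly round, wrongly sized, contaminated
cells. `sstseg` is for computational biologists processing SST runs into
gene–cell count matrices, and for method developers who need a controlled
test bed for segmentation quality.

## The method

Transcripts are rasterised into an `H × W × n_genes` expression map. A small
encoder–decoder network predicts, for every cell (conditioned on its nucleus
mask), per-pixel foreground probabilities `q̂`. It is trained with **no
manual labels**, by six biologically-informed losses (all weights 1):

| loss | signal | effect |
|---|---|---|
| nuclei encapsulation | nucleus mask `x_nuc` | cell contains its nucleus |
| cell calling | expansion mask `e_c` (disc of 20 px for round types; rotated ellipse with `l_h = 0.9·ecc·60` px for elongated types) | grows cells to type-shaped extents |
| over-segmentation | `Σσ(q̂(1−x_nuc)−0.5) − Σσ(q̂·x_nuc−0.5)`, hinged at 0 | counters over-growth |
| overlap | `Σ_c σ(q̂_c(1−x_nuc)−0.5)` vs 1, hinged | one cell per pixel |
| positive marker | map of the type's top-decile genes | capture own-type transcripts |
| negative marker | `Σσ(q̂·m_neg−0.5)/M` | reject other-type transcripts |

Cell types come from Spearman correlation of nuclear expression against a
reference profile; elongated types (e.g. fibroblasts) get elliptical
expansions aligned to the nucleus orientation, eccentricity
`ecc = √(1 − b²/a²)` from a moment-fit ellipse. Training runs on 48 × 48
patches (primary grid only); inference uses two staggered grids merged by
nearest patch centre, followed by morphological refinement (closing,
island removal, hole filling, nucleus capture) and transcript-to-cell
assignment.

The evaluation suite covers baseline characteristics (incl. eight shape
metrics with analytic identities: circularity, sphericity, compactness,
convexity, eccentricity, solidity = 1 for a circle; elongation = 1 for a
square), expression purity (`purityF1 = 2(1−F1_neg)F1_pos/(1−F1_neg+F1_pos)`),
spatial diversity (Shannon entropy vs coefficient of variation), neighbour
contamination, and replicability.

## Worked example

```r
library(sstseg)

# fully specified synthetic tissue: 256x256 px, 50 cells, 3 types (1 elongated)
sim <- simulate_sst(sim_config(rng_seed = 11))

fit <- sstseg(sim$transcripts, sim$nuclei_mask, sim$profile,
              config = train_config(n_iterations = 300, channels = 16,
                                    learning_rate = 1e-3, rng_seed = 12))
pred <- predict(fit)
print(pred)
#> SST segmentation result
#>   cells: 50   transcripts assigned: 70.2%

mask_iou(pred$cell_mask, sim$truth$cell_mask)$mean_iou
#> [1] 0.641
```

Fifty cells are recovered (one per nucleus, each a single connected
component containing its nucleus); 70% of transcripts are assigned to cells
(the truth assigns ~97%, nuclei alone ~35%), and the mean IoU against the
true cells is 0.64, versus 0.48 for a 3 × 3 nuclei-dilation baseline.
`evaluate_segmentation(pred, truth = sim$truth)` adds purity, concordance,
diversity and shape reports; `plot(fit)` shows the loss trajectory.

A thin command-line dispatcher over the same stages lives in
`inst/cli/sstseg.R` (`simulate | train | predict | evaluate | all`, YAML
config).

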