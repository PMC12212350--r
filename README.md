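# spotfuse

Spatial domain detection for a single spatially resolved transcriptomics
section (10x Visium style) that fuses **gene expression** with **spot-level
image features** — multiplexed immunofluorescence protein channels or the
RGB channels of an H&E scan.

Many spatial clustering tools use expression and coordinates alone; when a
paired image carries structure the transcriptome does not (a pathology
stain, a cell-type marker, tissue morphology), folding it in can resolve
domains that expression-only clustering misses. spotfuse is aimed at
analysts of Visium / Visium-SPG sections who want domain calls that weight
both views, with an explicit dial for how much each modality counts.

## Method

For spots `i = 1..N` with centroid coordinates and features per modality:

1. **Preprocess expression**: drop out-of-tissue spots, mitochondrial /
   spike-in genes and genes in < 3 spots; library-size normalize to the
   median total, log1p, keep the top 3000 highly variable genes, scale per
   gene to unit variance clipping above +10 SD.
2. **Extract image features**: per spot and channel, crop the `d x d` patch
   circumscribing the spot (`d = ceil(spot diameter)`), resize to 48 x 48 by
   area averaging, rescale to the expression range, and train a small
   convolutional autoencoder (5x5 kernels, 2x2 average pooling, mirrored
   transposed convolutions; Adam, lr 1e-3, 800 iterations). The flattened
   reconstruction is the spot's image feature vector.
3. **Build the spot graph**: k = 6 nearest neighbours, symmetrized by
   union; propagation operator `L = I + D^{-1/2} A D^{-1/2}`.
4. **Graph autoencoder + contrastive refinement**, per modality: encoder
   `Z_{t+1} = ReLU(L Z_t W_t + b_t)` (widths 64, 32), mirrored decoder, and
   a Deep-Graph-Infomax-style objective against a feature-shuffled graph:
   `alpha ||X - H||^2 + beta (L_CSL + L_CSL')`, where summaries
   `S_i = sigmoid(mean_{j~i} Z_j + Z_i)` are scored by a bilinear
   discriminator `sigmoid(Z_i' W S_i)` (Adam, lr 1e-3, 600 iterations).
5. **Fuse, cluster, refine**: concatenate the top 30 PCs of the
   reconstructed expression with the top 5 PCs of the reconstructed image
   features (the per-block counts are the modality weights), cluster with a
   shared-covariance Gaussian mixture (mclust EEE; silhouette-selected k if
   unknown), then relabel each spot to the majority domain among its r = 10
   nearest spots.

Agreement with ground truth is measured by the Adjusted Rand Index (ARI),
cluster separation by the mean silhouette width.

## Worked example

Simulate a Visium-like section with known domains, run the pipeline, and
compare against the planted truth:

```r
library(spotfuse)

# 30 x 30 honeycomb, 3 horizontal-layer domains, 300 genes (50 markers per
# domain at 2 log-units), one domain-correlated image channel
fx <- simulate_fixture(synthetic_config(), "fixture/")

res <- run_pipeline(run_config(
  visium_dir = fx$dir, image = fx$image,
  k_domains = 3, truth = file.path(fx$dir, "truth_labels.csv"),
  seed = 1
))
res
#> <pipeline_result> 900 spots, k = 3 domains, silhouette 0.858
#>   ARI vs truth: raw 1.000, refined 1.000
```

The silhouette (0.86) says the three domains are well separated in the
fused principal-component profile, and both the raw mixture labels and
their spatially refined version (majority vote among each spot's 10
nearest neighbours) recover the planted truth exactly; on harder draws the
raw labels typically land around ARI 0.9 and refinement cleans up the
stragglers. On real tissue you would pass your
spaceranger output directory and image instead, set `k_domains` from
annotation (or a `k_range` to select by silhouette), and read
`labels.csv` / `metrics.json` from the output directory.

A command-line front end wraps the same functions:

```sh
inst/cli/spotfuse simulate --seed 7 --out fixture/
inst/cli/spotfuse run --config cfg.yaml
inst/cli/spotfuse evaluate --pred labels.csv --truth truth_labels.csv
```

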