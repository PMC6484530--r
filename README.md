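# ecprofiler

High-content phenotypic profiling of confluent endothelial-cell (EC)
monolayers from three-channel fluorescence images — nuclei, the
adherens-junction marker VE-cadherin (VEC), and activated-NOTCH (NICD)
spots — plus a ground-truthed synthetic image simulator so the entire
pipeline is testable without microscope data.

It is written for quantitative cell biologists and image-analysis
engineers who want a scriptable, reproducible replacement for
point-and-click high-content screening (HCS) pipelines when comparing EC
models (e.g. primary HUVECs vs iPSC-derived ECFCs) across treatments
(e.g. VEGF).

## What it computes

Per stitched area (a 3×3 tile mosaic), the pipeline measures every cell
and aggregates a **47-feature profile**:

* **Segmentation** — nuclei by smoothing → Otsu → distance-transform
  watershed; cells by seeded region growing on the VEC channel (junction
  ridges act as barriers), with the confluent assumption that cell labels
  partition the frame.
* **Junctions** — a Hessian ridge filter enhances thin VEC-positive
  structures; thresholded ridge pixels are intersected with each cell's
  boundary ring and 8-connected components become junction objects. The
  summary statistic is

  `J_n = (total junction objects over cells) / (number of nuclei)`,

  low for continuous ("stable") junctions, high for discontinuous
  ("active") ones.
* **NOTCH activation** — difference-of-Gaussians spot detection, then a
  per-cell category: `N-/-` (no spots), `N+/-` (cytoplasmic only),
  `N+/+` (any nuclear spot). Contiguous `N+/+` cells on the
  cell-contact graph form **NOTCH clusters**, summarized by four context
  features (count, mean size, max size, fraction in clusters ≥ 2).
* **Morphometry** — shape (area, Crofton perimeter, roundness
  `4πA/P²`, ellipse-equivalent length/width `4√λ`) and STAR
  (Symmetry, Threshold compactness, Axial, Radial) intensity-distribution
  features per cell and channel.
* **Profiling** — area-level rows are z-scored, then analyzed by PCA
  (SVD; explained-variance ratios `s_j²/Σs²`) and average-linkage
  (UPGMA) hierarchical clustering with Euclidean distances.

The simulator (`sample_monolayer()` / `render_field()` /
`generate_experiment()`) draws confluent monolayers as anisotropically
stretched Voronoi tessellations with per-cell ground truth (polygons,
nucleus ellipses, true NOTCH category, spot coordinates, adjacency), so
segmentation accuracy, classification accuracy and the `J_n`
dose-response can be verified against planted truth.

## Worked example

Generate a small synthetic experiment (four conditions × one area of
3×3 tiles), analyze it, and look at the per-condition readouts:

```r
library(ecprofiler)

layout <- experiment_layout(replicates_per_condition = 1, areas_per_replicate = 1)
manifest <- generate_experiment(layout, seed = 1, out_dir = "demo")
features <- analyze_experiment(manifest, "demo")
features[, c("cell_model", "treatment", "jn", "pct_nnuc",
             "cell_count", "cell_width_length_ratio")]
#> # A tibble: 4 × 6
#>   cell_model treatment    jn pct_nnuc cell_count cell_width_length_ratio
#>   <chr>      <chr>     <dbl>    <dbl>      <dbl>                   <dbl>
#> 1 huvec      basal      1.63     28.9         97                   0.758
#> 2 huvec      vegf       1.72     36.5         96                   0.700
#> 3 ipsc       basal     10.3      20.8         96                   0.754
#> 4 ipsc       vegf      10.9      31.2         96                   0.739
```

Read: iPSC-ECFC junctions are far more fragmented than HUVEC junctions
(`J_n` ≈ 10 vs ≈ 1.7); VEGF elongates cells (width/length ratio drops)
and raises the nuclear-NOTCH fraction, most visibly in the iPSC model.
With the full default layout (two replicates × five areas, 40 areas
total) the profile separates the two cell models:

```r
profile <- profile_features(features)   # z-score + PCA + UPGMA
glance(profile)                          # areas, features, variance explained
tidy(profile)                            # annotated PC scores
autoplot(profile)                        # PC1 x PC2 score plot
plot_dendrogram(profile)                 # area dendrogram
```

A YAML-driven runner (`run_pipeline("config.yaml")`) chains
simulate → analyze → profile with per-stage caching, and a thin CLI
wrapper lives in `inst/cli/ecprof.R`.

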