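---
title: "Methods: simulating and profiling endothelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and profiling endothelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Endothelial cells (ECs) grown to confluence form a cobblestone monolayer
whose phenotype is read out in high-content screens from three stains: a
nuclear dye, the adherens-junction marker VE-cadherin (VEC) outlining
cell-cell borders, and an antibody against cleaved NOTCH intracellular
domain (NICD) that appears as bright puncta. Three families of questions
are asked of such images:

* **morphology** — are cells stretched and elongated (the VEGF response),
  round, large, small?
* **junction state** — are VEC-stained borders continuous ("stable"
  junctions) or discontinuous and jagged ("active" junctions)? We
  summarize this with `J_n`, the mean number of discrete VEC-positive
  junction objects per nucleus: continuous borders give one object per
  cell-cell contact and a low `J_n`, fragmented borders give many short
  objects and a high `J_n`.
* **NOTCH activation** — per cell, are there no NICD spots (`N-/-`),
  cytoplasmic spots only (`N+/-`, cleaved but not transcriptionally
  active), or nuclear spots (`N+/+`, putatively active)? Because active
  cells touch each other, the sizes of contiguous groups of `N+/+` cells
  on the cell-contact graph ("NOTCH clusters") are context features in
  their own right.

`ecprofiler` implements this pipeline end to end and couples it to a
ground-truthed simulator so that every stage is testable without
microscope data: segmentation accuracy, classification accuracy, and the
dose-response of `J_n` can all be measured against planted truth.

## The synthetic monolayer model

`sample_monolayer()` draws a confluent tessellation:

1. **Seeds** are Poisson-disc sampled (dart throwing with an exclusion
   radius derived from the target density) in a coordinate system whose
   column axis is divided by `elongation`; the subsequent nearest-seed
   assignment in that stretched metric produces uniformly stretched cells
   without overlaps, which mimics monolayer-wide cell elongation.
2. **Boundaries** are perturbed by a smooth random displacement field
   (white noise blurred at sigma 6 px, rescaled to standard deviation
   `jaggedness`), giving wavy, interdigitated-looking borders without
   destroying the partition.
3. **Nuclei** are ellipses at each cell's centroid, aligned with the
   cell's principal axis, with area `nucleus_area_fraction` times the
   cell area, shrunk in 5% steps until fully inside the cell.
4. **Categories and spots**: each cell draws its true NOTCH category from
   `category_probs`; `N+/+` cells place `1 + Poisson(spot_rate_nuc - 1)`
   nuclear spots (the shifted Poisson makes "at least one spot"
   guaranteed by construction, so the category invariants cannot be
   violated by sampling), plus Poisson cytoplasmic spots; `N+/-` cells
   place `1 + Poisson(spot_rate_cyt - 1)` cytoplasmic spots; `N-/-` cells
   none.

`render_field()` draws the three channels (nuclear, junction, spots) at
16-bit range, applies a global Gaussian point-spread blur, adds a
background offset and Gaussian read noise, and rounds. Everything is
deterministic given `(params, seed)`.

### Junction fragmentation is notching, not deletion

The discontinuity knob `junction_fragmentation` (p_frag) selects each
border segment (length `segment_length`) independently and removes the
**central 60% of the selected segment**, leaving flanking stubs. We chose
notching over deleting whole segments deliberately: with whole-segment
deletion the number of surviving junction fragments behaves like the
number of runs in a Bernoulli sequence, `~ N p (1 - p)`, which peaks at
p = 0.5 and *falls* again — the statistic `J_n` would stop being a
monotone readout of discontinuity exactly where discontinuity is
strongest. Micrographs of activated endothelium show junctions with local
discontinuations, not absent borders, and notching reproduces that: the
number of objects grows monotonically with p_frag across the whole [0, 1]
range (the package asserts Spearman >= 0.9 over a five-level sweep).

### Default study conditions

The default experiment (`experiment_layout()`) mirrors a two-model,
two-treatment design: HUVEC vs iPSC-derived ECFC, each untreated or
VEGF-treated, in duplicate, five areas per replicate, each area stitched
from 3 x 3 tiles with 0.05% overlap — 40 areas of nine fields in total.
Tiles are 256 px at 0.2994 um/px (a 40x water-immersion objective scale).

The four presets (`preset_params()`) encode the qualitative contrasts
these conditions are known for, not fitted constants (no raw generative
parameters exist to fit): the iPSC presets carry strongly fragmented
junctions (p_frag 0.50/0.55 vs 0.04/0.06), rougher borders (jaggedness
5 vs 0.6 px) and a larger NOTCH-inactive fraction (pi_neg 0.65/0.55 vs
0.25/0.23); VEGF raises elongation within each model (1.15 -> 1.3 and
1.2 -> 1.3) and raises the nuclear-NOTCH fraction markedly in the iPSC
model (0.17 -> 0.27) but only marginally in HUVECs (0.33 -> 0.35). The
treatment deltas are intentionally smaller than the model deltas: the
design premise of the population-level analysis is that the two cell
models are discrete populations, and the presets realize that premise
while preserving every within-model ordering.

The default density is 140 cells per 768-px frame, about 2650 cells/mm^2
— a tightly confluent EC monolayer. Density matters
beyond realism: area-level rows are means and percentages over the
area's interior cells, so their sampling noise scales like 1/sqrt(n);
at much sparser defaults, binomial noise on the category percentages
(only ~20 interior cells) occasionally produces outlier areas that any
average-linkage dendrogram will happily cut off on their own.

## Image analysis

* **Nuclei**: Gaussian smooth (`smooth_sigma` 2 px) -> Otsu threshold ->
  fill holes -> watershed on the distance transform to split touching
  nuclei -> area gate (25-1000 um^2). Labels are re-ordered row-major by
  centroid so output is reproducible.
* **Cells**: seeded region growing (`EBImage::propagate`) on the smoothed
  junction channel with nuclei as seeds. VEC ridges act as barriers, so
  region borders settle on them (a constructed-ridge test asserts the
  boundary lands within 1 px of the ridge crest). The monolayer is
  assumed confluent: the foreground is the whole frame and cell labels
  partition it. Cells touching the frame edge are excluded from per-cell
  statistics but keep their pixels, so adjacency of interior cells is
  unaffected.
* **Junctions**: a Hessian ridge filter at scale `ridge_sigma` (the
  magnitude of the most negative Hessian eigenvalue, clipped at zero,
  computed with sigma-normalized Gaussian derivative kernels) stands in
  for the proprietary "SER edge" texture operator; both enhance thin
  bright structures, and `J_n` depends only on a thresholded ridge
  response, not the exact kernel. The response is offset-invariant and,
  with Otsu-on-ridge thresholding, invariant to global intensity
  scaling. Thresholded ridge pixels are intersected with each cell's
  boundary ring (within `ring_width` = 6 px of the border, inside the
  cell); 8-connected components of area >= `min_object_area` are that
  cell's junction objects. Without the per-cell ring the junction network
  of a confluent field would be one image-wide component and per-cell
  counting would be meaningless. A shared unbroken border contributes one
  object to each neighbor — `J_n` is used comparatively, so a consistent
  convention suffices.
* **Spots**: difference-of-Gaussians band-pass (sigma, 1.6 sigma), local
  maxima with a minimum separation, kept when the response exceeds the
  median by `t_spot` = 5 median absolute deviations. Compartment is
  decided by the spot *center*: nuclear if the center lies in the cell's
  nucleus mask, cytoplasmic otherwise — a per-spot location rule with no
  area-overlap ambiguity. Cells with any nuclear spot are `N+/+`
  (nucleus-only cells are grouped there), cytoplasmic-only cells `N+/-`,
  spotless cells `N-/-`.
* **Adjacency and clusters**: cells are adjacent when at least
  `min_shared_border` = 3 four-connected pixel pairs straddle their
  labels (suppressing corner-touch artifacts); NOTCH clusters are
  connected components of the `N+/+`-induced subgraph, singletons
  included. Four context features summarize them: count, mean size,
  maximum size, and the fraction of `N+/+` cells in clusters of size
  >= 2.

## The 47-feature registry

Area-level rows consist of exactly 47 features: 6 cell-shape + 6
nucleus-shape + 1 nucleus/cell area ratio + 9 STAR features of the
junction channel + 9 of the spot channel + 4 compartment mean
intensities + 4 junction statistics (`J_n`, mean object area, ring area
fraction, mean junction intensity) + 3 NOTCH category percentages + 4
cluster features + the interior cell count. Per-cell features aggregate
by mean; the rest are area-level statistics by definition. The
composition is config-overridable, but the default must and does count
47.

Shape features use the ellipse-equivalent axis convention
`length = 4 sqrt(lambda1) * pixel_size` on binary-mask coordinate
covariance (for a solid ellipse this recovers the full axis), a
4-direction Crofton perimeter, and roundness `4 pi A / P^2` clipped to 1.
STAR (Symmetry / Threshold-compactness / Axial / Radial) features are
intensity-distribution descriptors; the vendor definitions are
proprietary, so this package defines them exactly, preferring
dimensionless, bounded, disk-normalized quantities whose invariants are
testable: symmetry is an L1 mirror asymmetry across the principal axis
mapped to [0, 1]; threshold compactness at fraction f of the in-mask
mean is (area/2pi) / (mean squared distance to centroid), equal to 1 for
a uniform disk and clipped there; the axial pair are the
intensity-weighted covariance aspect `sqrt(lambda2/lambda1)` and minor
axis; the radial pair are the intensity-weighted mean and standard
deviation of border distance normalized to [0, 1]. Zero-intensity
regions yield all-zero STAR features by declared rule. Rotation
invariance is asserted to within 2% on rasters.

## Multivariate profiling

Rows (areas) are z-scored per feature (sd with denominator n-1;
zero-variance features become zero columns and are reported), then:

* **PCA** by singular value decomposition of the centered matrix;
  explained-variance ratios are `s_j^2 / sum s^2`; the sign convention
  (largest-magnitude loading positive) makes scores deterministic. An
  eigendecomposition of the covariance matrix serves as an independent
  oracle in the tests (agreement to 1e-8).
* **Hierarchical clustering** with Euclidean distances and average
  linkage (UPGMA), the common default in high-content analysis suites;
  single and complete linkage are available in the API. The linkage is
  checked exactly against a brute-force O(n^3) UPGMA oracle via
  cophenetic matrices. Exact-tie behavior follows `stats::hclust`; all
  profiled quantities are continuous, so ties have measure zero. The
  displayed leaf order re-orders the dendrogram by each leaf's average
  feature value — ordering by average value is treated as a display
  convention, not a feature weighting, since weighting features would
  contradict the plain Euclidean row distance used for the linkage.

On the default synthetic experiment the package asserts the
population-level property the analysis exists for: cutting the
dendrogram into two groups separates the two cell models exactly
(adjusted Rand index 1), and the PC scores admit a perfect linear
threshold on PC1 or PC2.

## Numerical and interface choices

* 1-based, row-major pixel coordinates (R matrix convention); object
  labels 1-based with 0 = background.
* The tile overlap default 0.0005 reads the instrument setting "0.05%
  overlapping" literally; if it is a typo for 5%, pass
  `tile_overlap_frac = 0.05` — stitching supports any value in [0, 0.5).
  At 0.05% and 256-px tiles the rounded overlap is 0 px, so the mosaic
  arithmetic is exact either way.
* Stitching trusts stage offsets (no registration) and feathers overlaps
  linearly; any symmetric blend satisfies the reconstruction tests.
* Degenerate guards: < 4 px objects are excluded and logged; zero-signal
  STAR features are 0; `J_n` with zero nuclei is an error rather than a
  NaN; empty areas abort aggregation explicitly.
* The workflow runner derives per-area seeds from the master seed with a
  stateless 31-bit string hash, so areas are independent of execution
  order; stages are skipped when outputs exist and the config-section
  hash matches.

## Problem sizes in the test-suite

Unit and property tests run on 128-640 px frames with 6-50 cells;
recovery suites pool ~10 areas (>= 200 interior cells) at low read noise
(sigma 20); the end-to-end suite generates the full default experiment
(40 areas, 3 x 3 tiles of 256 px, ~140 cells/area) once and shares it
across assertions. These sizes were chosen as the smallest at which the
binomial and boundary-discretization noise terms are comfortably below
the contrasts being asserted.

## What passing tests do and do not show

The simulator emulates geometry, staining logic and camera noise; it
does not emulate uneven illumination, out-of-focus light, mitotic or
apoptotic figures, overlapping cells, staining variability between
batches, or junction morphologies beyond fragmentation (no
linear-vs-interdigitated distinction — a deliberate non-goal). Passing
recovery tests therefore demonstrates the pipeline's internal
correctness and its sensitivity to the modeled contrasts, not
performance on real micrographs; on real data the segmentation and
threshold defaults (`smooth_sigma`, `ridge_sigma`, `t_spot`) are the
parameters to revisit first, and all of them are logged by the runner.
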