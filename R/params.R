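#' Simulation parameters for a synthetic monolayer scene
#'
#' Bundles every knob of the synthetic confluent-endothelium generator.
#' Cells are modeled as an anisotropically stretched Voronoi tessellation of
#' Poisson-disc-sampled seed points; junction continuity is controlled by a
#' per-segment deletion probability, and per-cell NOTCH activation spots are
#' placed in the nuclear or cytoplasmic compartment according to the cell's
#' true category.
#'
#' @param frame_size integer (rows, cols) of the rendered field, >= 64 px.
#' @param pixel_size pixel size in micrometres per pixel (0.2994 matches a
#'   40x water-immersion objective).
#' @param target_cell_count number of cells to seed in the frame.
#' @param elongation unitless >= 1; anisotropic stretch of the tessellation
#'   metric along the column axis. 1 = isotropic, larger = more elongated
#'   cells (the VEGF-stretch phenotype).
#' @param jaggedness boundary-perturbation amplitude in px (standard
#'   deviation of a smooth random displacement field).
#' @param junction_fragmentation probability in `[0,1]` that any given border
#'   segment is deleted before rendering (`p_frag`); higher values emulate
#'   discontinuous, "active" adherens junctions.
#' @param segment_length border segment length in px used for fragmentation.
#' @param junction_width Gaussian cross-profile width of rendered junctions,
#'   px.
#' @param category_probs numeric length-3 `(pi_neg, pi_cyt, pi_nuc)` summing
#'   to 1: probabilities that a cell is NOTCH-inactive (no spots),
#'   cytoplasmic-only, or nuclear-positive.
#' @param spot_rate_cyt,spot_rate_nuc mean spots per cell (> 0) for the
#'   cytoplasmic and nuclear compartments; counts are drawn as
#'   `1 + Poisson(rate - 1)` so category constraints hold by construction.
#' @param spot_sigma Gaussian spot width, px.
#' @param background_offset,noise_sigma camera background level and additive
#'   Gaussian noise sd, 16-bit intensity units.
#' @param psf_sigma global optical blur sd, px.
#' @param nucleus_area_fraction fraction of the cell area occupied by the
#'   nucleus ellipse, in (0,1).
#' @param nuclear_amp,junction_amp,spot_amp rendered signal amplitudes,
#'   16-bit intensity units.
#'
#' @return An object of class `scene_params` (a validated list).
#' @export
#' @examples
#' p <- scene_params(target_cell_count = 10, frame_size = c(128, 128))
#' p$elongation
scene_params <- function(frame_size = c(768L, 768L),
                         pixel_size = 0.2994,
                         target_cell_count = 140L,
                         elongation = 1,
                         jaggedness = 2,
                         junction_fragmentation = 0.1,
                         segment_length = 12,
                         junction_width = 3,
                         category_probs = c(0.45, 0.35, 0.20),
                         spot_rate_cyt = 3,
                         spot_rate_nuc = 2,
                         spot_sigma = 2,
                         background_offset = 1000,
                         noise_sigma = 120,
                         psf_sigma = 1,
                         nucleus_area_fraction = 0.15,
                         nuclear_amp = 12000,
                         junction_amp = 16000,
                         spot_amp = 20000) {
  p <- list(frame_size = as.integer(frame_size), pixel_size = pixel_size,
            target_cell_count = as.integer(target_cell_count),
            elongation = elongation, jaggedness = jaggedness,
            junction_fragmentation = junction_fragmentation,
            segment_length = segment_length, junction_width = junction_width,
            category_probs = category_probs,
            spot_rate_cyt = spot_rate_cyt, spot_rate_nuc = spot_rate_nuc,
            spot_sigma = spot_sigma, background_offset = background_offset,
            noise_sigma = noise_sigma, psf_sigma = psf_sigma,
            nucleus_area_fraction = nucleus_area_fraction,
            nuclear_amp = nuclear_amp, junction_amp = junction_amp,
            spot_amp = spot_amp)
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (length(p$frame_size) != 2L || any(p$frame_size < 64L))
    abort("frame_size must be (rows, cols) with both >= 64 px")
  if (abs(sum(p$category_probs) - 1) > 1e-9 || length(p$category_probs) != 3L)
    abort("category_probs must be 3 probabilities summing to 1")
  if (any(p$category_probs < 0)) abort("category_probs must be non-negative")
  if (p$elongation < 1) abort("elongation must be >= 1")
  if (p$junction_fragmentation < 0 || p$junction_fragmentation > 1)
    abort("junction_fragmentation must be in [0, 1]")
  if (p$pixel_size <= 0) abort("pixel_size must be > 0")
  if (p$target_cell_count < 0) abort("target_cell_count must be >= 0")
  if (p$nucleus_area_fraction <= 0 || p$nucleus_area_fraction >= 1)
    abort("nucleus_area_fraction must be in (0, 1)")
  if (p$spot_rate_cyt <= 0 || p$spot_rate_nuc <= 0)
    abort("spot rates must be > 0")
  invisible(p)
}

#' Phenotype presets for the four study conditions
#'
#' Returns `scene_params` tuned to one of four named conditions contrasting
#' two endothelial models (primary HUVECs vs iPSC-derived ECFCs) with and
#' without VEGF. Values encode the qualitative orderings the conditions are
#' known for rather than fitted constants: iPSC presets carry looser, more
#' fragmented junctions and a larger NOTCH-inactive fraction; VEGF presets
#' are more elongated; VEGF raises the nuclear-NOTCH fraction in the iPSC
#' model but not appreciably in HUVECs.
#'
#' @param name one of `"huvec_basal"`, `"huvec_vegf"`, `"ipsc_basal"`,
#'   `"ipsc_vegf"`.
#' @param ... overrides forwarded to [scene_params()].
#' @return A `scene_params` object.
#' @export
#' @examples
#' preset_params("ipsc_vegf")$junction_fragmentation
preset_params <- function(name, ...) {
  presets <- list(
    huvec_basal = list(elongation = 1.15, jaggedness = 0.6,
                       junction_fragmentation = 0.04,
                       category_probs = c(0.25, 0.42, 0.33)),
    huvec_vegf  = list(elongation = 1.3, jaggedness = 0.6,
                       junction_fragmentation = 0.06,
                       category_probs = c(0.23, 0.42, 0.35)),
    ipsc_basal  = list(elongation = 1.2, jaggedness = 5,
                       junction_fragmentation = 0.50,
                       category_probs = c(0.65, 0.18, 0.17)),
    ipsc_vegf   = list(elongation = 1.3, jaggedness = 5,
                       junction_fragmentation = 0.55,
                       category_probs = c(0.55, 0.18, 0.27)))
  if (!name %in% names(presets))
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  do.call(scene_params, utils::modifyList(presets[[name]], list(...)))
}

#' Experiment layout: conditions, replicates, areas and tiling
#'
#' Describes the acquisition design: which phenotype presets are imaged, how
#' many replicates per condition, how many areas per replicate, and the tile
#' grid each area is composed of. The default mirrors a design of two cell
#' models x two treatments in duplicate with five areas each, every area a
#' 3x3 tile mosaic with 0.05% overlap (40 areas of nine fields in total).
#'
#' @param cell_models character vector of model names (preset prefix).
#' @param treatments character vector of treatment names (preset suffix).
#' @param replicates_per_condition integer >= 1.
#' @param areas_per_replicate integer >= 1.
#' @param tile_grid integer (rows, cols) of the tile mosaic.
#' @param tile_overlap_frac fractional overlap between neighboring tiles,
#'   in `[0, 0.5)`.
#' @param tile_size integer (rows, cols) of one tile in px.
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(cell_models = c("huvec", "ipsc"),
                              treatments = c("basal", "vegf"),
                              replicates_per_condition = 2L,
                              areas_per_replicate = 5L,
                              tile_grid = c(3L, 3L),
                              tile_overlap_frac = 0.0005,
                              tile_size = c(256L, 256L)) {
  l <- list(cell_models = cell_models, treatments = treatments,
            replicates_per_condition = as.integer(replicates_per_condition),
            areas_per_replicate = as.integer(areas_per_replicate),
            tile_grid = as.integer(tile_grid),
            tile_overlap_frac = tile_overlap_frac,
            tile_size = as.integer(tile_size))
  if (l$replicates_per_condition < 1L || l$areas_per_replicate < 1L ||
      any(l$tile_grid < 1L))
    abort("all layout counts must be >= 1")
  if (tile_overlap_frac < 0 || tile_overlap_frac >= 0.5)
    abort("tile_overlap_frac must be in [0, 0.5)")
  structure(l, class = "experiment_layout")
}

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing sd, px.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold used when
#'   `threshold_method = "fixed"`.
#' @param min_nucleus_area,max_nucleus_area nucleus area bounds in square
#'   micrometres; components outside the range are dropped.
#' @param split_min_distance minimum distance (px) between seed maxima when
#'   splitting touching nuclei on the distance transform.
#' @param border_policy `"exclude"` drops frame-edge cells from per-cell
#'   statistics (their pixels are kept for adjacency); `"keep"` retains them.
#' @param min_shared_border minimum shared border length (px) for two cells
#'   to count as adjacent.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 2,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_nucleus_area = 25,
                       max_nucleus_area = 1000,
                       split_min_distance = 6,
                       border_policy = c("exclude", "keep"),
                       min_shared_border = 3L) {
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  if (min_nucleus_area <= 0 || max_nucleus_area <= min_nucleus_area)
    abort("need 0 < min_nucleus_area < max_nucleus_area")
  structure(list(smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 split_min_distance = split_min_distance,
                 border_policy = border_policy,
                 min_shared_border = as.integer(min_shared_border)),
            class = "seg_params")
}

#' Junction-detection parameters
#'
#' @param ridge_sigma Hessian scale (px) of the ridge filter; match to the
#'   junction width.
#' @param edge_threshold `"otsu-on-ridge"` (Otsu on the nonzero ridge
#'   response) or `"fixed"`.
#' @param fixed_threshold ridge-response threshold when `"fixed"`.
#' @param ring_width width (px, >= 2) of the per-cell boundary ring within
#'   which junction objects are counted.
#' @param min_object_area minimum junction-object area, px^2.
#' @return An object of class `junction_params`.
#' @export
junction_params <- function(ridge_sigma = 2,
                            edge_threshold = c("otsu-on-ridge", "fixed"),
                            fixed_threshold = NULL,
                            ring_width = 6L,
                            min_object_area = 4L) {
  edge_threshold <- match.arg(edge_threshold)
  if (ridge_sigma <= 0) abort("ridge_sigma must be > 0")
  if (ring_width < 2) abort("ring_width must be >= 2")
  structure(list(ridge_sigma = ridge_sigma, edge_threshold = edge_threshold,
                 fixed_threshold = fixed_threshold,
                 ring_width = as.integer(ring_width),
                 min_object_area = min_object_area),
            class = "junction_params")
}

#' Spot-detection parameters
#'
#' Difference-of-Gaussians band-pass (`sigma`, `1.6 * sigma`) followed by
#' local-maximum selection with a minimum separation and a robust
#' significance gate: a maximum is kept when its band-pass response exceeds
#' `t_spot` median absolute deviations above the median response.
#'
#' @param sigma inner DoG scale, px (match to spot size).
#' @param min_separation minimum distance between detections, px.
#' @param t_spot significance threshold in robust (MAD) units.
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(sigma = 2, min_separation = 5L, t_spot = 5) {
  structure(list(sigma = sigma, min_separation = as.integer(min_separation),
                 t_spot = t_spot), class = "spot_params")
}
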