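#' Run the full single-area analysis
#'
#' Convenience wrapper chaining every per-area stage on one stitched field:
#' nucleus segmentation, seeded cell segmentation, junction enhancement and
#' object detection, J_n, spot detection, NOTCH classification, the
#' cell-contact graph and NOTCH clusters, and the per-cell record table.
#'
#' @param field a [field_image()] with `nuclear`, `junction` and `spots`
#'   channels.
#' @param seg a [seg_params()].
#' @param jct a [junction_params()].
#' @param spot a [spot_params()].
#' @return A list of class `area_analysis`: `nuclei`, `cells`, `jset`,
#'   `jn`, `notch`, `graph`, `clusters`, `cell_table`.
#' @export
analyze_area <- function(field, seg = seg_params(), jct = junction_params(),
                         spot = spot_params()) {
  nuclei0 <- segment_nuclei(field, seg)
  cells <- segment_cells(field, nuclei0, seg)
  # nuclei pixels forced inside their cell; labels shared with cells
  nuc_lab <- nuclei0$labels
  nuc_lab[nuc_lab > 0 & nuc_lab != cells$labels] <- 0L
  nuclei <- label_mask(relabel_keep(nuc_lab), "nuclei", field$pixel_size,
                       retained = cells$retained, check_contiguous = FALSE)
  ridge <- junction_enhance(field$channels[["junction"]], jct)
  jset <- detect_junctions(ridge, cells, nuclei, jct)
  n_ret <- length(cells$retained)
  jn <- if (n_ret >= 1) junction_summary(jset, n_ret)$jn else NA_real_
  spots <- detect_spots(field$channels[["spots"]], spot)
  notch <- classify_notch(spots, nuclei, cells)
  graph <- cell_adjacency(cells, seg$min_shared_border)
  clusters <- notch_clusters(graph, notch$categories)
  cell_table <- build_cell_table(field, nuclei, cells, jset, notch, clusters)
  structure(list(nuclei = nuclei, cells = cells, jset = jset, jn = jn,
                 notch = notch, graph = graph, clusters = clusters,
                 cell_table = cell_table, field = field),
            class = "area_analysis")
}

# keep label values as-is (they must match the cell labels), only ensure
# integer storage; gaps from dropped nuclei are fine here because labels
# are tied to cells, not re-packed
relabel_keep <- function(lab) {
  storage.mode(lab) <- "integer"
  lab
}

#' Aggregate one analyzed area into a 47-feature row
#'
#' Applies the registry's aggregation rules: per-cell features are averaged
#' over the area's retained cells; area-level statistics (J_n, junction
#' object area / ring fraction / intensity, NOTCH category percentages,
#' cluster features, cell count) are computed from their definitions.
#'
#' @param analysis an `area_analysis` from [analyze_area()], or a cell
#'   table plus `stats` list for pre-computed stages.
#' @param registry the [feature_registry()] (default registry).
#' @return A one-row tibble with the 47 feature columns in registry order.
#' @export
aggregate_area <- function(analysis, registry = feature_registry()) {
  ct <- analysis$cell_table
  if (nrow(ct) == 0) abort("no cells in area")
  mean_cols <- registry$source[registry$aggregation == "cell_mean"]
  means <- vapply(mean_cols, function(cl) mean(ct[[cl]]), numeric(1))
  jmask <- analysis$jset$junction_mask$labels
  jch <- analysis$field$channels[["junction"]]
  stats_v <- c(
    jn = analysis$jn,
    jct_mean_object_area = mean(ct$jct_object_area),
    jct_ring_area_fraction = mean(ct$jct_ring_frac),
    jct_mean_intensity = if (any(jmask > 0)) mean(jch[jmask > 0]) else 0,
    pct_nneg = unname(analysis$notch$fractions["Nneg"]),
    pct_ncyt = unname(analysis$notch$fractions["Ncyt"]),
    pct_nnuc = unname(analysis$notch$fractions["Nnuc"]),
    notch_n_clusters = unname(analysis$clusters$features["n_clusters"]),
    notch_mean_cluster_size = unname(analysis$clusters$features["mean_size"]),
    notch_max_cluster_size = unname(analysis$clusters$features["max_size"]),
    notch_frac_in_multi = unname(analysis$clusters$features["frac_in_multi"]),
    cell_count = length(analysis$cells$retained))
  vals <- c(stats::setNames(means, registry$feature[registry$aggregation == "cell_mean"]),
            stats_v)
  as_tibble(as.list(vals[registry$feature]))
}

#' Analyze every area of a generated experiment
#'
#' Stitches each area from its tiles, runs [analyze_area()] and
#' [aggregate_area()], and binds the annotated rows into the experiment's
#' feature table.
#'
#' @param manifest manifest tibble from [generate_experiment()] /
#'   [read_manifest()].
#' @param dir directory holding the tiles.
#' @inheritParams analyze_area
#' @param registry the [feature_registry()].
#' @return A tibble: one row per area, annotation columns (`cell_model`,
#'   `treatment`, `replicate`, `area`) followed by the 47 features.
#' @export
analyze_experiment <- function(manifest, dir, seg = seg_params(),
                               jct = junction_params(), spot = spot_params(),
                               registry = feature_registry()) {
  areas <- dplyr::distinct(manifest, .data$cell_model, .data$treatment,
                           .data$replicate, .data$area)
  rows <- purrr::pmap(areas, function(cell_model, treatment, replicate, area) {
    f <- stitch_manifest_area(manifest, dir, cell_model, treatment,
                              replicate, area)
    an <- analyze_area(f, seg, jct, spot)
    dplyr::bind_cols(tibble(cell_model = cell_model, treatment = treatment,
                            replicate = replicate, area = area),
                     aggregate_area(an, registry))
  })
  dplyr::bind_rows(rows)
}
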