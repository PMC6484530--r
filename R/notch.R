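#' Detect activation spots in the spot channel
#'
#' Difference-of-Gaussians band-pass at scales `(sigma, 1.6 sigma)`,
#' followed by local-maximum selection with minimum separation
#' `min_separation` px and a robust significance gate: maxima are kept when
#' their band-pass response exceeds the median response by at least
#' `t_spot` median absolute deviations. Deterministic.
#'
#' @param spot_channel 2D numeric matrix.
#' @param params a [spot_params()].
#' @return A tibble with one row per detection: center `(r, c)`, `intensity`
#'   (raw pixel value at the peak) and `response` (band-pass value).
#' @export
detect_spots <- function(spot_channel, params = spot_params()) {
  s <- params$sigma
  dog <- gblur_mat(spot_channel, s) - gblur_mat(spot_channel, 1.6 * s)
  thr <- stats::median(dog) + params$t_spot * stats::mad(dog)
  if (stats::mad(dog) == 0 && diff(range(dog)) == 0)
    return(tibble(r = integer(), c = integer(),
                  intensity = numeric(), response = numeric()))
  # non-maximum suppression: a pixel survives if it equals the running max
  # over a (2 min_sep + 1) box
  w <- 2L * params$min_separation + 1L
  mx <- as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::Image(dog - min(dog)),
    EBImage::makeBrush(w, shape = "box")))) + min(dog)
  peaks <- which(dog >= mx - 1e-9 & dog >= thr)
  if (length(peaks) == 0)
    return(tibble(r = integer(), c = integer(),
                  intensity = numeric(), response = numeric()))
  nr <- nrow(dog)
  r <- ((peaks - 1L) %% nr) + 1L
  cc <- ((peaks - 1L) %/% nr) + 1L
  out <- tibble(r = r, c = cc,
                intensity = spot_channel[peaks], response = dog[peaks])
  # plateau duplicates within min_separation: keep the first in row-major order
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    d2 <- (out$r - out$r[i])^2 + (out$c - out$c[i])^2
    close_later <- which(d2 <= params$min_separation^2 &
                           seq_len(nrow(out)) > i)
    keep[close_later] <- FALSE
  }
  out[keep, ]
}

#' Classify cells into NOTCH activation categories
#'
#' Assigns every detected spot to the cell containing its center; the
#' compartment is nuclear when the center also falls in that cell's
#' nucleus, cytoplasmic otherwise; spots outside all cells (or in
#' non-retained cells) are flagged `outside` and excluded. Each retained
#' cell is then labeled: `Nneg` (no spots, pathway inactive), `Ncyt`
#' (cytoplasmic spots only, not transcriptionally active) or `Nnuc`
#' (any nuclear spot, with or without cytoplasmic ones, putatively
#' transcriptionally active — nucleus-only cells are grouped here).
#'
#' @param spots tibble from [detect_spots()].
#' @param nuclei nucleus `label_mask`; nucleus labels match cell labels.
#' @param cells cell `label_mask`.
#' @return A list with `spots` (input tibble plus `cell` and `compartment`),
#'   `categories` (tibble `cell`, `category`), `fractions` (named
#'   percentages over retained cells, summing to 100) and `n_outside`.
#' @export
classify_notch <- function(spots, nuclei, cells) {
  if (!all(dim(nuclei$labels) == dim(cells$labels)))
    abort("masks are not aligned")
  ret <- cells$retained
  if (nrow(spots) > 0) {
    cell_at <- cells$labels[cbind(spots$r, spots$c)]
    nuc_at <- nuclei$labels[cbind(spots$r, spots$c)]
    compartment <- ifelse(cell_at == 0 | !(cell_at %in% ret), "outside",
                          ifelse(nuc_at == cell_at, "nuclear", "cytoplasmic"))
    spots$cell <- ifelse(compartment == "outside", NA_integer_, cell_at)
    spots$compartment <- compartment
  } else {
    spots$cell <- integer()
    spots$compartment <- character()
  }
  cat_of <- function(i) {
    s <- spots[!is.na(spots$cell) & spots$cell == i, ]
    if (nrow(s) == 0) "Nneg"
    else if (any(s$compartment == "nuclear")) "Nnuc"
    else "Ncyt"
  }
  categories <- tibble(cell = ret,
                       category = vapply(ret, cat_of, character(1)))
  n <- max(nrow(categories), 1L)
  fractions <- c(Nneg = 100 * sum(categories$category == "Nneg") / n,
                 Ncyt = 100 * sum(categories$category == "Ncyt") / n,
                 Nnuc = 100 * sum(categories$category == "Nnuc") / n)
  list(spots = spots, categories = categories, fractions = fractions,
       n_outside = sum(spots$compartment == "outside"))
}

#' Cell-contact adjacency graph
#'
#' Two cells are adjacent when at least `min_shared_border` 4-connected
#' pixel pairs straddle their labels; this suppresses corner-touch
#' artifacts. The graph is undirected with no self-edges and covers all
#' labels present in the mask (including non-retained border cells, whose
#' contacts are real).
#'
#' @param cells cell `label_mask` (confluent labeling).
#' @param min_shared_border minimum shared border length in px.
#' @return An [igraph::graph] whose vertex names are cell labels.
#' @export
cell_adjacency <- function(cells, min_shared_border = 3L) {
  edges <- adjacency_from_labels(cells$labels, min_shared = min_shared_border)
  labs <- sort(unique(cells$labels[cells$labels > 0]))
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(labs))
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(cbind(match(edges$i, labs),
                                      match(edges$j, labs))))
  g
}

#' NOTCH clusters: contiguous groups of nuclear-active cells
#'
#' Connected components of the adjacency subgraph induced by the `Nnuc`
#' cells; isolated `Nnuc` cells count as clusters of size 1. The four
#' context features summarize cluster structure: number of clusters, mean
#' and maximum cluster size, and the fraction of `Nnuc` cells sitting in
#' clusters of size >= 2.
#'
#' @param graph adjacency graph from [cell_adjacency()].
#' @param categories tibble (`cell`, `category`) from [classify_notch()].
#' @return An object of class `cluster_summary`: `clusters` (list of
#'   integer cell-id vectors) and `features` (named numeric vector
#'   `n_clusters`, `mean_size`, `max_size`, `frac_in_multi`).
#' @export
#' @examples
#' g <- igraph::make_graph(~ 1 - 2, 2 - 3, 4)
#' cats <- tibble::tibble(cell = 1:4, category = rep("Nnuc", 4))
#' notch_clusters(g, cats)$features
notch_clusters <- function(graph, categories) {
  nnuc <- categories$cell[categories$category == "Nnuc"]
  if (length(nnuc) == 0)
    return(structure(list(clusters = list(),
                          features = c(n_clusters = 0, mean_size = 0,
                                       max_size = 0, frac_in_multi = 0)),
                     class = "cluster_summary"))
  keep <- intersect(as.character(nnuc), igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, keep)
  comp <- igraph::components(sub)
  clusters <- split(as.integer(igraph::V(sub)$name), comp$membership)
  clusters <- unname(clusters)
  # Nnuc cells absent from the graph (degenerate masks) become singletons
  missing <- setdiff(nnuc, as.integer(keep))
  clusters <- c(clusters, lapply(missing, identity))
  sizes <- lengths(clusters)
  structure(list(
    clusters = clusters,
    features = c(n_clusters = length(clusters),
                 mean_size = mean(sizes),
                 max_size = max(sizes),
                 frac_in_multi = sum(sizes[sizes >= 2]) / sum(sizes))),
    class = "cluster_summary")
}
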