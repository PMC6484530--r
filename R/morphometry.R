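#' Shape features of a binary object
#'
#' Area from the pixel count, perimeter by a 4-direction Crofton estimate,
#' roundness `4 pi A / P^2` clipped to 1, and length/width from the
#' eigenvalues of the pixel-coordinate covariance using the
#' ellipse-equivalent axis convention `4 sqrt(lambda)` (for a solid
#' ellipse, this recovers the full major/minor axis lengths).
#'
#' @param mask logical or 0/1 matrix containing one object of >= 4 px.
#' @param pixel_size micrometres per pixel.
#' @return A one-row tibble: `area` (um^2), `perimeter` (um), `roundness`,
#'   `length` (um), `width` (um), `width_length_ratio`.
#' @export
#' @examples
#' m <- matrix(FALSE, 50, 50); m[10:40, 20:30] <- TRUE
#' shape_features(m, 1)$width_length_ratio
shape_features <- function(mask, pixel_size) {
  idx <- which(mask != 0)
  if (length(idx) < 4) abort("degenerate object: fewer than 4 pixels")
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- length(idx) * pixel_size^2
  per <- crofton_perimeter(mask) * pixel_size
  roundness <- min(1, 4 * pi * area / per^2)
  cv <- stats::cov(cbind(r, cc)) * (length(r) - 1) / length(r)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 1 / 12)  # single-pixel-row floor (uniform pixel variance)
  len <- 4 * sqrt(ev[1]) * pixel_size
  wid <- 4 * sqrt(ev[2]) * pixel_size
  tibble(area = area, perimeter = per, roundness = roundness,
         length = len, width = wid, width_length_ratio = wid / len)
}

#' STAR intensity-distribution features
#'
#' Nine Symmetry / Threshold-compactness / Axial / Radial descriptors of
#' how intensity is distributed inside a cell region:
#' \describe{
#'   \item{symmetry}{`1 - sum |I - I_mirror| / (sum I + sum I_mirror)`,
#'     mirroring across the principal axis of the intensity-weighted
#'     coordinate distribution through the intensity centroid; 1 for a
#'     mirror-symmetric pattern.}
#'   \item{tc30..tc60}{threshold compactness at fractions f of the in-mask
#'     mean intensity: with S(f) the pixels at intensity >= f * mean,
#'     `TC = (|S| / 2 pi) / m2` where `m2` is the mean squared distance of
#'     S to its centroid — 1 for a uniform disk, clipped to (0, 1]; |S| <= 4
#'     is defined as 1.}
#'   \item{axial_ratio}{`sqrt(lambda2 / lambda1)` of the intensity-weighted
#'     coordinate covariance.}
#'   \item{axial_small_length}{`4 sqrt(lambda2) * pixel_size` (um).}
#'   \item{radial_mean}{intensity-weighted mean of the normalized border
#'     distance `d_hat` (distance to the cell border divided by its
#'     maximum); 0 = signal at the border, 1 = at the center.}
#'   \item{radial_rel_dev}{intensity-weighted standard deviation of
#'     `d_hat`.}
#' }
#' A region with zero total intensity yields all features 0.
#'
#' @param channel 2D intensity matrix.
#' @param mask logical matrix (>= 16 px) delimiting the cell region.
#' @param pixel_size micrometres per pixel.
#' @return A one-row tibble with the nine features.
#' @export
star_features <- function(channel, mask, pixel_size) {
  idx <- which(mask != 0)
  if (length(idx) < 16) abort("mask must contain >= 16 pixels")
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  I <- pmax(channel[idx], 0)
  tot <- sum(I)
  zero <- tibble(symmetry = 0, tc30 = 0, tc40 = 0, tc50 = 0, tc60 = 0,
                 axial_ratio = 0, axial_small_length = 0,
                 radial_mean = 0, radial_rel_dev = 0)
  if (tot <= 0) return(zero)

  mr <- sum(I * r) / tot; mc <- sum(I * cc) / tot
  cv <- matrix(c(sum(I * (r - mr)^2), sum(I * (r - mr) * (cc - mc)),
                 sum(I * (r - mr) * (cc - mc)), sum(I * (cc - mc)^2)),
               2, 2) / tot
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-9)
  axis1 <- eg$vectors[, 1]

  # symmetry: reflect coordinates across the principal axis, sample I there
  u <- (r - mr) * axis1[1] + (cc - mc) * axis1[2]
  v <- -(r - mr) * axis1[2] + (cc - mc) * axis1[1]
  # reflected point = centroid + u*axis1 - v*axis2, axis2 = (-axis1[2], axis1[1])
  ref_r <- round(mr + u * axis1[1] + v * axis1[2])
  ref_c <- round(mc + u * axis1[2] - v * axis1[1])
  Iref <- numeric(length(idx))
  ok <- ref_r >= 1 & ref_r <= nr & ref_c >= 1 & ref_c <= ncol(mask)
  lin <- (ref_c[ok] - 1L) * nr + ref_r[ok]
  inmask <- mask[lin] != 0
  Iref[ok][inmask] <- pmax(channel[lin[inmask]], 0)
  symmetry <- 1 - sum(abs(I - Iref)) / (sum(I) + sum(Iref))

  tc <- vapply(c(0.3, 0.4, 0.5, 0.6), function(f) {
    sel <- I >= f * mean(I)
    if (sum(sel) <= 4) return(1)
    sr <- r[sel]; sc2 <- cc[sel]
    m2 <- mean((sr - mean(sr))^2 + (sc2 - mean(sc2))^2)
    min(1, (sum(sel) / (2 * pi)) / m2)
  }, numeric(1))

  axial_ratio <- sqrt(lam[2] / lam[1])
  axial_small_length <- 4 * sqrt(lam[2]) * pixel_size

  # normalized distance-to-border inside the mask
  bb <- bbox_of(idx, nr, ncol(mask), pad = 1L)
  sub <- mask[bb$r0:bb$r1, bb$c0:bb$c1] != 0
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(sub))))
  d <- dm[cbind(r - bb$r0 + 1L, cc - bb$c0 + 1L)]
  dhat <- d / max(d, 1e-9)
  rmean <- sum(I * dhat) / tot
  rdev <- sqrt(sum(I * (dhat - rmean)^2) / tot)

  tibble(symmetry = symmetry, tc30 = tc[1], tc40 = tc[2], tc50 = tc[3],
         tc60 = tc[4], axial_ratio = axial_ratio,
         axial_small_length = axial_small_length,
         radial_mean = rmean, radial_rel_dev = rdev)
}

#' Assemble the per-cell record table for one area
#'
#' Joins every analysis stage into one row per retained cell: cell and
#' nucleus shape features, nucleus/cell area ratio, STAR features of the
#' junction and spot channels over the cell region, compartment mean
#' intensities, the junction-object count, the NOTCH category and the
#' NOTCH cluster id. Border-excluded cells are absent (their pixels still
#' informed adjacency). Rows are ordered by cell id.
#'
#' @param field the analyzed [field_image()].
#' @param nuclei,cells `label_mask` objects from segmentation.
#' @param jset `junction_set` from [detect_junctions()].
#' @param notch result of [classify_notch()].
#' @param clusters `cluster_summary` from [notch_clusters()].
#' @return A tibble, one row per retained cell.
#' @export
build_cell_table <- function(field, nuclei, cells, jset, notch, clusters) {
  if (!all(dim(nuclei$labels) == dim(cells$labels)))
    abort("stage outputs come from mismatched areas")
  ret <- cells$retained
  ps <- cells$pixel_size
  nr <- nrow(cells$labels)
  cluster_of <- integer(0)
  if (length(clusters$clusters) > 0)
    for (ci in seq_along(clusters$clusters))
      cluster_of[as.character(clusters$clusters[[ci]])] <- ci

  jch <- field$channels[["junction"]]
  sch <- field$channels[["spots"]]
  nch <- field$channels[["nuclear"]]

  rows <- lapply(ret, function(i) {
    idx <- which(cells$labels == i)
    bb <- bbox_of(idx, nr, ncol(cells$labels), pad = 2L)
    sl <- function(m) m[bb$r0:bb$r1, bb$c0:bb$c1]
    cmask <- sl(cells$labels) == i
    nmask <- sl(nuclei$labels) == i
    if (sum(nmask) < 4 || sum(cmask) < 16) return(NULL)
    csh <- shape_features(cmask, ps)
    nsh <- shape_features(nmask, ps)
    names(csh) <- paste0("cell_", names(csh))
    names(nsh) <- paste0("nuc_", names(nsh))
    stj <- star_features(sl(jch), cmask, ps)
    names(stj) <- paste0("star_jct_", names(stj))
    sts <- star_features(sl(sch), cmask, ps)
    names(sts) <- paste0("star_spot_", names(sts))
    cyt <- cmask & !nmask
    jrow <- jset$per_cell[jset$per_cell$cell == i, ]
    cat_i <- notch$categories$category[notch$categories$cell == i]
    dplyr::bind_cols(
      tibble(cell = i),
      csh, nsh,
      tibble(nuc_cell_area_ratio = nsh$nuc_area / csh$cell_area),
      stj, sts,
      tibble(
        mean_junction_in_cell = mean(sl(jch)[cmask]),
        mean_spots_in_cytoplasm = if (any(cyt)) mean(sl(sch)[cyt]) else 0,
        mean_spots_in_nucleus = mean(sl(sch)[nmask]),
        mean_nuclear_in_nucleus = mean(sl(nch)[nmask]),
        jn_count = if (nrow(jrow)) jrow$jn_count else 0L,
        jct_object_area = if (nrow(jrow)) jrow$mean_object_area_px * ps^2 else 0,
        jct_ring_frac = if (nrow(jrow)) jrow$ring_frac else 0,
        category = if (length(cat_i)) cat_i else "Nneg",
        cluster_id = unname(cluster_of[as.character(i)][1])))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- empty_cell_table()
  dplyr::arrange(out, .data$cell)
}

empty_cell_table <- function() {
  sh <- c("area", "perimeter", "roundness", "length", "width",
          "width_length_ratio")
  st <- c("symmetry", "tc30", "tc40", "tc50", "tc60", "axial_ratio",
          "axial_small_length", "radial_mean", "radial_rel_dev")
  cols <- c("cell", paste0("cell_", sh), paste0("nuc_", sh),
            "nuc_cell_area_ratio", paste0("star_jct_", st),
            paste0("star_spot_", st),
            "mean_junction_in_cell", "mean_spots_in_cytoplasm",
            "mean_spots_in_nucleus", "mean_nuclear_in_nucleus",
            "jn_count", "jct_object_area", "jct_ring_frac",
            "category", "cluster_id")
  out <- as_tibble(stats::setNames(
    lapply(cols, function(x)
      if (x == "category") character() else numeric()), cols))
  out$cell <- integer(); out$cluster_id <- integer()
  out
}

#' The canonical 47-feature area-level registry
#'
#' Enumerates the ordered default set of 47 area-level features: 6 cell
#' shape + 6 nucleus shape + 1 nucleus/cell area ratio + 9 STAR features
#' of the junction channel + 9 STAR of the spot channel + 4 mean
#' intensities + 4 junction statistics (J_n, mean junction-object area,
#' boundary-ring area fraction, mean junction intensity) + 3 NOTCH
#' category percentages + 4 NOTCH cluster features + the retained cell
#' count. Per-cell features are aggregated over the area's cells by mean;
#' the rest are area-level statistics by definition.
#'
#' @return A tibble with columns `feature`, `family`, `aggregation`
#'   (`"cell_mean"` or `"area_stat"`) and `source` (the per-cell column or
#'   area statistic it is computed from), with exactly 47 rows.
#' @export
#' @examples
#' nrow(feature_registry())  # 47
feature_registry <- function() {
  sh <- c("area", "perimeter", "roundness", "length", "width",
          "width_length_ratio")
  st <- c("symmetry", "tc30", "tc40", "tc50", "tc60", "axial_ratio",
          "axial_small_length", "radial_mean", "radial_rel_dev")
  reg <- dplyr::bind_rows(
    tibble(feature = paste0("cell_", sh), family = "cell_shape",
           aggregation = "cell_mean", source = paste0("cell_", sh)),
    tibble(feature = paste0("nuc_", sh), family = "nucleus_shape",
           aggregation = "cell_mean", source = paste0("nuc_", sh)),
    tibble(feature = "nuc_cell_area_ratio", family = "nucleus_shape_ratio",
           aggregation = "cell_mean", source = "nuc_cell_area_ratio"),
    tibble(feature = paste0("star_jct_", st), family = "star_junction",
           aggregation = "cell_mean", source = paste0("star_jct_", st)),
    tibble(feature = paste0("star_spot_", st), family = "star_spot",
           aggregation = "cell_mean", source = paste0("star_spot_", st)),
    tibble(feature = c("mean_junction_in_cell", "mean_spots_in_cytoplasm",
                       "mean_spots_in_nucleus", "mean_nuclear_in_nucleus"),
           family = "mean_intensity", aggregation = "cell_mean",
           source = c("mean_junction_in_cell", "mean_spots_in_cytoplasm",
                      "mean_spots_in_nucleus", "mean_nuclear_in_nucleus")),
    tibble(feature = c("jn", "jct_mean_object_area", "jct_ring_area_fraction",
                       "jct_mean_intensity"),
           family = "junction_stat", aggregation = "area_stat",
           source = c("junction_summary", "junction_objects",
                      "junction_ring", "junction_intensity")),
    tibble(feature = c("pct_nneg", "pct_ncyt", "pct_nnuc"),
           family = "notch_category", aggregation = "area_stat",
           source = "category_fractions"),
    tibble(feature = c("notch_n_clusters", "notch_mean_cluster_size",
                       "notch_max_cluster_size", "notch_frac_in_multi"),
           family = "notch_cluster", aggregation = "area_stat",
           source = "cluster_features"),
    tibble(feature = "cell_count", family = "population",
           aggregation = "area_stat", source = "n_retained"))
  stopifnot(nrow(reg) == 47L, !anyDuplicated(reg$feature))
  reg
}
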