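#' Enhance junction signal with a Hessian ridge filter
#'
#' Computes a line-likeness map at scale `ridge_sigma`: the image is
#' convolved with Gaussian second-derivative kernels, and each pixel scores
#' the magnitude of the most negative eigenvalue of the 2x2 Hessian,
#' clipped at zero. Bright thin lines (adherens junctions stained for
#' VE-cadherin) respond strongly; flat regions score 0. The response is
#' invariant to additive intensity offsets.
#'
#' @param junction_channel 2D numeric matrix.
#' @param params a [junction_params()].
#' @return A non-negative ridge map, same shape as the input.
#' @export
junction_enhance <- function(junction_channel, params = junction_params()) {
  s <- params$ridge_sigma
  k <- gaussian_deriv_kernels(s)
  ixx <- conv2_sep(junction_channel, k$d2, k$g)
  iyy <- conv2_sep(junction_channel, k$g, k$d2)
  ixy <- conv2_sep(junction_channel, k$d1, k$d1)
  tr <- ixx + iyy
  disc <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  lam_min <- (tr - disc) / 2
  out <- pmax(-lam_min, 0)
  # suppress float residue so flat regions are exactly zero
  out[out < 1e-9 * max(abs(junction_channel))] <- 0
  out
}

# separable Gaussian derivative kernels at scale sigma (sigma-normalized)
gaussian_deriv_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  d1 <- -x / sigma^2 * g
  d2 <- (x^2 / sigma^2 - 1) / sigma^2 * g
  d2 <- d2 - sum(d2) / length(d2)  # exact zero response to constants
  # scale-normalize (gamma = 2) so responses are comparable across scales
  list(g = g, d1 = d1 * sigma, d2 = d2 * sigma^2)
}

# separable convolution with replicate padding
conv2_sep <- function(x, kr, kc) {
  x1 <- apply_1d(x, kr, along = 1)
  apply_1d(x1, kc, along = 2)
}

apply_1d <- function(x, k, along) {
  r <- (length(k) - 1L) %/% 2L
  if (along == 2) x <- t(x)
  n <- nrow(x)
  pad <- rbind(x[rep(1L, r), , drop = FALSE], x,
               x[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(x))
  for (i in seq_along(k))
    out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  if (along == 2) t(out) else out
}

#' Detect per-cell junction objects
#'
#' Thresholds the ridge map (Otsu on the nonzero response by default) into
#' binary junction pixels, then for every retained cell intersects them
#' with that cell's boundary ring — the pixels inside the cell within
#' `ring_width` px of its border. The 8-connected components of each
#' intersection with area at least `min_object_area` are that cell's
#' junction objects. Counting is per cell, so an unbroken shared border
#' contributes one object to each adjacent cell.
#'
#' @param ridge_map output of [junction_enhance()].
#' @param cells cell `label_mask`.
#' @param nuclei nucleus `label_mask` (used for the object mask bookkeeping).
#' @param params a [junction_params()].
#' @return An object of class `junction_set`: a labeled junction mask, the
#'   per-cell counts tibble (`cell`, `jn_count`, `mean_object_area_px`,
#'   `ring_area_px`, `ring_frac`), and the binary ridge mask.
#' @export
detect_junctions <- function(ridge_map, cells, nuclei,
                             params = junction_params()) {
  if (!any(cells$labels > 0)) abort("empty cells mask")
  thr <- switch(params$edge_threshold,
                `otsu-on-ridge` = {
                  nz <- ridge_map[ridge_map > 0]
                  if (length(nz) < 2) Inf else otsu_threshold(nz_mat(nz))
                },
                fixed = params$fixed_threshold %||%
                  abort("fixed_threshold required"))
  binary <- ridge_map >= thr & ridge_map > 0
  lab <- cells$labels
  nr <- nrow(lab); nc <- ncol(lab)
  counts <- vector("list", length(cells$retained))
  jmask <- matrix(0L, nr, nc)
  next_lab <- 0L
  for (ii in seq_along(cells$retained)) {
    i <- cells$retained[ii]
    idx <- which(lab == i)
    bb <- bbox_of(idx, nr, nc, pad = 1L)
    sub <- lab[bb$r0:bb$r1, bb$c0:bb$c1] == i
    dm <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(sub))))
    ring <- sub & dm <= params$ring_width
    inter <- ring & binary[bb$r0:bb$r1, bb$c0:bb$c1]
    comp <- label8(inter)
    sizes <- if (max(comp) > 0) tabulate(comp[comp > 0]) else integer()
    keep <- which(sizes >= params$min_object_area)
    # record kept objects into the global junction mask
    for (kk in keep) {
      next_lab <- next_lab + 1L
      sel <- which(comp == kk)
      rr <- ((sel - 1L) %% nrow(comp)) + bb$r0
      cc2 <- ((sel - 1L) %/% nrow(comp)) + bb$c0
      jmask[cbind(rr, cc2)] <- next_lab
    }
    counts[[ii]] <- tibble(
      cell = i, jn_count = length(keep),
      mean_object_area_px = if (length(keep)) mean(sizes[keep]) else 0,
      ring_area_px = sum(ring), ring_frac = sum(ring) / length(idx))
  }
  per_cell <- dplyr::bind_rows(counts)
  if (nrow(per_cell) == 0)
    per_cell <- tibble(cell = integer(), jn_count = integer(),
                       mean_object_area_px = numeric(),
                       ring_area_px = numeric(), ring_frac = numeric())
  structure(list(junction_mask = label_mask(relabel_rowmajor(jmask),
                                            "junctions", cells$pixel_size),
                 per_cell = per_cell, binary = binary, threshold = thr),
            class = "junction_set")
}

nz_mat <- function(v) matrix(v, nrow = 1)

#' Junction summary statistic J_n
#'
#' `J_n` is the average number of discrete VE-cadherin-positive junction
#' objects per nucleus: total junction objects over retained cells divided
#' by the number of retained nuclei. High values indicate discontinuous
#' ("active") junctions, low values continuous ("stable") ones.
#'
#' @param jset a `junction_set` from [detect_junctions()].
#' @param n_nuclei number of retained nuclei, >= 1.
#' @return A list with `jn` (the statistic) and `per_cell` (the count
#'   distribution tibble).
#' @export
#' @examples
#' js <- structure(list(per_cell = tibble::tibble(cell = 1:4,
#'   jn_count = c(3L, 3L, 3L, 3L))), class = "junction_set")
#' junction_summary(js, n_nuclei = 4)$jn  # 3
junction_summary <- function(jset, n_nuclei) {
  if (n_nuclei < 1) abort("J_n undefined: n_nuclei must be >= 1")
  list(jn = sum(jset$per_cell$jn_count) / n_nuclei,
       per_cell = jset$per_cell)
}
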