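#' Sample a ground-truthed synthetic confluent monolayer
#'
#' Generates the geometric and categorical ground truth for one field of a
#' confluent endothelial monolayer: a Voronoi tessellation of
#' Poisson-disc-sampled seeds under an anisotropically stretched metric
#' (factor `elongation`, along the column axis), with boundaries perturbed by
#' a smooth displacement field of amplitude `jaggedness`; one nucleus
#' ellipse per cell aligned to the cell's long axis with area about
#' `nucleus_area_fraction` times the cell area; a true NOTCH category per
#' cell drawn from `category_probs`; and activation-spot centers placed in
#' the compartments the category requires (counts `1 + Poisson(rate - 1)`).
#'
#' Deterministic for fixed `(params, seed)`.
#'
#' @param params a [scene_params()] object.
#' @param seed integer random seed.
#' @return An object of class `gt_scene` with elements:
#'   \describe{
#'     \item{label_mask}{integer matrix, ground-truth cell labels 1..K
#'       (row-major centroid order), covering the full frame.}
#'     \item{cells}{tibble: `cell`, centroid `(r, c)`, `category`
#'       (Nneg/Ncyt/Nnuc).}
#'     \item{nuclei}{tibble of per-cell nucleus ellipses: center, semi-axes
#'       `(a, b)` in px, orientation `theta` (radians).}
#'     \item{spots}{tibble: `cell`, `compartment`, center `(r, c)`.}
#'     \item{adjacency}{tibble of unordered adjacent cell-id pairs `(i, j)`.}
#'     \item{polygons}{list of closed boundary polygons (px), one per cell.}
#'     \item{params, seed}{inputs, recorded for provenance.}
#'   }
#' @export
#' @examples
#' sc <- sample_monolayer(scene_params(frame_size = c(128, 128),
#'                                     target_cell_count = 6L), seed = 1)
#' nrow(sc$cells)
sample_monolayer <- function(params, seed) {
  validate_scene_params(params)
  set.seed(as.integer(seed))
  nr <- params$frame_size[1]; nc <- params$frame_size[2]
  n <- params$target_cell_count
  empty <- function() {
    structure(list(
      label_mask = matrix(0L, nr, nc),
      cells = tibble(cell = integer(), r = numeric(), c = numeric(),
                     category = character()),
      nuclei = tibble(cell = integer(), r = numeric(), c = numeric(),
                      a = numeric(), b = numeric(), theta = numeric()),
      spots = tibble(cell = integer(), compartment = character(),
                     r = numeric(), c = numeric()),
      adjacency = tibble(i = integer(), j = integer()),
      polygons = list(), params = params, seed = as.integer(seed)),
      class = "gt_scene")
  }
  if (n == 0L) return(empty())

  # Poisson-disc seeds in the stretched coordinate system (columns divided
  # by elongation), dart throwing with a density-derived exclusion radius.
  el <- params$elongation
  wr <- nr; wc <- nc / el
  dmin <- 0.68 * sqrt(wr * wc / n)
  if (dmin < 2) abort("infeasible density: frame too small for target_cell_count")
  sr <- numeric(0); sc_ <- numeric(0)
  tries <- 0L; max_tries <- 400L * n
  while (length(sr) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("infeasible density: could not place target_cell_count seeds")
    cr <- stats::runif(1, 1, wr); ccol <- stats::runif(1, 1, wc)
    if (length(sr) == 0 ||
        min((sr - cr)^2 + (sc_ - ccol)^2) >= dmin^2) {
      sr <- c(sr, cr); sc_ <- c(sc_, ccol)
    }
  }

  # Smooth boundary-perturbation displacement fields.
  disp <- function() {
    if (params$jaggedness <= 0) return(matrix(0, nr, nc))
    f <- gblur_mat(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 6)
    f * (params$jaggedness / stats::sd(f))
  }
  dr <- disp(); dc <- disp()

  # Nearest stretched-metric seed per (displaced) pixel.
  X <- matrix(rep(seq_len(nr), nc), nr, nc) + dr
  Y <- (matrix(rep(seq_len(nc), each = nr), nr, nc) + dc) / el
  best <- matrix(Inf, nr, nc); lab <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    d <- (X - sr[k])^2 + (Y - sc_[k])^2
    w <- d < best
    best[w] <- d[w]; lab[w] <- k
  }
  # displacement can strand isolated pixels: keep each cell's largest
  # 4-connected piece, then fill strays from their neighborhood majority
  lab <- clean_label_mask(lab)
  lab <- relabel_rowmajor(lab)
  k <- max(lab)

  # Per-cell geometry from pixel moments.
  idx_by <- split(seq_len(nr * nc), lab[seq_len(nr * nc)])
  idx_by[["0"]] <- NULL
  cells <- purrr::map_dfr(seq_len(k), function(i) {
    idx <- idx_by[[as.character(i)]]
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    tibble(cell = i, r = mean(r), c = mean(cc), area_px = length(idx))
  })

  # Nucleus ellipses: centered at the cell centroid, aligned with the cell's
  # principal axis, shrunk until fully inside the cell.
  nuclei <- purrr::map_dfr(seq_len(k), function(i) {
    idx <- idx_by[[as.character(i)]]
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    cv <- stats::cov(cbind(r, cc)) * (length(r) - 1) / length(r)
    eg <- eigen(cv, symmetric = TRUE)
    theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    aspect <- sqrt(max(eg$values[1], 1e-9) / max(eg$values[2], 1e-9))
    aspect <- min(aspect, 3)
    area <- params$nucleus_area_fraction * length(idx)
    b <- sqrt(area / (pi * aspect)); a <- aspect * b
    mr <- mean(r); mc <- mean(cc)
    for (s in seq(1, 0.3, by = -0.05)) {
      ok <- ellipse_inside_cell(lab, i, mr, mc, a * s, b * s, theta)
      if (ok) return(tibble(cell = i, r = mr, c = mc,
                            a = a * s, b = b * s, theta = theta))
    }
    tibble(cell = i, r = mr, c = mc, a = 2, b = 2, theta = theta)
  })

  # True category and spot placement.
  cats <- c("Nneg", "Ncyt", "Nnuc")
  category <- sample(cats, k, replace = TRUE, prob = params$category_probs)
  cells$category <- category
  spots <- purrr::map_dfr(seq_len(k), function(i) {
    cat_i <- category[i]
    if (cat_i == "Nneg") return(NULL)
    nu <- nuclei[nuclei$cell == i, ]
    out <- NULL
    if (cat_i == "Nnuc") {
      n_nuc <- 1L + stats::rpois(1, max(params$spot_rate_nuc - 1, 0))
      pts <- sample_in_ellipse(n_nuc, nu$r, nu$c, nu$a, nu$b, nu$theta)
      out <- tibble(cell = i, compartment = "nuclear",
                    r = pts[, 1], c = pts[, 2])
      n_cyt <- stats::rpois(1, max(params$spot_rate_cyt - 1, 0))
    } else {
      n_cyt <- 1L + stats::rpois(1, max(params$spot_rate_cyt - 1, 0))
    }
    if (n_cyt > 0) {
      pts <- sample_in_cytoplasm(n_cyt, lab, i, nu, idx_by[[as.character(i)]], nr)
      if (!is.null(pts))
        out <- dplyr::bind_rows(out, tibble(cell = i, compartment = "cytoplasmic",
                                            r = pts[, 1], c = pts[, 2]))
    }
    out
  })
  if (nrow(spots) == 0)
    spots <- tibble(cell = integer(), compartment = character(),
                    r = numeric(), c = numeric())

  adjacency <- adjacency_from_labels(lab, min_shared = 1L)
  polygons <- trace_polygons(lab, k)

  structure(list(label_mask = lab,
                 cells = cells[, c("cell", "r", "c", "category")],
                 nuclei = nuclei, spots = spots, adjacency = adjacency,
                 polygons = polygons, params = params,
                 seed = as.integer(seed)),
            class = "gt_scene")
}

# Keep only the largest 4-connected piece per label; reassign stray pixels
# to the most frequent neighboring label.
clean_label_mask <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  stray <- matrix(FALSE, nr, nc)
  for (i in sort(unique(lab[lab > 0]))) {
    m <- lab == i
    cm <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m))))
    if (max(cm) > 1L) {
      tab <- tabulate(cm[cm > 0])
      keep <- which.max(tab)
      stray[m & cm != keep] <- TRUE
    }
  }
  if (!any(stray)) return(lab)
  lab[stray] <- 0L
  # iterative majority fill from 4-neighbors
  repeat {
    idx <- which(lab == 0L)
    if (length(idx) == 0L) break
    filled <- FALSE
    for (p in idx) {
      r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
      nb <- c(if (r > 1) lab[p - 1L], if (r < nr) lab[p + 1L],
              if (cc > 1) lab[p - nr], if (cc < nc) lab[p + nr])
      nb <- nb[nb > 0]
      if (length(nb)) { lab[p] <- as.integer(names(which.max(table(nb)))); filled <- TRUE }
    }
    if (!filled) break
  }
  lab
}

ellipse_inside_cell <- function(lab, i, cr, cc, a, b, theta) {
  nr <- nrow(lab); nc <- ncol(lab)
  rr <- max(1L, floor(cr - a)):min(nr, ceiling(cr + a))
  ccs <- max(1L, floor(cc - a)):min(nc, ceiling(cc + a))
  if (cr - a < 1 || cr + a > nr || cc - a < 1 || cc + a > nc) return(FALSE)
  g <- expand.grid(r = rr, c = ccs)
  dx <- g$r - cr; dy <- g$c - cc
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  all(lab[cbind(g$r[inside], g$c[inside])] == i)
}

sample_in_ellipse <- function(n, cr, cc, a, b, theta) {
  # uniform in the ellipse, margin so rendered spots stay mostly nuclear
  t <- stats::runif(n, 0, 2 * pi); rad <- sqrt(stats::runif(n))
  u <- 0.8 * a * rad * cos(t); v <- 0.8 * b * rad * sin(t)
  cbind(cr + cos(theta) * u - sin(theta) * v,
        cc + sin(theta) * u + cos(theta) * v)
}

sample_in_cytoplasm <- function(n, lab, i, nu, idx, nr) {
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  dx <- r - nu$r; dy <- cc - nu$c
  u <- cos(nu$theta) * dx + sin(nu$theta) * dy
  v <- -sin(nu$theta) * dx + cos(nu$theta) * dy
  # outside an expanded ellipse and away from the cell border
  outside <- (u / (nu$a + 3))^2 + (v / (nu$b + 3))^2 > 1
  er <- erode_ok(lab, i, r, cc)
  ok <- which(outside & er)
  if (length(ok) == 0L) ok <- which(outside)
  if (length(ok) == 0L) return(NULL)
  pick <- ok[sample.int(length(ok), n, replace = TRUE)]
  cbind(r[pick], cc[pick])
}

# TRUE for pixels of cell i whose 4-neighborhood is entirely cell i
erode_ok <- function(lab, i, r, cc) {
  nr <- nrow(lab); nc <- ncol(lab)
  ok <- r > 2 & r < nr - 1 & cc > 2 & cc < nc - 1
  ok[ok] <- lab[cbind(r[ok] - 1L, cc[ok])] == i &
    lab[cbind(r[ok] + 1L, cc[ok])] == i &
    lab[cbind(r[ok], cc[ok] - 1L)] == i &
    lab[cbind(r[ok], cc[ok] + 1L)] == i
  ok
}

# Unordered adjacent label pairs from 4-connected straddling pixel pairs.
adjacency_from_labels <- function(lab, min_shared = 1L) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, ]; b <- lab[-1, ]
  h <- cbind(as.vector(a), as.vector(b))
  a <- lab[, -nc]; b <- lab[, -1]
  v <- cbind(as.vector(a), as.vector(b))
  pr <- rbind(h, v)
  pr <- pr[pr[, 1] != pr[, 2] & pr[, 1] > 0 & pr[, 2] > 0, , drop = FALSE]
  if (nrow(pr) == 0)
    return(tibble(i = integer(), j = integer()))
  key <- paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  tab <- table(key)
  keep <- names(tab)[tab >= min_shared]
  if (length(keep) == 0) return(tibble(i = integer(), j = integer()))
  ij <- do.call(rbind, strsplit(keep, " "))
  out <- tibble(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  dplyr::arrange(out, .data$i, .data$j)
}

trace_polygons <- function(lab, k) {
  if (k == 0) return(list())
  oc <- EBImage::ocontour(EBImage::Image(lab))
  # ocontour returns 0-based (x, y) = (row-1, col-1); convert to 1-based px
  lapply(seq_len(k), function(i) {
    p <- oc[[i]]
    cbind(r = p[, 1] + 1, c = p[, 2] + 1)
  })
}

#' Render a synthetic field image from a ground-truth scene
#'
#' Draws the three stained channels of a scene: (1) nuclear — filled nucleus
#' ellipses; (2) junction — cell-cell border polylines with a Gaussian
#' cross-profile, each border split into segments of `segment_length` px
#' that are deleted independently with probability
#' `junction_fragmentation`; (3) spots — isotropic Gaussians at the true
#' spot centers. All channels then receive a global optical blur
#' (`psf_sigma`), the background offset, and additive Gaussian noise, and
#' are clipped to the 16-bit range. Deterministic for fixed inputs.
#'
#' @param scene a `gt_scene` from [sample_monolayer()].
#' @param params the [scene_params()] used to build the scene.
#' @param seed integer seed for fragmentation and noise.
#' @return A [field_image()] with channels `nuclear`, `junction`, `spots`.
#' @export
render_field <- function(scene, params, seed) {
  stopifnot(inherits(scene, "gt_scene"))
  if (!all(dim(scene$label_mask) == params$frame_size))
    abort("scene is inconsistent with params frame_size")
  set.seed(as.integer(seed))
  nr <- params$frame_size[1]; nc <- params$frame_size[2]

  nuclear <- matrix(0, nr, nc)
  if (nrow(scene$nuclei) > 0) {
    for (i in seq_len(nrow(scene$nuclei))) {
      nu <- scene$nuclei[i, ]
      rr <- max(1L, floor(nu$r - nu$a)):min(nr, ceiling(nu$r + nu$a))
      ccs <- max(1L, floor(nu$c - nu$a)):min(nc, ceiling(nu$c + nu$a))
      g <- expand.grid(r = rr, c = ccs)
      dx <- g$r - nu$r; dy <- g$c - nu$c
      u <- cos(nu$theta) * dx + sin(nu$theta) * dy
      v <- -sin(nu$theta) * dx + cos(nu$theta) * dy
      inside <- (u / nu$a)^2 + (v / nu$b)^2 <= 1
      nuclear[cbind(g$r[inside], g$c[inside])] <- params$nuclear_amp
    }
  }

  junction <- render_junction_channel(scene, params)

  spots <- matrix(0, nr, nc)
  if (nrow(scene$spots) > 0) {
    s <- params$spot_sigma
    w <- ceiling(3 * s)
    for (i in seq_len(nrow(scene$spots))) {
      sr <- scene$spots$r[i]; scc <- scene$spots$c[i]
      rr <- max(1L, floor(sr - w)):min(nr, ceiling(sr + w))
      ccs <- max(1L, floor(scc - w)):min(nc, ceiling(scc + w))
      g <- expand.grid(r = rr, c = ccs)
      val <- params$spot_amp * exp(-((g$r - sr)^2 + (g$c - scc)^2) / (2 * s^2))
      spots[cbind(g$r, g$c)] <- spots[cbind(g$r, g$c)] + val
    }
  }

  finish <- function(ch) {
    x <- gblur_mat(ch, params$psf_sigma) + params$background_offset
    if (params$noise_sigma > 0)
      x <- x + matrix(stats::rnorm(nr * nc, 0, params$noise_sigma), nr, nc)
    matrix(pmin(pmax(round(x), 0), 65535), nr, nc)
  }
  field_image(list(nuclear = finish(nuclear), junction = finish(junction),
                   spots = finish(spots)),
              pixel_size = params$pixel_size)
}

render_junction_channel <- function(scene, params) {
  nr <- nrow(scene$label_mask); nc <- ncol(scene$label_mask)
  canvas <- matrix(0, nr, nc)
  lab <- scene$label_mask
  if (nrow(scene$adjacency) > 0) {
    # border pixels per adjacent pair: pixels of either cell 4-adjacent to
    # the other, chunked into segments along the border's principal axis
    pairs_px <- border_pixels_by_pair(lab)
    for (key in names(pairs_px)) {
      px <- pairs_px[[key]]
      r <- px[, 1]; cc <- px[, 2]
      if (length(r) < 2) next
      cv <- stats::cov(cbind(r, cc))
      eg <- eigen(cv, symmetric = TRUE)
      proj <- (r - mean(r)) * eg$vectors[1, 1] + (cc - mean(cc)) * eg$vectors[2, 1]
      nseg <- max(1L, ceiling((max(proj) - min(proj)) / params$segment_length))
      seg_w <- (max(proj) - min(proj)) / nseg + 1e-9
      segi <- pmin(nseg, 1L + floor((proj - min(proj)) / seg_w))
      # a fragmented segment loses its central 60%: junctions discontinue
      # in place rather than vanish, so object counts grow with p_frag
      frag <- stats::runif(nseg) < params$junction_fragmentation
      tpos <- (proj - min(proj)) / seg_w - (segi - 1)  # within-segment [0,1]
      keep <- !frag[segi] | tpos < 0.2 | tpos > 0.8
      if (any(keep))
        canvas[cbind(r[keep], cc[keep])] <- 1
    }
  }
  if (max(canvas) > 0) {
    canvas <- gblur_mat(canvas, sigma = params$junction_width / 2)
    canvas <- canvas / max(canvas) * params$junction_amp
  }
  canvas
}

# Split the inter-cell "crack" pixels by unordered label pair.
border_pixels_by_pair <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  res <- list()
  grab <- function(ra, ca, rb, cb) {
    la <- lab[cbind(ra, ca)]; lb <- lab[cbind(rb, cb)]
    sel <- la != lb & la > 0 & lb > 0
    list(r = c(ra[sel], rb[sel]), c = c(ca[sel], cb[sel]),
         key = rep(paste(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel])), 2))
  }
  g1 <- expand.grid(r = seq_len(nr - 1), c = seq_len(nc))
  h <- grab(g1$r, g1$c, g1$r + 1L, g1$c)
  g2 <- expand.grid(r = seq_len(nr), c = seq_len(nc - 1))
  v <- grab(g2$r, g2$c, g2$r, g2$c + 1L)
  allr <- c(h$r, v$r); allc <- c(h$c, v$c); key <- c(h$key, v$key)
  if (length(allr) == 0) return(list())
  df <- unique(data.frame(key = key, r = allr, c = allc))
  split(cbind(df$r, df$c), df$key) |>
    lapply(function(x) matrix(x, ncol = 2))
}

#' Generate a full synthetic experiment to disk
#'
#' For each combination of cell model, treatment, replicate and area in the
#' layout, samples and renders one area-sized scene, cuts it into an
#' overlapping tile grid, and writes the tiles (multi-page TIFF), the
#' ground truth (JSON) and a manifest (JSON) with complete annotations.
#' Per-area seeds are derived deterministically from the master seed, so
#' the output is reproducible tile-for-tile.
#'
#' @param layout an [experiment_layout()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest as a tibble (also written to
#'   `manifest.json`): one row per tile with cell model, treatment,
#'   replicate, area, tile indices, grid geometry and file paths.
#' @export
generate_experiment <- function(layout, seed, out_dir) {
  stopifnot(inherits(layout, "experiment_layout"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste("cannot create out_dir:", out_dir))
  tg <- layout$tile_grid; ts <- layout$tile_size
  ov <- layout$tile_overlap_frac
  step <- c(round(ts[1] * (1 - ov)), round(ts[2] * (1 - ov)))
  area_size <- c((tg[1] - 1) * step[1] + ts[1], (tg[2] - 1) * step[2] + ts[2])

  rows <- list()
  for (cm in layout$cell_models) for (tr in layout$treatments) {
    preset <- paste(cm, tr, sep = "_")
    # constant cell density: the default 140 cells refer to a 768 px frame
    n_cells <- max(3L, as.integer(round(140 * prod(area_size) / 768^2)))
    params <- preset_params(preset, frame_size = area_size,
                            target_cell_count = n_cells)
    for (rep_i in seq_len(layout$replicates_per_condition))
      for (area_i in seq_len(layout$areas_per_replicate)) {
        s_area <- derive_seed(seed, preset, rep_i, area_i)
        scene <- sample_monolayer(params, seed = s_area)
        field <- render_field(scene, params, seed = derive_seed(s_area, "render"))
        area_tag <- sprintf("%s_rep%d_area%d", preset, rep_i, area_i)
        gt_path <- file.path(out_dir, paste0(area_tag, "_truth.json"))
        write_scene_json(scene, gt_path)
        for (ti in seq_len(tg[1])) for (tj in seq_len(tg[2])) {
          r0 <- (ti - 1) * step[1] + 1; c0 <- (tj - 1) * step[2] + 1
          tile <- field_image(
            lapply(field$channels, function(ch)
              ch[r0:(r0 + ts[1] - 1), c0:(c0 + ts[2] - 1)]),
            pixel_size = field$pixel_size, origin = c(r0, c0))
          tp <- file.path(out_dir, sprintf("%s_tile%d%d.tif", area_tag, ti, tj))
          write_field(tile, tp)
          rows[[length(rows) + 1]] <- tibble(
            cell_model = cm, treatment = tr, replicate = rep_i,
            area = area_i, tile_row = ti, tile_col = tj,
            grid_rows = tg[1], grid_cols = tg[2], overlap_frac = ov,
            seed = s_area, tile_path = basename(tp),
            truth_path = basename(gt_path))
        }
      }
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(list(schema_version = 1L, manifest = manifest),
                       file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

write_scene_json <- function(scene, path) {
  jsonlite::write_json(
    list(seed = scene$seed,
         cells = scene$cells, nuclei = scene$nuclei, spots = scene$spots,
         adjacency = scene$adjacency,
         polygons = lapply(scene$polygons, function(p)
           list(r = p[, 1], c = p[, 2])),
         params = unclass(scene$params)),
    path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
}

#' Read an experiment manifest written by [generate_experiment()]
#' @param path directory containing `manifest.json`, or the file itself.
#' @return The manifest tibble.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) abort(paste("no manifest at", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tibble(m$manifest)
}
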