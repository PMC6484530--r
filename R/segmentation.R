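#' Label mask container
#'
#' @param labels non-negative integer matrix, 0 = background; labels are
#'   relabeled to a contiguous 1..K set in row-major centroid order.
#' @param kind one of `"nuclei"`, `"cells"`, `"junctions"`.
#' @param pixel_size micrometres per pixel.
#' @param retained integer vector of labels retained for per-cell
#'   statistics (defaults to all).
#' @param check_contiguous require labels to be the contiguous set 1..K
#'   (disable for masks whose labels are tied to another mask's ids).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, kind = c("nuclei", "cells", "junctions"),
                       pixel_size = 1, retained = NULL,
                       check_contiguous = TRUE) {
  kind <- match.arg(kind)
  storage.mode(labels) <- "integer"
  labs <- sort(unique(labels[labels > 0]))
  if (check_contiguous && length(labs) > 0 &&
      !identical(labs, seq_len(length(labs))))
    abort("labels must form a contiguous set 1..K")
  structure(list(labels = labels, kind = kind, pixel_size = pixel_size,
                 retained = retained %||% labs),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask:%s> %d x %d px, %d object(s), %d retained\n",
              x$kind, nrow(x$labels), ncol(x$labels),
              length(unique(x$labels[x$labels > 0])), length(x$retained)))
  invisible(x)
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' then a distance-transform watershed that splits touching nuclei whose
#' intensity maxima are at least `split_min_distance` apart. Components
#' outside the `[min_nucleus_area, max_nucleus_area]` range (in square
#' micrometres) are removed. Labels are sorted by centroid in row-major
#' order, so output is deterministic.
#'
#' @param field a [field_image()] with a `nuclear` channel.
#' @param params a [seg_params()].
#' @return A `label_mask` of kind `"nuclei"`.
#' @export
segment_nuclei <- function(field, params = seg_params()) {
  if (!"nuclear" %in% field$channel_roles)
    abort("field has no nuclear channel")
  x <- field$channels[["nuclear"]]
  sm <- gblur_mat(x, params$smooth_sigma)
  thr <- switch(params$threshold_method,
                otsu = otsu_threshold(sm),
                fixed = params$fixed_threshold %||%
                  abort("fixed_threshold required"))
  mask <- sm > thr
  if (!any(mask))
    return(label_mask(matrix(0L, nrow(x), ncol(x)), "nuclei",
                      field$pixel_size))
  mask <- as.matrix(EBImage::imageData(
    EBImage::fillHull(EBImage::Image(mask))))
  dm <- EBImage::distmap(EBImage::Image(mask))
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = max(1L, as.integer(params$split_min_distance)))
  lab <- as.matrix(EBImage::imageData(ws))
  storage.mode(lab) <- "integer"
  # area filter in um^2
  px_area <- field$pixel_size^2
  tab <- tabulate(lab[lab > 0])
  bad <- which(tab * px_area < params$min_nucleus_area |
                 tab * px_area > params$max_nucleus_area)
  lab[lab %in% bad] <- 0L
  label_mask(relabel_rowmajor(lab), "nuclei", field$pixel_size)
}

otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xn <- (x - rng[1]) / diff(rng)
  EBImage::otsu(EBImage::Image(xn), range = c(0, 1)) * diff(rng) + rng[1]
}

#' Segment cells by seeded growth on the junction-marker landscape
#'
#' Cells are recovered by seeded region growing
#' ([EBImage::propagate()]) on the smoothed junction channel with the
#' nuclei as seeds: the junction marker outlines cell borders as bright
#' ridges, which act as barriers so region boundaries settle on them. The
#' monolayer is assumed confluent, so the foreground is the full frame and
#' the cell labels partition the image; each cell inherits the label of its
#' seed nucleus. With `border_policy = "exclude"`, cells touching the frame
#' edge are dropped from per-cell statistics (their pixels remain in the
#' mask so adjacency is still defined).
#'
#' @param field a [field_image()] with a `junction` channel.
#' @param nuclei nucleus `label_mask` from [segment_nuclei()].
#' @param params a [seg_params()].
#' @return A `label_mask` of kind `"cells"`; `$retained` holds the labels
#'   kept for downstream statistics.
#' @export
segment_cells <- function(field, nuclei, params = seg_params()) {
  if (!"junction" %in% field$channel_roles)
    abort("field has no junction channel")
  if (!any(nuclei$labels > 0)) abort("no seeds: empty nuclei mask")
  if (!all(dim(nuclei$labels) == dim(field$channels[["junction"]])))
    abort("nuclei mask is not aligned with the field")
  x <- gblur_mat(field$channels[["junction"]], params$smooth_sigma)
  x <- (x - min(x)) / max(diff(range(x)), 1e-9)
  lab <- EBImage::propagate(EBImage::Image(x),
                            EBImage::Image(nuclei$labels),
                            lambda = 1e-4)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  nr <- nrow(lab); nc <- ncol(lab)
  retained <- sort(unique(lab[lab > 0]))
  if (params$border_policy == "exclude") {
    edge <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    retained <- setdiff(retained, edge)
  }
  label_mask(lab, "cells", field$pixel_size, retained = retained)
}
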