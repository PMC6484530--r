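#' Multi-channel field image container
#'
#' A light container for one microscope field: a named list of 2D intensity
#' matrices (all the same shape), the channel roles, the pixel size, and the
#' field's origin offset in area coordinates.
#'
#' @param channels named list of numeric matrices; names are the channel
#'   roles, drawn from `nuclear`, `junction`, `spots`.
#' @param pixel_size micrometres per pixel, > 0.
#' @param origin `(row, col)` offset of this field inside its area.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size, origin = c(1L, 1L)) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    abort("channels must be a named list")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    abort("all channels must share an identical shape")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  structure(list(channels = lapply(channels, function(x) {
    storage.mode(x) <- "double"; x
  }),
  channel_roles = names(channels),
  pixel_size = pixel_size, origin = as.numeric(origin)),
  class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px, %d channel(s): %s; %.4f um/px\n",
              d[1], d[2], length(x$channels),
              paste(x$channel_roles, collapse = ", "), x$pixel_size))
  invisible(x)
}

#' Write / read a field as multi-page TIFF with a JSON sidecar
#'
#' One 16-bit TIFF page per channel, in the container's channel order.
#' Channel roles, pixel size and origin are carried in a `.json` sidecar
#' next to the TIFF so the round-trip is lossless: `read_field(write_field(x))`
#' reproduces the pixel data bit-exactly and the metadata exactly.
#'
#' @param field a [field_image()]; intensities must lie in `[0, 65535]`.
#' @param path output `.tif` path.
#' @return `write_field` returns `path` invisibly; `read_field` returns the
#'   [field_image()].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(channel_roles = field$channel_roles,
                            pixel_size = field$pixel_size,
                            origin = field$origin),
                       sidecar_path(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) abort(paste("cannot read field: no file at", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(paste("missing metadata sidecar for", path))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (length(pages) != length(meta$channel_roles))
    abort(sprintf("format error in %s: %d page(s) but %d declared role(s)",
                  path, length(pages), length(meta$channel_roles)))
  chans <- lapply(pages, function(p) round(p * 65535))
  names(chans) <- meta$channel_roles
  field_image(chans, pixel_size = meta$pixel_size, origin = meta$origin)
}

#' Stitch a tile grid into an area mosaic
#'
#' Places tiles at their nominal stage offsets
#' `step = round(dim * (1 - overlap_frac))` and blends overlapping strips by
#' linear feathering (weights fall linearly to the tile edge). No
#' registration is attempted: offsets are trusted, as with stage-metadata
#' stitching. The mosaic dimension per axis is `(n - 1) * step + dim`.
#'
#' @param tiles list of [field_image()] tiles in row-major grid order.
#' @param grid integer `(rows, cols)`; `length(tiles)` must equal the product.
#' @param overlap_frac fractional overlap in `[0, 0.5)`.
#' @return The stitched [field_image()].
#' @export
stitch_area <- function(tiles, grid, overlap_frac) {
  grid <- as.integer(grid)
  if (length(tiles) != prod(grid))
    abort(sprintf("tile count %d does not match grid %dx%d",
                  length(tiles), grid[1], grid[2]))
  if (overlap_frac < 0 || overlap_frac >= 0.5)
    abort("overlap_frac must be in [0, 0.5)")
  dims <- unique(lapply(tiles, function(t) dim(t$channels[[1]])))
  if (length(dims) != 1L) abort("all tiles must share the same shape")
  d <- dims[[1]]
  step <- c(round(d[1] * (1 - overlap_frac)), round(d[2] * (1 - overlap_frac)))
  out_d <- c((grid[1] - 1) * step[1] + d[1], (grid[2] - 1) * step[2] + d[2])
  roles <- tiles[[1]]$channel_roles

  # feather weight: linear ramp over the overlap margin, applied only on
  # edges that face another tile
  ramp1 <- function(n, margin, at_start, at_end) {
    w <- rep(1, n)
    if (margin > 0) {
      up <- seq_len(margin) / (margin + 1)
      if (at_start) w[seq_len(margin)] <- up
      if (at_end) w[n + 1 - seq_len(margin)] <- up
    }
    w
  }
  mr <- d[1] - step[1]; mc <- d[2] - step[2]

  acc <- lapply(roles, function(r) matrix(0, out_d[1], out_d[2]))
  names(acc) <- roles
  wacc <- matrix(0, out_d[1], out_d[2])
  k <- 0L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    k <- k + 1L
    r0 <- (i - 1) * step[1]; c0 <- (j - 1) * step[2]
    rs <- (r0 + 1):(r0 + d[1]); cs <- (c0 + 1):(c0 + d[2])
    w <- ramp1(d[1], mr, i > 1, i < grid[1]) %o%
      ramp1(d[2], mc, j > 1, j < grid[2])
    for (r in roles) acc[[r]][rs, cs] <- acc[[r]][rs, cs] + tiles[[k]]$channels[[r]] * w
    wacc[rs, cs] <- wacc[rs, cs] + w
  }
  wacc[wacc == 0] <- 1
  field_image(lapply(acc, function(a) a / wacc),
              pixel_size = tiles[[1]]$pixel_size)
}

#' Stitch one area's tiles from an experiment manifest
#'
#' @param manifest manifest tibble from [read_manifest()].
#' @param dir directory holding the tile files.
#' @param cell_model,treatment,replicate,area the area to stitch.
#' @return The stitched [field_image()].
#' @export
stitch_manifest_area <- function(manifest, dir, cell_model, treatment,
                                 replicate, area) {
  rows <- manifest[manifest$cell_model == cell_model &
                     manifest$treatment == treatment &
                     manifest$replicate == replicate &
                     manifest$area == area, ]
  if (nrow(rows) == 0) abort("no such area in manifest")
  rows <- rows[order(rows$tile_row, rows$tile_col), ]
  tiles <- lapply(file.path(dir, rows$tile_path), read_field)
  stitch_area(tiles, grid = c(rows$grid_rows[1], rows$grid_cols[1]),
              overlap_frac = rows$overlap_frac[1])
}
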