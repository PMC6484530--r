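test_that("shape features recover disk and rectangle geometry", {
  disk <- raster_disk(20)
  sf <- shape_features(disk, 1)
  expect_gte(sf$roundness, 0.95)
  expect_lte(sf$roundness, 1)
  expect_gte(sf$width_length_ratio, 0.98)
  expect_equal(sf$area, sum(disk))

  rect <- matrix(FALSE, 60, 30); rect[11:50, 11:20] <- TRUE
  sr <- shape_features(rect, 1)
  # closed-form moments of a uniform 40 x 10 rectangle:
  # lambda1 = 40^2/12, so 4*sqrt(lambda1) = 40 * 2/sqrt(12) = 23.09 scaled
  # by the 4-sqrt-lambda convention: length = 4*sqrt(1599/12 ish)
  expect_equal(sr$width_length_ratio, 0.25, tolerance = 0.02)
  expect_equal(sr$length, 4 * sqrt((40^2 - 1) / 12), tolerance = 0.01)
  expect_equal(sr$width, 4 * sqrt((10^2 - 1) / 12), tolerance = 0.01)

  # rotation by 90 degrees leaves features unchanged
  sq <- matrix(FALSE, 40, 40); sq[10:30, 15:25] <- TRUE
  expect_equal(shape_features(sq, 1)[, -1], shape_features(t(sq), 1)[, -1],
               tolerance = 1e-12)
  expect_error(shape_features(matrix(c(TRUE, TRUE, rep(FALSE, 23)), 5, 5), 1),
               "degenerate")
})

test_that("STAR features hit their analytic anchors on constructed rasters", {
  disk <- raster_disk(20)
  uni <- matrix(0, nrow(disk), ncol(disk)); uni[disk] <- 100
  st <- star_features(uni, disk, 1)
  expect_equal(st$symmetry, 1, tolerance = 0.02)
  # rasterization keeps TC a hair under the analytic value of 1
  for (tc in c(st$tc30, st$tc40, st$tc50, st$tc60))
    expect_equal(tc, 1, tolerance = 1e-3)
  expect_equal(st$axial_ratio, 1, tolerance = 0.02)

  # all-zero channel: declared degenerate rule
  z <- star_features(matrix(0, nrow(disk), ncol(disk)), disk, 1)
  expect_true(all(as.numeric(z) == 0))

  # intensity concentrated in one off-axis quadrant breaks symmetry
  q <- matrix(0, nrow(disk), ncol(disk))
  q[disk] <- 1
  g <- expand.grid(r = seq_len(nrow(disk)), c = seq_len(ncol(disk)))
  ctr <- (nrow(disk) + 1) / 2
  quad <- disk & matrix(g$r < ctr - 2 & g$c < ctr - 2, nrow(disk))
  q[quad] <- 400
  sq <- star_features(q, disk, 1)
  expect_lt(sq$symmetry, 0.9)
})

test_that("threshold compactness is monotone for a centered Gaussian blob", {
  disk <- raster_disk(25)
  g <- expand.grid(r = seq_len(nrow(disk)), c = seq_len(ncol(disk)))
  ctr <- (nrow(disk) + 1) / 2
  blob <- matrix(exp(-((g$r - ctr)^2 + (g$c - ctr)^2) / (2 * 8^2)),
                 nrow(disk))
  st <- star_features(blob, disk, 1)
  tcs <- c(st$tc30, st$tc40, st$tc50, st$tc60)
  expect_true(all(diff(tcs) >= -0.01))  # monotone up to raster jitter
})

test_that("STAR features are stable under 90-degree rotation", {
  fx <- small_area()
  an <- fx$analysis
  i <- an$cells$retained[1]
  lab <- an$cells$labels
  idx <- which(lab == i)
  nr <- nrow(lab)
  bb <- list(r0 = max(1, min((idx - 1) %% nr + 1) - 2),
             r1 = min(nr, max((idx - 1) %% nr + 1) + 2),
             c0 = max(1, min((idx - 1) %/% nr + 1) - 2),
             c1 = min(ncol(lab), max((idx - 1) %/% nr + 1) + 2))
  m <- lab[bb$r0:bb$r1, bb$c0:bb$c1] == i
  ch <- fx$field$channels$junction[bb$r0:bb$r1, bb$c0:bb$c1]
  rot <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  a <- star_features(ch, m, 1)
  b <- star_features(rot(ch), rot(m), 1)
  for (f in names(a)) {
    if (abs(a[[f]]) < 0.05) expect_lt(abs(b[[f]] - a[[f]]), 0.02)
    else expect_lt(abs(b[[f]] - a[[f]]) / abs(a[[f]]), 0.02)
  }
})

test_that("the cell table is complete, ordered and conserves cells", {
  fx <- small_area()
  an <- fx$analysis
  ct <- an$cell_table
  expect_equal(nrow(ct), length(an$cells$retained))
  expect_equal(ct$cell, sort(ct$cell))
  expect_false(any(is.na(dplyr::select(ct, -"cluster_id"))))
  expect_true(all(ct$nuc_area <= ct$cell_area))
  expect_true(all(ct$category %in% c("Nneg", "Ncyt", "Nnuc")))
  # border-excluded cells absent from the table but present in adjacency
  edge_labels <- setdiff(unique(c(an$cells$labels[1, ], an$cells$labels[, 1])), 0)
  expect_false(any(edge_labels %in% ct$cell))
  expect_true(all(as.character(edge_labels) %in%
                    igraph::V(an$graph)$name))
})

test_that("the default feature registry is the canonical 47-feature set", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 47L)
  expect_false(anyDuplicated(reg$feature) > 0)
  fam <- table(reg$family)
  expect_equal(as.integer(fam[c("cell_shape", "nucleus_shape",
                            "nucleus_shape_ratio", "star_junction",
                            "star_spot", "mean_intensity", "junction_stat",
                            "notch_category", "notch_cluster",
                            "population")]),
               c(6L, 6L, 1L, 9L, 9L, 4L, 4L, 3L, 4L, 1L))
  # registry round-trips through JSON unchanged
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(reg, tf, dataframe = "rows")
  back <- tibble::as_tibble(jsonlite::read_json(tf, simplifyVector = TRUE))
  expect_equal(back, reg)
  # every cell_mean source is a cell-table column
  ct_cols <- names(ecprofiler:::empty_cell_table())
  expect_true(all(reg$source[reg$aggregation == "cell_mean"] %in% ct_cols))
})

test_that("area aggregation applies the registry rules", {
  fx <- small_area()
  row <- aggregate_area(fx$analysis)
  reg <- feature_registry()
  expect_identical(names(row), reg$feature)
  expect_equal(row$cell_count, length(fx$analysis$cells$retained))
  expect_equal(row$pct_nneg + row$pct_ncyt + row$pct_nnuc, 100)
  expect_equal(row$cell_area, mean(fx$analysis$cell_table$cell_area))
  expect_equal(row$jn, fx$analysis$jn)
})
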