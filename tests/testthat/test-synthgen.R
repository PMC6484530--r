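test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(category_probs = c(0.5, 0.5, 0.5)), "summing|sum")
  expect_error(scene_params(elongation = 0.5), "elongation")
  expect_error(scene_params(frame_size = c(32, 32)), "64")
  expect_error(scene_params(junction_fragmentation = 1.2), "fragmentation")
  expect_error(preset_params("huvec_basel"), "unknown preset")
})

test_that("empty and forced-category scenes honor their invariants", {
  p0 <- scene_params(frame_size = c(96, 96), target_cell_count = 0L)
  sc0 <- sample_monolayer(p0, seed = 3)
  expect_equal(nrow(sc0$cells), 0)
  expect_equal(nrow(sc0$adjacency), 0)
  expect_true(all(sc0$label_mask == 0))

  p1 <- scene_params(frame_size = c(192, 192), target_cell_count = 8L,
                     category_probs = c(1, 0, 0))
  sc1 <- sample_monolayer(p1, seed = 4)
  expect_true(all(sc1$cells$category == "Nneg"))
  expect_equal(nrow(sc1$spots), 0)
})

test_that("per-cell spot placement matches the category constraints", {
  sc <- small_area()$scene
  for (i in sc$cells$cell) {
    s <- sc$spots[sc$spots$cell == i, ]
    cat_i <- sc$cells$category[i]
    if (cat_i == "Nneg") expect_equal(nrow(s), 0)
    if (cat_i == "Ncyt") {
      expect_gte(sum(s$compartment == "cytoplasmic"), 1)
      expect_equal(sum(s$compartment == "nuclear"), 0)
    }
    if (cat_i == "Nnuc") expect_gte(sum(s$compartment == "nuclear"), 1)
  }
  # every nucleus ellipse lies inside its cell: sampled nuclear spot centers
  # must land on their own cell's label
  nuc_sp <- sc$spots[sc$spots$compartment == "nuclear", ]
  own <- sc$label_mask[cbind(round(nuc_sp$r), round(nuc_sp$c))]
  expect_true(all(own == nuc_sp$cell))
})

test_that("infeasible density is rejected with a clear error", {
  expect_error(
    sample_monolayer(scene_params(frame_size = c(64, 64),
                                  target_cell_count = 5000L), seed = 1),
    "infeasible density")
})

test_that("category frequencies converge to category_probs (binomial CI)", {
  # pooled over 20 small scenes; exact binomial CI for the Nnuc fraction
  probs <- c(0.45, 0.35, 0.20)
  p <- scene_params(frame_size = c(192, 192), target_cell_count = 10L,
                    category_probs = probs, jaggedness = 0)
  cats <- unlist(lapply(1:20, function(s)
    sample_monolayer(p, seed = s)$cells$category))
  n <- length(cats)
  ci <- stats::binom.test(sum(cats == "Nnuc"), n)$conf.int
  expect_true(probs[3] >= ci[1] && probs[3] <= ci[2])
  # chi-square goodness of fit over all three categories not rejected
  obs <- table(factor(cats, levels = c("Nneg", "Ncyt", "Nnuc")))
  expect_gt(stats::chisq.test(obs, p = probs)$p.value, 0.01)
})

test_that("scene generation and rendering are deterministic", {
  p <- scene_params(frame_size = c(128, 128), target_cell_count = 6L)
  a <- sample_monolayer(p, seed = 9)
  b <- sample_monolayer(p, seed = 9)
  expect_identical(a$label_mask, b$label_mask)
  expect_identical(a$spots, b$spots)
  fa <- render_field(a, p, seed = 10)
  fb <- render_field(b, p, seed = 10)
  expect_identical(fa$channels, fb$channels)
})

test_that("ground-truth adjacency equals a brute-force pairwise border scan", {
  for (s in 1:3) {
    p <- scene_params(frame_size = c(160, 160), target_cell_count = 8L)
    sc <- sample_monolayer(p, seed = s)
    expected <- oracle_adjacency(sc$label_mask)
    got <- as.matrix(sc$adjacency)
    dimnames(got) <- NULL
    expect_equal(got, expected)
  }
})

test_that("mean width/length ratio strictly decreases with elongation", {
  expect_true(all(diff(elongation_ratios()) < 0))
})

test_that("rendering honors its degenerate and construction cases", {
  # empty scene, zero noise: all channels constant at the background
  p <- scene_params(frame_size = c(96, 96), target_cell_count = 0L,
                    noise_sigma = 0)
  f <- render_field(sample_monolayer(p, seed = 1), p, seed = 2)
  for (ch in f$channels) expect_true(all(ch == p$background_offset))

  # unfragmented, unjagged scene: thresholded junction boundary network is
  # one connected component spanning the interior borders
  p2 <- scene_params(frame_size = c(256, 256), target_cell_count = 12L,
                     junction_fragmentation = 0, jaggedness = 0,
                     noise_sigma = 0)
  sc2 <- sample_monolayer(p2, seed = 5)
  f2 <- render_field(sc2, p2, seed = 6)
  jc <- f2$channels$junction
  binary <- jc > (p2$background_offset + p2$junction_amp / 4)
  expect_equal(max(oracle_flood_fill(binary)), 1)

  # a nuclear spot renders with its argmax inside the nucleus ellipse
  p3 <- scene_params(frame_size = c(128, 128), target_cell_count = 4L,
                     category_probs = c(0, 0, 1), noise_sigma = 0)
  sc3 <- sample_monolayer(p3, seed = 8)
  f3 <- render_field(sc3, p3, seed = 9)
  peak <- which.max(f3$channels$spots)
  pr <- ((peak - 1) %% 128) + 1; pc <- ((peak - 1) %/% 128) + 1
  d <- sqrt((sc3$spots$r - pr)^2 + (sc3$spots$c - pc)^2)
  expect_lt(min(d), 2)
})

test_that("generated experiments carry complete, deterministic manifests", {
  dir1 <- withr::local_tempdir()
  lay <- experiment_layout(cell_models = "huvec", treatments = "basal",
                           replicates_per_condition = 1L,
                           areas_per_replicate = 1L, tile_grid = c(1L, 1L),
                           tile_size = c(192L, 192L))
  m <- generate_experiment(lay, seed = 5, out_dir = dir1)
  expect_equal(nrow(m), 1L)
  expect_true(file.exists(file.path(dir1, m$tile_path)))
  expect_true(file.exists(file.path(dir1, m$truth_path)))
  m2 <- read_manifest(dir1)
  expect_equal(m2$tile_path, m$tile_path)

  # same seed, fresh directory: bit-identical tiles
  dir2 <- withr::local_tempdir()
  generate_experiment(lay, seed = 5, out_dir = dir2)
  f1 <- read_field(file.path(dir1, m$tile_path))
  f2 <- read_field(file.path(dir2, m$tile_path))
  expect_identical(f1$channels, f2$channels)
})
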