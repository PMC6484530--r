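test_that("spot detection finds planted spots and suppresses near pairs", {
  expect_equal(nrow(detect_spots(matrix(100, 64, 64))), 0)

  set.seed(5)
  n <- 128
  img <- matrix(stats::rnorm(n * n, 1000, 20), n, n)
  centers <- cbind(r = c(20, 40, 70, 95, 110), c = c(30, 90, 55, 20, 100))
  for (k in 1:5) {
    g <- expand.grid(r = 1:n, c = 1:n)
    img <- img + matrix(2000 * exp(-((g$r - centers[k, 1])^2 +
                                       (g$c - centers[k, 2])^2) / (2 * 4)),
                        n, n)
  }
  sp <- detect_spots(img, spot_params(sigma = 2, min_separation = 5))
  expect_equal(nrow(sp), 5)
  # nearest-neighbor match: every planted center found within 2 px
  for (k in 1:5) {
    d <- sqrt((sp$r - centers[k, 1])^2 + (sp$c - centers[k, 2])^2)
    expect_lte(min(d), 2)
  }

  # two spots 1 px apart with min separation 5 merge to one detection
  img2 <- matrix(stats::rnorm(64 * 64, 0, 1), 64, 64)
  g <- expand.grid(r = 1:64, c = 1:64)
  img2 <- img2 + matrix(100 * exp(-((g$r - 32)^2 + (g$c - 32)^2) / 8) +
                          100 * exp(-((g$r - 32)^2 + (g$c - 33)^2) / 8), 64, 64)
  expect_equal(nrow(detect_spots(img2, spot_params(min_separation = 5))), 1)
})

test_that("classification applies the three-category rule and percentages", {
  # 3 cells side by side; nuclei share cell labels
  cells <- label_mask(matrix(rep(1:3, each = 20 * 60), 60, 60), "cells")
  nuc <- matrix(0L, 60, 60)
  nuc[25:35, 5:15] <- 1L; nuc[25:35, 25:35] <- 2L; nuc[25:35, 45:55] <- 3L
  nuclei <- label_mask(nuc, "nuclei", check_contiguous = FALSE)
  spots <- tibble::tibble(
    r = c(10, 30, 10, 12), c = c(25, 50, 45, 48),
    intensity = 1, response = 1)
  # cell A (cols 1..20): none; B: one cytoplasmic (r10,c25);
  # C: one nuclear (r30,c50) + two cytoplasmic
  res <- classify_notch(spots, nuclei, cells)
  expect_equal(res$categories$category, c("Nneg", "Ncyt", "Nnuc"))
  expect_equal(unname(res$fractions), rep(100 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(res$fractions), 100)

  # no spots at all
  res0 <- classify_notch(spots[0, ], nuclei, cells)
  expect_equal(unname(res0$fractions), c(100, 0, 0))
})

test_that("per-cell category agreement with ground truth is high at low noise", {
  matches <- category_agreement()
  expect_gte(nrow(matches), 200)
  expect_gte(mean(matches$truth == matches$measured), 0.95)
})

test_that("cell adjacency matches the brute-force scan with a border floor", {
  # hand construction: two rectangles sharing a 50-px border
  lab <- matrix(1L, 50, 60); lab[, 31:60] <- 2L
  g <- cell_adjacency(label_mask(lab, "cells"), min_shared_border = 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
  g1 <- cell_adjacency(label_mask(matrix(1L, 20, 20), "cells"))
  expect_equal(igraph::ecount(g1), 0)

  # random scenes vs oracle
  for (s in 1:3) {
    p <- scene_params(frame_size = c(192, 192), target_cell_count = 12L)
    sc <- sample_monolayer(p, seed = s + 40)
    cm <- label_mask(sc$label_mask, "cells")
    g <- cell_adjacency(cm, min_shared_border = 3)
    got <- igraph::as_edgelist(g)
    got <- matrix(as.integer(got), ncol = 2)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(got, oracle_adjacency(sc$label_mask, 3L))
  }
})

test_that("cluster features follow their definitions on known graphs", {
  g0 <- cell_adjacency(label_mask(matrix(1L, 20, 20), "cells"))
  res0 <- notch_clusters(g0, tibble::tibble(cell = 1L, category = "Nneg"))
  expect_equal(unname(res0$features), c(0, 0, 0, 0))

  # path of 3 contiguous Nnuc cells + 1 isolated Nnuc cell (5 is an island
  # inside the Ncyt cell 4, so it touches no other Nnuc cell)
  lab <- matrix(0L, 40, 80)
  lab[, 1:20] <- 1L; lab[, 21:40] <- 2L; lab[, 41:60] <- 3L; lab[, 61:80] <- 4L
  lab[10:30, 65:75] <- 5L
  cm <- label_mask(lab, "cells")
  g <- cell_adjacency(cm, min_shared_border = 3)
  cats <- tibble::tibble(cell = 1:5,
                         category = c("Nnuc", "Nnuc", "Nnuc", "Ncyt", "Nnuc"))
  res <- notch_clusters(g, cats)
  sizes <- sort(lengths(res$clusters))
  expect_equal(sizes, c(1L, 3L))
  expect_equal(unname(res$features["n_clusters"]), 2)
  expect_equal(unname(res$features["mean_size"]), 2)
  expect_equal(unname(res$features["max_size"]), 3)
  expect_equal(unname(res$features["frac_in_multi"]), 0.75)
})

test_that("cluster partition equals the BFS oracle on random graphs", {
  set.seed(99)
  for (trial in 1:100) {
    n <- sample(5:30, 1)
    p_edge <- stats::runif(1, 0.05, 0.3)
    pairs <- t(utils::combn(n, 2))
    sel <- stats::runif(nrow(pairs)) < p_edge
    edges <- pairs[sel, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::V(g)$name <- as.character(seq_len(n))
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
    cats <- tibble::tibble(
      cell = seq_len(n),
      category = sample(c("Nneg", "Ncyt", "Nnuc"), n, TRUE))
    res <- notch_clusters(g, cats)
    # oracle: BFS on the induced subgraph of Nnuc nodes
    nnuc <- which(cats$category == "Nnuc")
    sub_edges <- edges[edges[, 1] %in% nnuc & edges[, 2] %in% nnuc, ,
                       drop = FALSE]
    remap <- match(sub_edges, nnuc)
    comp <- oracle_bfs_components(length(nnuc),
                                  matrix(remap, ncol = 2))
    oracle_parts <- lapply(split(nnuc, comp), sort)
    got_parts <- lapply(res$clusters, sort)
    expect_setequal(lapply(got_parts, paste, collapse = ","),
                    lapply(oracle_parts, paste, collapse = ","))
    # conservation: cluster sizes sum to the Nnuc count
    expect_equal(sum(lengths(res$clusters)), length(nnuc))
  }
})

test_that("raising the nuclear fraction raises %Nnuc and mean cluster size", {
  run_at <- function(pn) {
    rows <- lapply(1:3, function(s) {
      p <- scene_params(frame_size = c(448, 448), target_cell_count = 34L,
                        category_probs = c(0.9 - pn, 0.1, pn))
      sc <- sample_monolayer(p, seed = s + 70)
      f <- render_field(sc, p, seed = s + 170)
      an <- analyze_area(f)
      c(pct = unname(an$notch$fractions["Nnuc"]),
        msize = unname(an$clusters$features["mean_size"]))
    })
    colMeans(do.call(rbind, rows))
  }
  lo <- run_at(0.2); hi <- run_at(0.6)
  expect_gt(hi["pct"], lo["pct"])
  expect_gt(hi["msize"], lo["msize"])
})
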