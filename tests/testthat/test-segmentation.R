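make_field <- function(nuclear = NULL, junction = NULL, spots = NULL,
                       pixel_size = 1) {
  chans <- Filter(Negate(is.null),
                  list(nuclear = nuclear, junction = junction, spots = spots))
  field_image(chans, pixel_size = pixel_size)
}

test_that("blank images yield zero nuclei and missing channels error", {
  f <- make_field(nuclear = matrix(500, 128, 128))
  expect_equal(length(segment_nuclei(f)$retained), 0)
  f2 <- make_field(junction = matrix(0, 64, 64))
  expect_error(segment_nuclei(f2), "nuclear")
  expect_error(segment_cells(f2, label_mask(matrix(0L, 64, 64), "nuclei")),
               "no seeds")
})

test_that("touching nuclei are split by the distance-transform watershed", {
  n <- 120
  g <- expand.grid(r = 1:n, c = 1:n)
  # separated disks (gap 5 px)
  sep <- matrix(1000 * ((g$r - 60)^2 + (g$c - 35)^2 <= 15^2 |
                          (g$r - 60)^2 + (g$c - 70)^2 <= 15^2), n, n)
  f1 <- make_field(nuclear = sep)
  m1 <- segment_nuclei(f1, seg_params(smooth_sigma = 1,
                                      max_nucleus_area = 5000))
  expect_equal(length(m1$retained), 2)

  # overlapping disks (centers 25 px apart, radius 15)
  mrg <- matrix(1000 * ((g$r - 60)^2 + (g$c - 40)^2 <= 15^2 |
                          (g$r - 60)^2 + (g$c - 65)^2 <= 15^2), n, n)
  f2 <- make_field(nuclear = mrg)
  m2 <- segment_nuclei(f2, seg_params(smooth_sigma = 1,
                                      max_nucleus_area = 5000))
  expect_equal(length(m2$retained), 2)
})

test_that("nucleus recovery on synthetic areas is within 5% of truth", {
  fx <- small_area()
  n_true <- nrow(fx$scene$cells)
  nuc <- segment_nuclei(fx$field, seg_params())
  n_found <- length(unique(nuc$labels[nuc$labels > 0]))
  expect_lte(abs(n_found - n_true) / n_true, 0.05)
})

test_that("a single seed grows to cover the whole frame", {
  n <- 96
  nuc <- matrix(0L, n, n); nuc[40:50, 40:50] <- 1L
  f <- make_field(junction = matrix(100, n, n))
  cells <- segment_cells(f, label_mask(nuc, "nuclei"),
                         seg_params(border_policy = "keep"))
  expect_true(all(cells$labels == 1L))
})

test_that("the watershed boundary settles on a bright ridge", {
  n <- 101; ridge_col <- 51
  jc <- matrix(0, n, n)
  for (d in -3:3) jc[, ridge_col + d] <- jc[, ridge_col + d] + 1000 * exp(-d^2 / 2)
  nuc <- matrix(0L, n, n); nuc[48:54, 23:27] <- 1L; nuc[48:54, 75:79] <- 2L
  f <- make_field(junction = jc)
  cells <- segment_cells(f, label_mask(nuc, "nuclei"),
                         seg_params(smooth_sigma = 1, border_policy = "keep"))
  boundary_cols <- apply(cells$labels, 1, function(row) which(diff(row) != 0)[1])
  expect_true(all(abs(boundary_cols - ridge_col) <= 1))
})

test_that("cell labels partition the frame and nuclei biject with cells", {
  an <- small_area()$analysis
  lab <- an$cells$labels
  expect_true(all(lab > 0))  # confluent partition: every pixel labeled
  for (i in an$cells$retained) {
    nuc_px <- sum(an$nuclei$labels == i)
    cell_px <- sum(lab == i)
    expect_gte(nuc_px, 4)          # exactly one nucleus, non-degenerate
    expect_lte(nuc_px, cell_px)    # nucleus inside its cell
    expect_true(all(lab[an$nuclei$labels == i] == i))
  }
})

test_that("recovered borders track truth closely in clean conditions", {
  p <- scene_params(frame_size = c(320, 320), target_cell_count = 14L,
                    junction_fragmentation = 0, noise_sigma = 0,
                    jaggedness = 0)
  sc <- sample_monolayer(p, seed = 13)
  f <- render_field(sc, p, seed = 14)
  an <- analyze_area(f)
  # mean displacement between recovered and true boundary pixels
  disp <- function(lab) {
    nr <- nrow(lab)
    which(lab != rbind(lab[-1, ], lab[nr, ]) |
            lab != cbind(lab[, -1], lab[, ncol(lab)]))
  }
  got <- disp(an$cells$labels); tru <- disp(sc$label_mask)
  nr <- nrow(sc$label_mask)
  gr <- ((got - 1) %% nr) + 1; gc <- ((got - 1) %/% nr) + 1
  tr <- ((tru - 1) %% nr) + 1; tc <- ((tru - 1) %/% nr) + 1
  d <- vapply(seq_along(gr), function(k)
    sqrt(min((tr - gr[k])^2 + (tc - gc[k])^2)), numeric(1))
  expect_lt(mean(d), 3)
})

test_that("median per-cell IoU vs ground truth is at least 0.8", {
  ious <- unlist(lapply(1:5, function(s) {
    p <- scene_params(frame_size = c(320, 320), target_cell_count = 14L)
    sc <- sample_monolayer(p, seed = s)
    f <- render_field(sc, p, seed = s + 100)
    nuc <- segment_nuclei(f)
    cells <- segment_cells(f, nuc)
    nr <- nrow(cells$labels)
    vapply(cells$retained, function(i) {
      m <- cells$labels == i
      idx <- which(m)
      r <- round(mean(((idx - 1) %% nr) + 1))
      cc <- round(mean(((idx - 1) %/% nr) + 1))
      gt <- sc$label_mask[r, cc]
      if (gt == 0) return(NA_real_)
      g <- sc$label_mask == gt
      sum(m & g) / sum(m | g)
    }, numeric(1))
  }))
  expect_gte(stats::median(ious, na.rm = TRUE), 0.8)
})
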