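# Shared fixtures, memoized so expensive scenes are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small default-noise scene + rendered field + full analysis.
small_area <- function(seed = 1) {
  memo(paste0("small_area_", seed), function() {
    p <- scene_params(frame_size = c(384, 384), target_cell_count = 20L)
    sc <- sample_monolayer(p, seed = seed)
    f <- render_field(sc, p, seed = seed + 1000)
    list(params = p, scene = sc, field = f, analysis = analyze_area(f))
  })
}

# Match each retained measured cell to the ground-truth cell containing
# its centroid; returns a tibble with truth and measured categories.
match_to_truth <- function(scene, analysis) {
  lab <- analysis$cells$labels
  nr <- nrow(lab)
  ct <- analysis$cell_table
  rows <- lapply(analysis$cells$retained, function(i) {
    idx <- which(lab == i)
    r <- round(mean(((idx - 1L) %% nr) + 1L))
    cc <- round(mean(((idx - 1L) %/% nr) + 1L))
    gt <- scene$label_mask[r, cc]
    if (gt == 0 || !(i %in% ct$cell)) return(NULL)
    tibble::tibble(cell = i, gt_cell = gt,
                   truth = scene$cells$category[gt],
                   measured = ct$category[ct$cell == i])
  })
  dplyr::bind_rows(rows)
}

# The packaged default experiment (2 models x 2 treatments x 2 replicates
# x 5 areas of 3x3 tiles), generated and analyzed once and shared by the
# acceptance tests. Seed fixed: this is the study design, not a dial.
default_experiment <- function() {
  memo("default_experiment", function() {
    dir <- file.path(tempdir(), "ecprofiler_default_exp")
    layout <- experiment_layout()
    manifest <- generate_experiment(layout, seed = 42, out_dir = dir)
    features <- analyze_experiment(manifest, dir)
    list(dir = dir, layout = layout, manifest = manifest,
         features = features)
  })
}

# J_n sweep over junction fragmentation levels (4 scenes per level).
jn_sweep <- function() {
  memo("jn_sweep", function() {
    pfs <- c(0, 0.2, 0.4, 0.6, 0.8)
    mjn <- vapply(pfs, function(pf) {
      mean(vapply(1:4, function(s) {
        p <- scene_params(frame_size = c(256, 256), target_cell_count = 12L,
                          junction_fragmentation = pf)
        sc <- sample_monolayer(p, seed = s)
        f <- render_field(sc, p, seed = s + 10)
        analyze_area(f)$jn
      }, numeric(1)))
    }, numeric(1))
    list(p_frag = pfs, mean_jn = mjn)
  })
}

# Ground-truth vs measured NOTCH categories at low noise, pooled scenes.
category_agreement <- function() {
  memo("category_agreement", function() {
    dplyr::bind_rows(lapply(1:10, function(s) {
      p <- scene_params(frame_size = c(512, 512), target_cell_count = 42L,
                        noise_sigma = 20)
      sc <- sample_monolayer(p, seed = s)
      f <- render_field(sc, p, seed = s + 600)
      match_to_truth(sc, analyze_area(f))
    }))
  })
}

# Mean ground-truth width/length ratio at three elongation levels.
elongation_ratios <- function() {
  memo("elongation_ratios", function() {
    vapply(c(1, 1.5, 2), function(el) {
      p <- scene_params(frame_size = c(640, 640), target_cell_count = 50L,
                        elongation = el)
      sc <- sample_monolayer(p, seed = 21)
      mean(vapply(sc$cells$cell, function(i)
        shape_features(sc$label_mask == i, 1)$width_length_ratio,
        numeric(1)))
    }, numeric(1))
  })
}
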