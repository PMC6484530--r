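#' Run the whole pipeline from a YAML config
#'
#' Orchestrates simulate -> analyze (stitch + segment + junctions + NOTCH +
#' features) -> profile from a single YAML configuration with a master
#' seed. Each stage writes its outputs under `out_dir` together with a
#' hash of its config section; on re-runs, stages whose outputs exist and
#' whose config hash matches are skipped, so deleting an output directory
#' re-executes only that stage and everything downstream.
#'
#' Config sections (all optional, validated against the known keys):
#' \preformatted{
#' seed: 1
#' out_dir: runs/demo
#' simulate:
#'   cell_models: [huvec, ipsc]
#'   treatments: [basal, vegf]
#'   replicates_per_condition: 2
#'   areas_per_replicate: 5
#'   tile_grid: [3, 3]
#'   tile_overlap_frac: 0.0005
#'   tile_size: [256, 256]
#' segment: {smooth_sigma: 2.0, ...}
#' junctions: {ridge_sigma: 2.0, ...}
#' notch: {sigma: 2.0, min_separation: 5, t_spot: 5.0}
#' profile: {components: 3}
#' }
#'
#' @param config path to the YAML config, or an equivalent named list.
#' @return Invisibly, a list with the manifest, the feature-table path and
#'   the `ec_profile`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% abort("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }

  sim_dir <- file.path(out_dir, "tiles")
  if (stage_fresh(out_dir, "simulate", cfg$simulate, seed) &&
      file.exists(file.path(sim_dir, "manifest.json"))) {
    logf("simulate: outputs up to date, skipping")
    manifest <- read_manifest(sim_dir)
  } else {
    logf("simulate: generating experiment (seed %d)", seed)
    layout <- do.call(experiment_layout, cfg$simulate %||% list())
    manifest <- generate_experiment(layout, seed, sim_dir)
    stage_mark(out_dir, "simulate", cfg$simulate, seed)
    stage_clear(out_dir, c("analyze", "profile"))
    logf("simulate: wrote %d tiles", nrow(manifest))
  }

  feat_path <- file.path(out_dir, "features.csv")
  an_cfg <- list(segment = cfg$segment, junctions = cfg$junctions,
                 notch = cfg$notch)
  if (stage_fresh(out_dir, "analyze", an_cfg, seed) && file.exists(feat_path)) {
    logf("analyze: outputs up to date, skipping")
    features <- utils::read.csv(feat_path, check.names = FALSE) |> as_tibble()
  } else {
    logf("analyze: measuring %d areas",
         nrow(dplyr::distinct(manifest, .data$cell_model, .data$treatment,
                              .data$replicate, .data$area)))
    features <- analyze_experiment(
      manifest, sim_dir,
      seg = do.call(seg_params, cfg$segment %||% list()),
      jct = do.call(junction_params, cfg$junctions %||% list()),
      spot = do.call(spot_params, cfg$notch %||% list()))
    utils::write.csv(features, feat_path, row.names = FALSE)
    stage_mark(out_dir, "analyze", an_cfg, seed)
    stage_clear(out_dir, "profile")
    logf("analyze: wrote %s", feat_path)
  }

  prof_path <- file.path(out_dir, "profile.json")
  k <- (cfg$profile %||% list())$components %||% 3
  profile <- profile_features(features, k = k)
  jsonlite::write_json(
    list(explained_variance_ratio = profile$pca$explained_variance_ratio,
         loadings = as.data.frame(profile$pca$loadings),
         scores = profile$pca$scores,
         merge_heights = profile$clustering$merge_heights,
         leaf_order = profile$clustering$leaf_order),
    prof_path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  stage_mark(out_dir, "profile", cfg$profile, seed)
  logf("profile: wrote %s", prof_path)
  invisible(list(manifest = manifest, features = features,
                 feature_path = feat_path, profile = profile))
}

config_schema <- list(
  top = c("seed", "out_dir", "simulate", "segment", "junctions", "notch",
          "profile"),
  simulate = names(formals(experiment_layout)),
  segment = names(formals(seg_params)),
  junctions = names(formals(junction_params)),
  notch = names(formals(spot_params)),
  profile = "components")

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), config_schema$top)
  for (sec in c("simulate", "segment", "junctions", "notch", "profile"))
    bad <- c(bad, paste0(sec, ".",
                         setdiff(names(cfg[[sec]]), config_schema[[sec]])))
  bad <- bad[!grepl("\\.$", bad) & bad != ""]
  if (length(bad) > 0)
    abort(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  invisible(cfg)
}

stage_hash <- function(section, seed) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(list(seed = seed, section = section), tf,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

stage_hash_path <- function(out_dir, stage)
  file.path(out_dir, paste0(".", stage, ".hash"))

stage_fresh <- function(out_dir, stage, section, seed) {
  p <- stage_hash_path(out_dir, stage)
  file.exists(p) && readLines(p, warn = FALSE)[1] == stage_hash(section, seed)
}

stage_mark <- function(out_dir, stage, section, seed)
  writeLines(stage_hash(section, seed), stage_hash_path(out_dir, stage))

stage_clear <- function(out_dir, stages)
  unlink(vapply(stages, stage_hash_path, character(1), out_dir = out_dir))
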