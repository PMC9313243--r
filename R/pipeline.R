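# End-to-end pipeline: simulate -> boundary map -> spot detection ->
# colocalization -> group comparison, as one configured, seeded, logged run.

# Recursive list merge: values in `user` override `defaults`.
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; any subset of
#' fields can be overridden by the user config (CLI flag > config file >
#' default). Groups are defined by a label, a number of images, and the
#' ground-truth `f_boundary` of their scenes.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      image = list(height = 512L, width = 512L, mean_cell_width = 16,
                   anisotropy = 3, boundary_thickness_px = 3),
      placement = list(n_spots = 50L, boundary_jitter_px = 1,
                       min_separation_px = 5, margin_px = 8),
      imaging = list(psf_sigma_px = 1.5, spot_photon_mean = 2000,
                     background_level = 100, noise_model = "poisson",
                     gaussian_noise_sd = 2, bit_depth = 16L),
      groups = list(list(label = "groupA", n_images = 3L, f_boundary = 0.8))),
    boundary_map = list(method = "ridge", scales = c(1, 2.5, 5),
                        train = list(n_per_class = 2000L)),
    spots = list(detection_threshold = 5, min_separation_px = 5,
                 window_radius_px = 4L),
    coloc = list(probability_threshold = 0.2, interpolation = "nearest",
                 histogram_bins = 20L, include_border_spots = TRUE),
    compare = list(contrasts = list(), n_permutations = 9999L,
                   unit = "image"))
}

#' Demo configuration emulating the agonist-vs-alone imaging comparison
#'
#' Two groups of three scenes each: `QD-MEL` with a low ground-truth
#' boundary fraction (0.3, conjugate able to enter cells) versus `+RAM`
#' with a high one (0.85, conjugate blocked at the apoplast), compared with
#' a pooled spot-level permutation test. With three images per group an
#' image-level permutation cannot resolve p below 2/20 = 0.1, so the demo
#' pools spots.
#'
#' @param seed Top-level seed.
#' @param image_size Scene side length in px.
#' @param n_images Images per group.
#' @return Configuration list for [run_pipeline()].
#' @export
fig4_demo_config <- function(seed = 1L, image_size = 256L, n_images = 3L) {
  cfg <- default_pipeline_config()
  cfg$seed <- as.integer(seed)
  cfg$simulate$image$height <- as.integer(image_size)
  cfg$simulate$image$width <- as.integer(image_size)
  cfg$simulate$placement$n_spots <- 40L
  cfg$simulate$groups <- list(
    list(label = "QD-MEL", n_images = as.integer(n_images), f_boundary = 0.3),
    list(label = "+RAM", n_images = as.integer(n_images), f_boundary = 0.85))
  cfg$compare$contrasts <- list(c("+RAM", "QD-MEL"))
  cfg$compare$unit <- "spot"
  cfg
}

#' Run the full colocalization pipeline
#'
#' Executes simulate -> boundary map -> spot detection/refinement ->
#' colocalization -> group comparison in dependency order, writing every
#' intermediate artifact plus the resolved configuration and a timestamped
#' stage log to `out_dir`. Rerunning with the same configuration and seed
#' reproduces `report.json` exactly.
#'
#' @param config Configuration list (see [default_pipeline_config()]), or a
#'   path to a JSON/YAML file holding one.
#' @param out_dir Run directory (created; existing files are overwritten).
#' @param quiet Suppress per-stage messages.
#' @return The report, invisibly: per-image colocalization results by group
#'   and one [compare_groups()] result per configured contrast. Also
#'   written as `report.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("qdcoloc_run_"),
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (length(cfg$simulate$groups) == 0) stop("config defines no groups")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_stage <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  log_stage("run start; config md5 ", cfg_hash,
            "; qdcoloc ", as.character(packageVersion("qdcoloc")))

  im <- cfg$simulate$image
  pl <- cfg$simulate$placement
  imspec <- do.call(imaging_spec, cfg$simulate$imaging)
  ccfg <- coloc_config(
    probability_threshold = cfg$coloc$probability_threshold,
    interpolation = cfg$coloc$interpolation,
    histogram_bins = cfg$coloc$histogram_bins,
    include_border_spots = cfg$coloc$include_border_spots)

  classifier <- NULL
  if (identical(cfg$boundary_map$method, "classifier")) {
    t0 <- Sys.time()
    train_scene <- simulate_scene(
      cell_network_spec(im$height, im$width,
                        mean_cell_width = im$mean_cell_width,
                        anisotropy = im$anisotropy,
                        boundary_thickness_px = im$boundary_thickness_px),
      do.call(spot_placement_spec, c(pl, list(f_boundary = 0.5))),
      imspec, rng_seed = derive_seed(cfg$seed, "train-scene"))
    ts <- make_pixel_training_set(
      train_scene$boundary_channel, train_scene$boundary_mask,
      n_per_class = cfg$boundary_map$train$n_per_class,
      scales = cfg$boundary_map$scales,
      rng_seed = derive_seed(cfg$seed, "train-pixels"))
    classifier <- train_pixel_classifier(
      ts, rng_seed = derive_seed(cfg$seed, "train-fit"))
    log_stage("trained pixel classifier in ",
              round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  }

  results_by_group <- list()
  for (g in cfg$simulate$groups) {
    group_results <- list()
    for (i in seq_len(g$n_images)) {
      t0 <- Sys.time()
      img_id <- paste0(g$label, "_", i)
      img_dir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", img_id))
      scene_seed <- derive_seed(cfg$seed, paste0("scene-", img_id))
      scene <- simulate_scene(
        cell_network_spec(im$height, im$width,
                          mean_cell_width = im$mean_cell_width,
                          anisotropy = im$anisotropy,
                          boundary_thickness_px = im$boundary_thickness_px),
        do.call(spot_placement_spec, c(pl, list(f_boundary = g$f_boundary))),
        imspec, rng_seed = scene_seed)
      write_scene(scene, img_dir)

      map <- if (is.null(classifier)) {
        ridge_probability_map(scene$boundary_channel,
                              scales = cfg$boundary_map$scales,
                              source_id = img_id)
      } else {
        predict_probability_map(scene$boundary_channel, classifier,
                                source_id = img_id)
      }
      write_probability_map(map, file.path(img_dir, "probability_map.tif"))

      det <- detect_spots(scene$qd_channel,
                          psf_sigma_px = imspec$psf_sigma_px,
                          detection_threshold = cfg$spots$detection_threshold,
                          min_separation_px = cfg$spots$min_separation_px,
                          source_id = img_id)
      ref <- refine_centroids(scene$qd_channel, det,
                              window_radius_px = cfg$spots$window_radius_px)
      write_spots_csv(ref, file.path(img_dir, "spots.csv"))

      cres <- colocalize(ref, map, ccfg, source_id = img_id)
      write_coloc_json(cres, file.path(img_dir, "coloc.json"))
      group_results[[i]] <- cres
      log_stage("image ", img_id, ": ", nrow(ref$spots),
                " spots, boundary fraction ",
                round(cres$boundary_fraction, 3), " (",
                round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s)")
    }
    results_by_group[[g$label]] <- group_results
  }

  comparisons <- list()
  for (ct in cfg$compare$contrasts) {
    ct <- unlist(ct)
    missing_groups <- setdiff(ct, names(results_by_group))
    if (length(missing_groups)) {
      stop("contrast names unknown group(s): ",
           paste(missing_groups, collapse = ", "))
    }
    gc <- compare_groups(results_by_group[ct],
                         n_permutations = cfg$compare$n_permutations,
                         rng_seed = derive_seed(cfg$seed, "compare"),
                         unit = cfg$compare$unit)
    comparisons[[paste(ct, collapse = "_vs_")]] <- gc
    jsonlite::write_json(
      unclass(gc),
      file.path(out_dir, paste0("comparison_",
                                gsub("[^A-Za-z0-9_.-]", "_",
                                     paste(ct, collapse = "_vs_")),
                                ".json")),
      auto_unbox = TRUE, digits = NA)
    log_stage("contrast ", paste(ct, collapse = " vs "), ": diff ",
              round(gc$observed_difference, 3), ", p = ",
              signif(gc$p_value, 3))
  }

  report <- list(
    config_md5 = cfg_hash,
    qdcoloc_version = as.character(packageVersion("qdcoloc")),
    per_image_fractions = lapply(results_by_group, function(g) {
      setNames(vapply(g, function(r) r$boundary_fraction, numeric(1)),
               vapply(g, function(r) r$source_id, character(1)))
    }),
    comparisons = lapply(comparisons, function(gc) {
      list(groups = gc$group_labels,
           observed_difference = gc$observed_difference,
           p_value = gc$p_value, unit = gc$unit,
           n_permutations = gc$n_permutations)
    }))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("run complete: ", file.path(out_dir, "report.json"))
  invisible(list(report = report, results_by_group = results_by_group,
                 comparisons = comparisons, out_dir = out_dir))
}
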