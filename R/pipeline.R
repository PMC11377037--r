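#' @name pipeline
#' @title End-to-end pipeline orchestration
#'
#' @description
#' `run_pipeline()` chains the full analysis — stimulus generation,
#' population simulation, ETA estimation and sparse PCA, contrast-space
#' analysis, luminance/color decoding, response typing with distribution
#' indices, sparse-noise spatial RFs, and the object-detection simulation —
#' from a single configuration list, writing CSV/JSON artifacts and a
#' checksum manifest to an output directory. Every analysis constant
#' (quality threshold 10, 8 PCs, 10 folds, enrichment threshold 0.3,
#' contour threshold 0.25, prediction threshold 0.25) lives in the config
#' and is serialized with the run. Stages cache their intermediate objects
#' so a re-run reuses upstream results and is bit-identical given the same
#' seeds.
NULL

#' Default pipeline configuration (demo scale)
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    out_dir = "results/pipeline",
    stimulus = list(duration_s = 300, rate_hz = 5),
    population = list(n_neurons = 200, noise_sd = 1, gain_sdlog = 0.15,
                      kernel_jitter = 0.05),
    analysis = list(quality_threshold = 10, n_pcs = 8, sparsity = 0.2,
                    folds = 10, enrichment_threshold = 0.3,
                    contour_threshold = 0.25, prediction_threshold = 0.25,
                    px_per_deg = 2),
    decoding = list(n_neurons = c(10, 50, 100)),
    typing = list(k_range = c(4, 8, 12, 17), selection_restarts = 1,
                  final_restarts = 5),
    sparse = list(repeats = 10),
    objects = list(n_scenes = 200, rf_size_deg = 10, threshold = 0)
  )
}

validate_config <- function(config) {
  if (is.null(config$population$n_neurons) || config$population$n_neurons < 1) {
    abort("config error: population$n_neurons must be >= 1")
  }
  if (config$stimulus$duration_s * config$stimulus$rate_hz < 100) {
    abort("config error: stimulus too short for ETA estimation")
  }
  invisible(TRUE)
}

write_stage_csv <- function(df, out_dir, name, files) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' @param config configuration list (see [default_config()]); may be a path
#'   to a JSON config file.
#' @param stages character vector of stages to run, a subset of
#'   c("stimulus", "simulate", "eta", "contrast", "decode", "typing",
#'   "spatial", "objects"). Later stages load cached upstream results.
#' @return invisibly, a list with the run directory and the manifest
#'   data.frame (file, md5).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("stimulus", "simulate", "eta", "contrast",
                                    "decode", "typing", "spatial", "objects")) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_config(config)
  out_dir <- config$out_dir
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- file.path(out_dir, "config.json")
  seed <- config$seed

  cache <- function(name, expr) {
    path <- file.path(cache_dir, paste0(name, ".rds"))
    if (file.exists(path)) return(readRDS(path))
    val <- expr
    saveRDS(val, path)
    val
  }

  msg <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))

  if ("stimulus" %in% stages) msg("stage stimulus")
  stim <- cache("stim", make_color_noise(config$stimulus$duration_s,
                                         config$stimulus$rate_hz,
                                         seed = child_seed(seed, 1L)))
  pop <- cache("pop", {
    spec <- population_spec(config$population$n_neurons,
                            noise_sd = config$population$noise_sd,
                            gain_sdlog = config$population$gain_sdlog,
                            kernel_jitter = config$population$kernel_jitter,
                            seed = child_seed(seed, 2L))
    sample_population(spec)
  })
  if ("stimulus" %in% stages || "simulate" %in% stages) {
    files <- write_stage_csv(pop$neurons, out_dir, "neurons.csv", files)
  }

  if ("simulate" %in% stages) msg("stage simulate (%d neurons)", nrow(pop$neurons))
  resp <- cache("resp", simulate_noise_responses(pop, stim))

  if ("eta" %in% stages) msg("stage eta")
  etaset <- cache("etaset", {
    es <- compute_eta(stim, resp)
    es <- kernel_quality(es, threshold = config$analysis$quality_threshold)
    basis <- fit_sparse_pca(es, n_components = config$analysis$n_pcs,
                            sparsity = config$analysis$sparsity)
    es <- apply_sparse_pca(es, basis)
    attr(es, "basis") <- basis
    es
  })
  eta_summary <- data.frame(
    neuron_id = etaset$neurons$neuron_id,
    quality_green_c = etaset$quality[, "GreenC"],
    quality_uv_c = etaset$quality[, "UVC"],
    include = etaset$include
  )
  files <- write_stage_csv(eta_summary, out_dir, "eta_quality.csv", files)
  files <- write_stage_csv(attr(etaset, "basis")$mse_curve, out_dir,
                           "pca_mse_curve.csv", files)

  if ("contrast" %in% stages) {
    msg("stage contrast space")
    amps <- peak_amplitudes(etaset)
    amps$sc <- suppressWarnings(
      spectral_contrast(abs(amps$green_c), abs(amps$uv_c)))
    files <- write_stage_csv(amps, out_dir, "contrast_points.csv", files)
    vs <- list(center = variance_split(amps[, c("green_c", "uv_c")]),
               surround = variance_split(amps[, c("green_s", "uv_s")]))
    jsonlite::write_json(
      lapply(vs, function(v) list(fraction_luminance = v$fraction_luminance,
                                  fraction_color = v$fraction_color, n = v$n)),
      file.path(out_dir, "variance_split.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "variance_split.json"))
  }

  if ("decode" %in% stages) {
    msg("stage decoding")
    tf <- cache("trial_features", extract_trial_features(resp, stim))
    grid <- expand.grid(compartment = c("center", "surround"),
                        target = c("luminance", "color"),
                        n_neurons = config$decoding$n_neurons,
                        stringsAsFactors = FALSE)
    dec <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      labs <- trial_labels(tf, g$compartment, g$target)
      dr <- decode_class(tf$features, labs,
                         n_neurons = min(g$n_neurons, ncol(tf$features)),
                         seed = child_seed(seed, 30L + i),
                         n_folds = config$analysis$folds)
      transform(dr$splits, compartment = g$compartment, target = g$target,
                n_neurons = dr$n_neurons)
    }))
    files <- write_stage_csv(dec, out_dir, "decoding.csv", files)
  }

  if ("typing" %in% stages) {
    msg("stage typing")
    keep <- which(etaset$include)
    W <- etaset$pc_weights[keep, , drop = FALSE]
    sel <- cache("typing", suppressWarnings(
      select_and_fit(W, config$typing$k_range, seed = child_seed(seed, 40L),
                     selection_restarts = config$typing$selection_restarts,
                     final_restarts = config$typing$final_restarts)))
    files <- write_stage_csv(sel$curve, out_dir, "typing_selection.csv", files)
    di <- type_distribution_indices(sel$model$assignments,
                                    etaset$neurons$field[keep])
    part <- enrichment_partition(di, config$analysis$enrichment_threshold)
    typing_tab <- merge(di, part[, c("type", "group")], by = "type")
    files <- write_stage_csv(typing_tab, out_dir, "typing_types.csv", files)
    per_neuron <- data.frame(neuron_id = etaset$neurons$neuron_id[keep],
                             type = sel$model$assignments,
                             field = etaset$neurons$field[keep])
    files <- write_stage_csv(per_neuron, out_dir, "typing_neurons.csv", files)
  }

  if ("spatial" %in% stages) {
    msg("stage spatial RF")
    sn <- cache("sparse_stim", make_sparse_noise(repeats = config$sparse$repeats,
                                                 seed = child_seed(seed, 50L)))
    sresp <- cache("sparse_resp", simulate_sparse_noise_responses(pop, sn))
    srf <- spatial_rf_table(sresp,
                            contour = config$analysis$contour_threshold)
    files <- write_stage_csv(srf$table, out_dir, "spatial_rf.csv", files)
  }

  if ("objects" %in% stages) {
    msg("stage object detection (%d+%d scenes)",
        config$objects$n_scenes, config$objects$n_scenes)
    keep <- which(etaset$include)
    amps <- peak_amplitudes(etaset)
    sel <- cache("typing", suppressWarnings(
      select_and_fit(etaset$pc_weights[keep, , drop = FALSE],
                     config$typing$k_range, seed = child_seed(seed, 40L),
                     selection_restarts = config$typing$selection_restarts,
                     final_restarts = config$typing$final_restarts)))
    rfs <- build_type_rfs(sel$model$assignments, amps,
                          rf_size_deg = config$objects$rf_size_deg,
                          px_per_deg = config$analysis$px_per_deg)
    n_sc <- config$objects$n_scenes
    noise_sc <- make_scenes(n_sc, with_object = FALSE,
                            seed = child_seed(seed, 60L))
    obj_sc <- make_scenes(n_sc, with_object = TRUE,
                          seed = child_seed(seed, 61L))
    obj_sc <- match_contrast(obj_sc, noise_sc)
    responses <- simulate_scene_responses(rfs, c(obj_sc, noise_sc),
                                          threshold = config$objects$threshold)
    labels <- rep(c("object", "noise"), each = n_sc)
    obj_dec <- decode_object_presence(responses, labels,
                                      seed = child_seed(seed, 62L),
                                      n_folds = config$analysis$folds)
    files <- write_stage_csv(obj_dec, out_dir, "object_decoding.csv", files)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, digits = NA)
  msg("done: %d artifacts in %s", nrow(manifest), out_dir)
  invisible(list(out_dir = out_dir, manifest = manifest))
}
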