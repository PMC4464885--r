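# Configuration and the end-to-end pipeline:
# simulate (optional) -> detect -> quantify -> rank -> qc,
# with a run log capturing everything needed to reproduce the run.

#' Default screening configuration
#'
#' Flat hierarchical configuration with one section per pipeline stage;
#' every parameter of the simulator and the analysis has a home here.
#' Units: lengths in pixels, times in seconds, intensities in expected
#' photon counts per pixel, windows as 0-based half-open `[start, end)`.
#'
#' @return nested named list of class `screen_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(enabled = TRUE),
    plate = list(n_colonies = 750, plate_radius = 395,
                 min_separation = 18, radius_min = 3.5, radius_max = 5),
    sensors = list(R0_meanlog = log(0.95), R0_sdlog = 0.2,
                   dRR_meanlog = log(1.0), dRR_sdlog = 0.30,
                   brightness_meanlog = log(300), brightness_sdlog = 0.2),
    spray = list(model = "uniform", gradient = 0.5, power = 1,
                 patch_sdlog = 0.5, patch_scale = 30),
    optics = list(background_mode = "paper", background_level = 20,
                  mottle_amplitude = 0.25, mottle_scale = 40,
                  vignette_strength = 0.08, acceptor_direct_gain = 2.0,
                  artifact_gain = 0),
    noise = list(shot_noise = TRUE, read_noise_sd = 3, quantize = TRUE),
    kinetics = list(tau = 30),
    frames = list(n_frames = 16, frame_interval = 30,
                  application_frame = 4),
    detect = list(stat_mode = "robust", k_sigma = 3, erosion_radius = 1,
                  opening_radius = 2, connectivity = 8, min_area = 20,
                  max_area = NA, border_margin = 5, frame = 0),
    quantify = list(background = "local", response_mode = "mean-window",
                    artifact_threshold = 0.15),
    rank = list(top_fraction = 0.02, exclude_border = TRUE,
                exclude_artifact = TRUE),
    qc = list(spray_center = "image-center", exponent_p = 1,
              correct_radial = FALSE, eps = 0.1)
  ), class = "screen_config")
}

# Recursive validation against the default template: unknown keys are
# rejected, missing keys are filled with defaults.
merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]]))
        stop("config section ", path, k, " must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a YAML screening configuration
#'
#' Unknown keys are rejected; omitted keys take their documented
#' defaults, so a loaded config always normalizes to the full form.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a normalized `screen_config`.
#' @export
read_screen_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "screen_config")
  }
  cfg
}

#' Write a configuration as YAML
#' @param config a `screen_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_screen_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

config_objects <- function(cfg) {
  list(
    sensor = sensor_params(cfg$sensors$R0_meanlog, cfg$sensors$R0_sdlog,
                           cfg$sensors$dRR_meanlog, cfg$sensors$dRR_sdlog,
                           cfg$sensors$brightness_meanlog,
                           cfg$sensors$brightness_sdlog),
    optics = optics_params(cfg$optics$background_mode,
                           cfg$optics$background_level,
                           cfg$optics$mottle_amplitude,
                           cfg$optics$mottle_scale,
                           cfg$optics$vignette_strength,
                           cfg$optics$acceptor_direct_gain,
                           cfg$optics$artifact_gain),
    noise = noise_params(cfg$noise$shot_noise, cfg$noise$read_noise_sd,
                         cfg$noise$quantize),
    kinetics = kinetics_params(cfg$kinetics$tau),
    frames = frames_spec(cfg$frames$n_frames, cfg$frames$frame_interval,
                         cfg$frames$application_frame),
    detect = detect_params(cfg$detect$stat_mode, cfg$detect$k_sigma,
                           cfg$detect$erosion_radius,
                           cfg$detect$opening_radius,
                           cfg$detect$connectivity, cfg$detect$min_area,
                           if (is.na(cfg$detect$max_area)) NULL
                           else cfg$detect$max_area,
                           cfg$detect$border_margin,
                           frame = cfg$detect$frame)
  )
}

#' Run the full screening pipeline
#'
#' Executes simulate (if enabled) -> detect -> quantify -> rank -> qc and
#' writes all artifacts under `out_dir`: the stack TIFFs and truth
#' manifest, label TIFF and colonies CSV, traces and colony-table CSVs,
#' picks CSV with the three report figures, the QC summary, the
#' normalized config, and `run_log.json` (package version, seed, config
#' hash, per-stage counts) — enough to re-execute a bit-identical run.
#'
#' @param config a `screen_config` (or path to a YAML config).
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @param stack optional pre-existing `plate_stack` (skips simulation
#'   even if enabled in the config).
#' @return list with `colony_map`, `table`, `ranking`, `qc`,
#'   `manifest` (when simulated), `paths`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         seed = NULL, stack = NULL) {
  if (is.character(config)) config <- read_screen_config(config)
  if (!is.null(seed)) config$seed <- seed
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  paths <- list()
  counts <- list()
  manifest <- NULL

  cfg_path <- file.path(out_dir, "config.yaml")
  write_screen_config(cfg, cfg_path)
  paths$config <- cfg_path

  if (is.null(stack)) {
    if (!isTRUE(cfg$simulate$enabled))
      stop("stage simulate: no stack supplied and simulation disabled")
    sim <- simulate_plate(
      n_colonies = cfg$plate$n_colonies,
      plate_radius = cfg$plate$plate_radius,
      min_separation = cfg$plate$min_separation,
      radius_range = c(cfg$plate$radius_min, cfg$plate$radius_max),
      spray_model = cfg$spray$model,
      spray_params = list(gradient = cfg$spray$gradient,
                          power = cfg$spray$power,
                          patch_sdlog = cfg$spray$patch_sdlog,
                          patch_scale = cfg$spray$patch_scale),
      sensor = obj$sensor, optics = obj$optics, noise = obj$noise,
      kinetics = obj$kinetics, frames = obj$frames, seed = cfg$seed)
    stack <- sim$stack
    manifest <- sim$manifest
    paths$stack <- write_stack(stack, out_dir, "run")
    mpath <- file.path(out_dir, "run_manifest.csv")
    write.csv(manifest, mpath, row.names = FALSE)
    paths$manifest <- mpath
    counts$simulated_colonies <- nrow(manifest)
  }

  colony_map <- detect_colonies(stack, obj$detect)
  paths$colony_map <- write_colony_map(colony_map, out_dir, "run")
  counts$detected_colonies <- nrow(colony_map$records)

  table <- quantify_colonies(stack, colony_map,
                             background = cfg$quantify$background,
                             response_mode = cfg$quantify$response_mode,
                             artifact_threshold =
                               cfg$quantify$artifact_threshold)
  traces <- attr(table, "traces")
  tpath <- file.path(out_dir, "colony_table.csv")
  write.csv(table, tpath, row.names = FALSE)
  paths$colony_table <- tpath
  paths$traces <- write_traces(traces,
                               file.path(out_dir, "traces.csv"))
  counts$quantified_colonies <- nrow(table)

  ranked <- rank_colonies(table, cfg$rank$exclude_border,
                          cfg$rank$exclude_artifact)
  ranking <- select_top(ranked, fraction = cfg$rank$top_fraction)
  paths$reports <- make_reports(ranking, out_dir, traces = traces)
  counts$selected_colonies <- ranking$k

  qc <- list(summary = qc_summary(ranked))
  if (nrow(ranked) >= 10) {
    qc$radial <- fit_radial_model(ranked, cfg$qc$spray_center,
                                  cfg$qc$exponent_p)
    if (isTRUE(cfg$qc$correct_radial)) {
      qc$corrected <- correct_radial(ranked, qc$radial, cfg$qc$eps)
      cpath <- file.path(out_dir, "colony_table_corrected.csv")
      write.csv(qc$corrected, cpath, row.names = FALSE)
      paths$corrected_table <- cpath
    }
  }
  qpath <- file.path(out_dir, "qc_summary.csv")
  write.csv(qc$summary, qpath, row.names = FALSE)
  paths$qc_summary <- qpath

  log <- list(package = "fretscreen",
              version = as.character(packageVersion("fretscreen")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = cfg$seed,
              config_md5 = unname(tools::md5sum(cfg_path)),
              counts = counts)
  lpath <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, lpath, auto_unbox = TRUE, digits = NA)
  paths$run_log <- lpath

  list(colony_map = colony_map, table = table, ranking = ranking,
       qc = qc, manifest = manifest, paths = paths)
}
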