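#' Default pipeline configuration
#'
#' A nested list mirroring every tunable parameter of the pipeline, with
#' defaults equal to the module-level defaults. Serialises losslessly through
#' YAML/JSON via [write_config()]/[read_config()].
#'
#' @param n_neurons Neurons per condition in the simulate stage.
#' @param seed Master seed; per-stage seeds are derived from it so stages can
#'   be re-run independently.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_neurons = 60, seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    population = list(
      n_neurons = as.integer(n_neurons),
      class_proportions = list(il1b_specific = 0.15, tnf_specific = 0.25,
                               il10_responsive = 0.20, multi_cytokine = 0.25,
                               non_cytokine = 0.15),
      sampling_rate = 20, duration = 1000, latency_max = 100,
      n_animals = 10, active_noncytokine = TRUE,
      events = list(time_s = c(150, 450, 750),
                    stimulus = c("IL-1b", "TNF", "IL-10"),
                    concentration_ng_per_ml = c(200, 50, 50))),
    conditions = c("control", "dss"),
    detection = list(noise_sd_estimator = "mad", onset_k = 3,
                     offset_frac = 0.2, min_duration = 0.5,
                     smoothing_window = 5, peak_prominence_frac = 0.2,
                     abs_floor = 5),
    assignment = list(window_s = 100, exclude_if_active_at_event = TRUE,
                      exclude_saline_responders = FALSE,
                      baseline_window_s = 50, min_traces_per_animal = 10),
    # subsample size m is omitted: the adaptive default (80% of the smallest
    # group-by-condition cell) is used unless a config supplies one
    separability = list(fence_k = 1.5, drop_fraction = 0.25,
                        standardize = TRUE, S = 20, P = 499)),
    class = "pipeline_config")
}

#' Write a pipeline configuration to YAML or JSON
#' @param config A [pipeline_config()]-shaped list.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(config)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stopf("unsupported config extension '%s'", ext)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#' @param path YAML or JSON path.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stopf("unsupported config extension '%s'", ext)
  structure(cfg, class = "pipeline_config")
}

config_population <- function(config, seed) {
  p <- config$population
  population_spec(
    n_neurons = p$n_neurons,
    class_proportions = unlist(p$class_proportions),
    sampling_rate = p$sampling_rate, duration = p$duration,
    event_schedule = stimulus_events(p$events$time_s, p$events$stimulus,
                                     p$events$concentration_ng_per_ml),
    seed = seed, latency_max = p$latency_max, n_animals = p$n_animals,
    active_noncytokine = p$active_noncytokine)
}

config_condition <- function(name) {
  switch(name, control = control_condition(), dss = dss_condition(),
         stopf("unknown condition '%s'", name))
}

config_detection <- function(config) do.call(detection_params, config$detection)
config_assignment <- function(config) do.call(assignment_params,
                                              config$assignment)

artifact_path <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stopf("missing artifact '%s'; run '%s' first", path, producer)
  path
}

check_overwrite <- function(paths, overwrite) {
  exists <- paths[file.exists(paths)]
  if (length(exists) && !overwrite)
    stopf("artifact '%s' already exists; use overwrite = TRUE", exists[1L])
}

update_manifest <- function(out_dir, stage, config, files) {
  mpath <- artifact_path(out_dir, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = TRUE) else list()
  sums <- as.list(tools::md5sum(files[file.exists(files)]))
  names(sums) <- basename(names(sums))
  manifest[[stage]] <- list(seed = config$seed,
                            package_version = as.character(
                              utils::packageVersion("vagaltrace")),
                            checksums = sums)
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Pipeline stage: simulate
#'
#' Simulates one dataset per condition and writes `traces_<cond>.csv`,
#' `truth_<cond>.json`, and `events.csv` under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing existing artifacts.
#' @return Invisibly, the list of written paths.
#' @export
pipeline_simulate <- function(config, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- config$conditions
  files <- c(artifact_path(out_dir, "events.csv"),
             artifact_path(out_dir, paste0("traces_", conds, ".csv")),
             artifact_path(out_dir, paste0("truth_", conds, ".json")))
  check_overwrite(files, overwrite)
  for (i in seq_along(conds)) {
    cond <- conds[i]
    ds <- simulate_population(config_population(config, config$seed + i),
                              config_condition(cond))
    write_traces(ds$traces, artifact_path(out_dir,
                                          paste0("traces_", cond, ".csv")))
    write_truth(ds$truth, artifact_path(out_dir,
                                        paste0("truth_", cond, ".json")))
    if (i == 1L) write_events(ds$events, artifact_path(out_dir, "events.csv"))
  }
  update_manifest(out_dir, "simulate", config, files)
  invisible(files)
}

#' Pipeline stage: detect
#'
#' Reads the simulated traces and writes per-transient feature tables
#' `features_<cond>.csv`.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the list of written paths.
#' @export
pipeline_detect <- function(config, out_dir, overwrite = FALSE) {
  params <- config_detection(config)
  conds <- config$conditions
  files <- artifact_path(out_dir, paste0("features_", conds, ".csv"))
  check_overwrite(files, overwrite)
  for (i in seq_along(conds)) {
    cond <- conds[i]
    traces <- read_traces(require_artifact(
      artifact_path(out_dir, paste0("traces_", cond, ".csv")), "simulate"))
    truth <- read_truth(require_artifact(
      artifact_path(out_dir, paste0("truth_", cond, ".json")), "simulate"))
    feats <- detect_all(traces, params)
    feats$animal_id <- truth$neurons$animal_id[
      match(feats$neuron_id, truth$neurons$neuron_id)]
    write_features(feats, files[i])
  }
  update_manifest(out_dir, "detect", config, files)
  invisible(files)
}

#' Pipeline stage: classify
#'
#' Assigns responses and classifies neurons per condition, writing
#' `classification_<cond>.json` (classes, responses, responder proportions,
#' baseline counts).
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the list of written paths.
#' @export
pipeline_classify <- function(config, out_dir, overwrite = FALSE) {
  params <- config_assignment(config)
  conds <- config$conditions
  files <- artifact_path(out_dir, paste0("classification_", conds, ".json"))
  check_overwrite(files, overwrite)
  events <- read_events(require_artifact(artifact_path(out_dir, "events.csv"),
                                         "simulate"))
  for (i in seq_along(conds)) {
    cond <- conds[i]
    feats <- read_features(require_artifact(
      artifact_path(out_dir, paste0("features_", cond, ".csv")), "detect"))
    truth <- read_truth(artifact_path(out_dir, paste0("truth_", cond, ".json")))
    cls <- classify_neurons(feats, events, params,
                            neuron_ids = truth$neurons$neuron_id)
    props <- responder_proportions(cls,
                                   exclude_saline = params$exclude_saline_responders)
    responses <- attr(cls, "responses")
    write_results_json(
      list(condition = cond,
           classes = cls,
           proportions = as.list(props),
           baseline_active = count_active_baseline(
             feats, params$baseline_window_s, events),
           responses = responses),
      files[i])
  }
  update_manifest(out_dir, "classify", config, files)
  invisible(files)
}

#' Pipeline stage: separability
#'
#' Assembles the five-feature matrix across conditions and runs the full
#' cluster-separability procedure, writing `separability.json`.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the written path.
#' @export
pipeline_separability <- function(config, out_dir, overwrite = FALSE) {
  out <- artifact_path(out_dir, "separability.json")
  check_overwrite(out, overwrite)
  events <- read_events(require_artifact(artifact_path(out_dir, "events.csv"),
                                         "simulate"))
  params <- config_assignment(config)
  fm <- do.call(rbind, lapply(config$conditions, function(cond) {
    feats <- read_features(require_artifact(
      artifact_path(out_dir, paste0("features_", cond, ".csv")), "detect"))
    assemble_feature_matrix(assign_responses(feats, events, params), cond)
  }))
  sp <- config$separability
  res <- separability_analysis(fm, fence_k = sp$fence_k,
                               drop_fraction = sp$drop_fraction,
                               standardize = sp$standardize, S = sp$S,
                               m = sp$m, P = sp$P,
                               seed = config$seed + 10L)
  write_results_json(
    list(ch = as.list(res$ch), u_statistic = res$u_statistic,
         p_value = res$p_value,
         n_steps = as.list(res$n_steps),
         n_kept = as.data.frame(res$n_kept),
         params = res$params),
    out)
  update_manifest(out_dir, "separability", config, out)
  invisible(out)
}

#' Pipeline stage: report
#'
#' Aggregates classification and separability outputs into `report.json`:
#' responder proportions, baseline activity, per-cytokine amplitude means,
#' and the separability comparison.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the written path.
#' @export
pipeline_report <- function(config, out_dir, overwrite = FALSE) {
  out <- artifact_path(out_dir, "report.json")
  check_overwrite(out, overwrite)
  conds <- config$conditions
  sep <- jsonlite::read_json(require_artifact(
    artifact_path(out_dir, "separability.json"), "separability"),
    simplifyVector = TRUE)
  per_cond <- lapply(conds, function(cond) {
    cl <- jsonlite::read_json(require_artifact(
      artifact_path(out_dir, paste0("classification_", cond, ".json")),
      "classify"), simplifyVector = TRUE)
    resp <- as.data.frame(cl$responses, stringsAsFactors = FALSE)
    amp <- if (nrow(resp)) {
      vapply(split(resp$amplitude[!resp$censored],
                   resp$stimulus[!resp$censored]), mean, numeric(1))
    } else numeric(0)
    list(proportions = cl$proportions, baseline_active = cl$baseline_active,
         evoked_amplitude_mean = as.list(amp))
  })
  names(per_cond) <- conds
  write_results_json(list(conditions = per_cond, separability = sep), out)
  update_manifest(out_dir, "report", config, out)
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes simulate -> detect -> classify -> separability -> report into
#' `out_dir`. Deterministic for a fixed config: two runs with the same
#' configuration produce byte-identical result files.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the output directory.
#' @examples
#' \dontrun{
#' cfg <- pipeline_config(n_neurons = 40, seed = 7)
#' run_pipeline(cfg, tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  pipeline_simulate(config, out_dir, overwrite)
  pipeline_detect(config, out_dir, overwrite)
  pipeline_classify(config, out_dir, overwrite)
  pipeline_separability(config, out_dir, overwrite)
  pipeline_report(config, out_dir, overwrite)
  invisible(out_dir)
}
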